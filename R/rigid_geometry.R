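# Rigid-body mathematics: optimal superposition, principal-axis frames and
# swing-twist decomposition. These primitives underpin the hinge/twist
# analysis, so they are implemented here from first principles; tests
# cross-check the superposition against bio3d::fit.xyz.

as_xyz <- function(x) {
  if (inherits(x, "coordset")) x$xyz else unname(as.matrix(x))
}

#' Build a rotation matrix from an axis and angle
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg Rotation angle, degrees (right-handed about `axis`).
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

is_proper_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == 3L) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of paired point sets over proper rotations
#' and translations, with the determinant correction that forbids
#' reflections even for degenerate (e.g. planar) inputs.
#'
#' @param mobile,target Paired `coordset`s or N x 3 matrices, equal length,
#'   N >= 3.
#' @return List with `transform` (a `rigid_transform`: `R` 3 x 3 rotation,
#'   `t` translation such that `x -> R x + t`) and `rmsd` (Angstrom, the
#'   least-squares minimum).
#' @export
kabsch_superpose <- function(mobile, target) {
  M <- as_xyz(mobile); T_ <- as_xyz(target)
  if (nrow(M) != nrow(T_)) kd_stop("point sets differ in length",
                                   "kirdock_config_error")
  if (nrow(M) < 3L) kd_stop("need at least 3 paired points",
                            "kirdock_config_error")
  cm <- colMeans(M); ct <- colMeans(T_)
  Mc <- sweep(M, 2, cm); Tc <- sweep(T_, 2, ct)
  H <- crossprod(Mc, Tc)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(ct - R %*% cm)
  fitted <- Mc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Tc)^2)))
  list(transform = new_rigid_transform(R, t_vec), rmsd = rmsd)
}

new_rigid_transform <- function(R, t) {
  if (!is_proper_rotation(R)) kd_stop("rotation must be proper (det +1)",
                                      "kirdock_config_error")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords A `coordset` or N x 3 matrix.
#' @param transform A `rigid_transform` (see [kabsch_superpose()]).
#' @return Same type as `coords`, with `x' = R x + t` and labels unchanged.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  xyz <- as_xyz(coords)
  out <- sweep(xyz %*% t(transform$R), 2, -transform$t)
  if (inherits(coords, "coordset")) new_coordset(coords$labels, out) else out
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rinv <- t(transform$R)
  new_rigid_transform(Rinv, -as.numeric(Rinv %*% transform$t))
}

#' Principal-axis frame of a point cloud
#'
#' Computes the centroid and the orthonormal right-handed triad of principal
#' axes of a C-alpha cloud: `e1` (long axis, largest covariance eigenvalue),
#' `e2` (middle, the hinge axis) and `e3 = e1 x e2` (short, the twist axis).
#' Sign conventions make the frame reproducible: `e1` points from the
#' centroid of the first 10% of residues (in residue order) toward the
#' centroid of the last 10%; `e2` points into the hemisphere of the `up`
#' reference direction (for a domain within a complex, the platform-to-
#' receptor direction; the lab +z otherwise).
#'
#' @param coords A `coordset` (residue order taken from its labels) or an
#'   N x 3 matrix (row order used as residue order).
#' @param up Reference direction fixing the sign of `e2`
#'   (default `c(0, 0, 1)`).
#' @return A `domain_frame`: list with `centroid`, `axes` (3 x 3 matrix with
#'   columns e1, e2, e3) and `evals` (descending covariance eigenvalues).
#' @export
principal_frame <- function(coords, up = c(0, 0, 1)) {
  xyz <- as_xyz(coords)
  if (nrow(xyz) < 4L) kd_stop("need at least 4 points for a frame",
                              "kirdock_config_error")
  centroid <- colMeans(xyz)
  Xc <- sweep(xyz, 2, centroid)
  cv <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(cv, symmetric = TRUE)   # eigenvalues in decreasing order
  ev <- eg$values
  if (ev[2] <= 0 || ev[3] <= 0 || ev[1] / ev[2] < 1.01 || ev[2] / ev[3] < 1.01) {
    kd_stop(sprintf(paste0("degenerate anisotropy: eigenvalue ratios ",
                           "%.4f, %.4f must both exceed 1.01"),
                    ev[1] / max(ev[2], .Machine$double.eps),
                    ev[2] / max(ev[3], .Machine$double.eps)),
            "kirdock_degenerate_frame")
  }
  e1 <- eg$vectors[, 1]; e2 <- eg$vectors[, 2]
  k <- max(1L, floor(nrow(xyz) / 10))
  nc_dir <- colMeans(xyz[(nrow(xyz) - k + 1L):nrow(xyz), , drop = FALSE]) -
    colMeans(xyz[1:k, , drop = FALSE])
  if (sum(e1 * nc_dir) < 0) e1 <- -e1
  if (sum(e2 * up) < 0) e2 <- -e2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  structure(list(centroid = centroid, axes = cbind(e1 = e1, e2 = e2, e3 = e3),
                 evals = ev), class = "domain_frame")
}

# Quaternion helpers (w, x, y, z), scalar first ---------------------------

rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Swing-twist decomposition of a rotation
#'
#' Factors a proper rotation `R` exactly as `R = swing %*% twist`, where
#' `twist` is a rotation about the given axis and `swing` is a rotation
#' about an axis perpendicular to it. The twist angle is the component of
#' the rotation "about" the axis; it is what the docking comparison reports
#' as the twist of a receptor domain between two complexes.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @param axis Unit 3-vector (normalized internally).
#' @return List with `twist_deg` (signed, in (-180, 180]), `twist` and
#'   `swing` rotation matrices.
#' @export
swing_twist <- function(R, axis) {
  if (!is_proper_rotation(R)) kd_stop("R must be a proper rotation",
                                      "kirdock_config_error")
  a <- axis / sqrt(sum(axis^2))
  q <- rotation_to_quaternion(R)
  proj <- sum(q[2:4] * a)
  tq <- c(q[1], proj * a)
  n <- sqrt(sum(tq^2))
  if (n < 1e-12) {
    # 180-degree rotation about an axis perpendicular to `a`: pure swing
    twist <- diag(3)
    twist_deg <- 0
  } else {
    tq <- tq / n
    twist <- quaternion_to_rotation(tq)
    twist_deg <- 2 * atan2(proj / n, q[1] / n) * 180 / pi
  }
  if (twist_deg <= -180) twist_deg <- twist_deg + 360
  if (twist_deg > 180) twist_deg <- twist_deg - 360
  swing <- R %*% t(twist)
  list(twist_deg = twist_deg, twist = twist, swing = swing)
}

#' Serialize a rigid transform to a 12-number vector
#' @param transform A `rigid_transform`.
#' @return Numeric vector: the 9 rotation entries (row-major) then the
#'   3 translation components.
#' @export
transform_to_vector <- function(transform) {
  c(t(transform$R), transform$t)
}
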