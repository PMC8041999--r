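# Ground-truthed synthetic data: rigid ellipsoidal "domains" assembled into
# two-domain receptor complexes docked on a platform with controllable
# hinge, per-domain twist, centre-of-mass shift and coordinate noise; plus
# steady-state binding series and bead panels with known truth. Every
# generator is a pure function of (parameters, seed).

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Sub-streams are derived as (seed * 1000 + k) mod 2^31 - 1.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sub_seed <- function(seed, k) (abs(seed) * 1000 + k) %% (2^31 - 1)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Sample a rigid ellipsoidal C-alpha body with exact principal axes
#'
#' Points are drawn uniformly in an ellipsoid of semi-axes `(a, b, c)` and
#' then exactly whitened and rescaled so that the sample covariance equals
#' the target diagonal: the construction axes coincide with the sample
#' principal axes, so [principal_frame()] recovers them to numerical
#' precision rather than to Monte-Carlo sampling error. Residues are
#' labelled sequentially along the long axis.
#'
#' @param n_atoms Number of points (>= 30).
#' @param anisotropy Semi-axes `c(a, b, c)` in Angstrom with `a > b > c`
#'   and both `a/b` and `b/c` at least 1.5.
#' @param seed Integer RNG seed.
#' @param chain Chain id for the labels (default `"X"`).
#' @param resno_start First residue number (default 1).
#' @return A `coordset` of C-alpha points in the canonical frame (long axis
#'   +x, middle +y, short +z), centred at the origin.
#' @export
make_rigid_body <- function(n_atoms, anisotropy, seed, chain = "X",
                            resno_start = 1L) {
  stopifnot(length(anisotropy) == 3L)
  a <- anisotropy[1]; b <- anisotropy[2]; cc <- anisotropy[3]
  if (!(a > b && b > cc) || a / b < 1.5 || b / cc < 1.5) {
    kd_stop("anisotropy must satisfy a > b > c with a/b and b/c >= 1.5",
            "kirdock_degenerate_frame")
  }
  if (n_atoms < 30L) kd_stop("need at least 30 atoms", "kirdock_config_error")
  X <- with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- stats::runif(n_atoms)^(1 / 3)
    sweep(u * r, 2, c(a, b, cc), "*")
  })
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n_atoms
  eg <- eigen(S, symmetric = TRUE)
  W <- eg$vectors %*% diag(1 / sqrt(eg$values))
  Y <- Xc %*% W                       # exact identity sample covariance
  Z <- Y %*% diag(c(a, b, cc) / sqrt(5))
  Z <- Z[order(Z[, 1]), , drop = FALSE]
  n <- nrow(Z)
  labels <- data.frame(chain = chain,
                       resno = seq.int(resno_start, length.out = n),
                       insert = "", resid = "ALA", elety = "CA", elesy = "C",
                       stringsAsFactors = FALSE)
  new_coordset(labels, Z)
}

# Assemble an atom table (CA + dummy CB per residue) from a coordset body.
# CB sits 1.53 A outward from the body centroid so that surfaces facing
# other bodies carry protruding heavy atoms, making contact and buried-
# surface computations meaningful.
body_atoms <- function(cs, het = FALSE) {
  ctr <- colMeans(cs$xyz)
  dir <- sweep(cs$xyz, 2, ctr)
  nrm <- sqrt(rowSums(dir^2)); nrm[nrm < 1e-9] <- 1
  cb <- cs$xyz + dir / nrm * 1.53
  n <- nrow(cs$xyz)
  idx <- rep(seq_len(n), each = 2L)
  data.frame(chain = cs$labels$chain[idx], resno = cs$labels$resno[idx],
             insert = "", resid = "ALA",
             elety = rep(c("CA", "CB"), n), elesy = "C", alt = "", o = 1,
             x = as.vector(rbind(cs$xyz[, 1], cb[, 1])),
             y = as.vector(rbind(cs$xyz[, 2], cb[, 2])),
             z = as.vector(rbind(cs$xyz[, 3], cb[, 3])),
             het = het, stringsAsFactors = FALSE)
}

translate_cs <- function(cs, v) new_coordset(cs$labels, sweep(cs$xyz, 2, -v))

rotate_cs <- function(cs, R) new_coordset(cs$labels, cs$xyz %*% t(R))

#' Generate a synthetic two-domain receptor complex with a known hinge angle
#'
#' Builds a platform body (180 residues, long axis = groove axis), a
#' 9-residue peptide lying along the groove just above the platform
#' surface, a small body standing in for beta-2 microglobulin beneath the
#' platform, and a two-domain receptor (residues 1-102 and 108-200 plus a
#' 103-107 interdomain linker) whose long domain axes meet at exactly the
#' requested hinge angle, elbow positioned over the peptide C-terminal
#' half. Every residue carries a C-alpha and a dummy C-beta.
#'
#' @param hinge_deg Hinge angle in degrees, in (5, 175).
#' @param seed Integer RNG seed.
#' @param path Optional output path; if given, the complex is written as a
#'   PDB file (with a JSON truth manifest alongside, `<path>.truth.json`).
#' @return List with `model` (a `complex_model`), `structure`
#'   (`kir_structure`) and `truth` (named list of the generating
#'   parameters, including the groove axis and domain axes).
#' @export
make_two_domain_complex <- function(hinge_deg, seed = 0L, path = NULL) {
  if (!(hinge_deg > 5 && hinge_deg < 175)) {
    kd_stop("hinge angle must lie in (5, 175) degrees", "kirdock_config_error")
  }
  platform <- make_rigid_body(180L, c(20, 10, 5), sub_seed(seed, 1),
                              chain = "A")
  b2m <- translate_cs(make_rigid_body(99L, c(8, 5, 3), sub_seed(seed, 2),
                                      chain = "B"), c(0, 0, -12))
  pep_x <- seq(-12.8, 12.8, length.out = 9)
  pep <- new_coordset(
    data.frame(chain = "C", resno = 1:9, insert = "", resid = "ALA",
               elety = "CA", elesy = "C", stringsAsFactors = FALSE),
    cbind(pep_x, 0, 6.2))
  h <- hinge_deg * pi / 180
  u1 <- c(sin(h / 2), 0, cos(h / 2))
  u2 <- c(-sin(h / 2), 0, cos(h / 2))
  elbow <- c(6, 0, 11)
  # The middle (hinge) axis is the projection of the platform normal onto
  # the plane perpendicular to the long axis: this maximises its component
  # along the platform-to-receptor direction, keeping the e2 sign
  # convention stable under the twist perturbations the generator supports.
  orient <- function(u) {
    w <- c(0, 0, 1) - u[3] * u
    w <- w / sqrt(sum(w^2))
    cbind(u, w, cross3(u, w))
  }
  d1 <- make_rigid_body(102L, c(12, 6, 3), sub_seed(seed, 3), chain = "D")
  d1 <- translate_cs(rotate_cs(d1, orient(u1)), elbow + 9 * u1)
  d2 <- make_rigid_body(93L, c(12, 6, 3), sub_seed(seed, 4), chain = "D",
                        resno_start = 108L)
  d2 <- translate_cs(rotate_cs(d2, orient(u2)), elbow + 9 * u2)
  t_link <- seq(0, 1, length.out = 5)
  link_xyz <- outer(1 - t_link, elbow + 2.5 * u1) + outer(t_link, elbow + 2.5 * u2)
  link <- new_coordset(
    data.frame(chain = "D", resno = 103:107, insert = "", resid = "GLY",
               elety = "CA", elesy = "C", stringsAsFactors = FALSE),
    link_xyz)
  atoms <- rbind(body_atoms(platform), body_atoms(b2m), body_atoms(pep),
                 body_atoms(d1), body_atoms(link), body_atoms(d2))
  rownames(atoms) <- NULL
  struct <- new_kir_structure(atoms, title = sprintf("synthetic hinge %.1f",
                                                     hinge_deg))
  model <- build_complex_model(struct,
                               chains = list(hla = "A", b2m = "B",
                                             peptide = "C", kir = "D"))
  truth <- list(kind = "two_domain_complex", seed = seed,
                hinge_deg = hinge_deg, groove_axis = c(1, 0, 0),
                elbow = elbow, d1_axis = u1, d2_axis = u2,
                chains = list(hla = "A", b2m = "B", peptide = "C", kir = "D"))
  if (!is.null(path)) {
    write_structure(struct, path)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, structure = struct, truth = truth)
}

#' Perturb the docking geometry of a synthetic complex with known truth
#'
#' Rigidly rotates each receptor domain about its own twist axis (`e3`,
#' through the domain C-alpha centroid) by the requested angle, translates
#' the whole receptor along the groove axis, and adds isotropic Gaussian
#' coordinate noise to every atom of the complex. The generating values are
#' recorded as truth, making this the ground-truth source for twist and
#' centre-of-mass-shift recovery tests.
#'
#' @param complex Output of [make_two_domain_complex()].
#' @param twist_d1_deg,twist_d2_deg Domain twists in degrees, |angle| < 90.
#' @param com_shift Receptor translation along the groove axis (Angstrom).
#' @param noise_sd Gaussian noise standard deviation per coordinate
#'   (Angstrom).
#' @param seed Integer RNG seed (noise only).
#' @return List with `model`, `structure` and `truth`.
#' @export
perturb_docking <- function(complex, twist_d1_deg = 0, twist_d2_deg = 0,
                            com_shift = 0, noise_sd = 0, seed = 0L) {
  stopifnot(is.list(complex), inherits(complex$model, "complex_model"))
  if (abs(twist_d1_deg) >= 90 || abs(twist_d2_deg) >= 90) {
    kd_stop("|twist| must be < 90 degrees (small-perturbation regime)",
            "kirdock_config_error")
  }
  model <- complex$model
  at <- model$structure$atoms
  kirc <- model$chains$kir
  for (dom in c("d1", "d2")) {
    ang <- if (dom == "d1") twist_d1_deg else twist_d2_deg
    if (ang == 0) next
    rng <- if (dom == "d1") model$d1_range else model$d2_range
    axis <- domain_frame_of(model, dom)$axes[, "e3"]
    ctr <- colMeans(model_part(model, dom)$xyz)
    R <- rotation_about_axis(axis, ang)
    idx <- at$chain == kirc & at$resno >= rng[1] & at$resno <= rng[2]
    xyz <- as.matrix(at[idx, c("x", "y", "z")])
    at[idx, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, -ctr)
  }
  if (com_shift != 0) {
    pep <- model_part(model, "peptide")
    g <- pep$xyz[nrow(pep$xyz), ] - pep$xyz[1, ]
    g <- g / sqrt(sum(g^2))
    idx <- at$chain == kirc
    at[idx, c("x", "y", "z")] <- sweep(as.matrix(at[idx, c("x", "y", "z")]),
                                       2, -com_shift * g)
  }
  if (noise_sd > 0) {
    at[, c("x", "y", "z")] <- as.matrix(at[, c("x", "y", "z")]) +
      with_seed(sub_seed(seed, 5),
                matrix(stats::rnorm(3L * nrow(at), sd = noise_sd),
                       ncol = 3))
  }
  struct <- new_kir_structure(at, title = "synthetic perturbed")
  newmodel <- build_complex_model(struct, chains = model$chains,
                                  d1_range = model$d1_range,
                                  d2_range = model$d2_range,
                                  interdomain_range = model$interdomain_range,
                                  platform_range = model$platform_range,
                                  loops = model$loops,
                                  hla_elements = model$hla_elements)
  truth <- utils::modifyList(complex$truth, list(
    kind = "perturbed_complex", twist_d1_deg = twist_d1_deg,
    twist_d2_deg = twist_d2_deg, com_shift = com_shift,
    noise_sd = noise_sd, noise_seed = seed))
  list(model = newmodel, structure = struct, truth = truth)
}

#' Generate steady-state binding series and a bead panel with known truth
#'
#' Equilibrium responses follow the 1:1 Langmuir isotherm
#' `Req = Rmax C / (KD + C)` with multiplicative Gaussian noise, measured
#' over duplicate injections of a twofold dilution series (default
#' 0-50 micromolar, emulating a typical steady-state surface plasmon
#' resonance design). The bead panel carries sample/background channel
#' values constructed so the background-corrected normalization recovers a
#' known specific signal exactly.
#'
#' @param kd_list Named or unnamed numeric vector of true KD values (uM).
#' @param rmax True maximal response (RU; default 100).
#' @param conc Concentration series (uM; default `c(0, 50 / 2^(7:0))`).
#' @param noise_frac Multiplicative noise SD (default 0).
#' @param seed Integer RNG seed.
#' @param n_injections Replicate injections per series (default 2).
#' @param n_beads Beads in the synthetic panel (default 12).
#' @return List with `series` (list of data frames `conc`, `response`,
#'   `injection`, one per KD), `beads` (data frame `bead`, `s_n`, `snc`,
#'   `bg_n`, `bgnc`, `true_signal`) and `truth`.
#' @export
make_binding_datasets <- function(kd_list, rmax = 100,
                                  conc = c(0, 50 / 2^(7:0)),
                                  noise_frac = 0, seed = 0L,
                                  n_injections = 2L, n_beads = 12L) {
  stopifnot(all(kd_list > 0), all(conc >= 0))
  series <- lapply(seq_along(kd_list), function(i) {
    kd <- kd_list[i]
    cc <- rep(conc, n_injections)
    mu <- rmax * cc / (kd + cc)
    eps <- if (noise_frac > 0) {
      with_seed(sub_seed(seed, 10 + i),
                stats::rnorm(length(cc), sd = noise_frac))
    } else rep(0, length(cc))
    data.frame(conc = cc, response = mu * (1 + eps),
               injection = rep(seq_len(n_injections), each = length(conc)))
  })
  names(series) <- if (!is.null(names(kd_list))) names(kd_list) else
    paste0("kd_", signif(kd_list, 3))
  beads <- with_seed(sub_seed(seed, 99), {
    true_signal <- stats::runif(n_beads, 0, 5000)
    snc <- stats::runif(1, 50, 200)
    bgnc <- stats::runif(1, 20, 100)
    bg_n <- stats::runif(n_beads, 20, 300)
    data.frame(bead = seq_len(n_beads),
               s_n = true_signal + snc + (bg_n - bgnc),
               snc = snc, bg_n = bg_n, bgnc = bgnc,
               true_signal = true_signal)
  })
  list(series = series, beads = beads,
       truth = list(kind = "binding_datasets", kd = unname(kd_list),
                    rmax = rmax, conc = conc, noise_frac = noise_frac,
                    seed = seed))
}
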