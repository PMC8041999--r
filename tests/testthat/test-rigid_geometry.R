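test_that("kabsch superposition is exact on identity and recovers constructions", {
  set.seed(11)
  X <- matrix(rnorm(150, sd = 8), ncol = 3)
  id <- kabsch_superpose(X, X)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$transform$R, diag(3), tolerance = 1e-10)
  expect_equal(id$transform$t, c(0, 0, 0), tolerance = 1e-10)
  for (i in 1:25) {
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    Y <- sweep(X %*% t(R), 2, -t)
    fit <- kabsch_superpose(X, Y)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(fit$transform$R, R, tolerance = 1e-8)
    expect_equal(fit$transform$t, t, tolerance = 1e-7)
    expect_equal(apply_transform(X, fit$transform), Y, tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(X, X[1:10, ]), class = "kirdock_config_error")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]),
               class = "kirdock_config_error")
})

test_that("kabsch agrees with an established superposition routine", {
  set.seed(7)
  X <- matrix(rnorm(120, sd = 10), ncol = 3)
  Y <- X %*% t(random_rotation()) + matrix(rnorm(120, sd = 0.6), ncol = 3)
  ours <- kabsch_superpose(X, Y)
  theirs <- suppressWarnings(    # bio3d reports which indices it fits
    bio3d::fit.xyz(fixed = as.vector(t(Y)), mobile = as.vector(t(X))))
  rmsd_bio3d <- sqrt(mean(colSums(matrix(theirs - as.vector(t(Y)), 3)^2)))
  expect_equal(ours$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("kabsch never returns a reflection, even for planar point sets", {
  set.seed(5)
  X <- cbind(rnorm(60, sd = 10), rnorm(60, sd = 4), 0)   # exactly planar
  Y <- X %*% t(rotation_about_axis(c(0, 0, 1), 40))
  Y[, 3] <- -Y[, 3] * 0                                  # still planar
  fit <- kabsch_superpose(X, Y)
  expect_equal(det(fit$transform$R), 1, tolerance = 1e-9)
  # mirrored target: best proper fit is still a rotation, never det = -1
  fit2 <- kabsch_superpose(X, cbind(-X[, 1], X[, 2], X[, 3]))
  expect_equal(det(fit2$transform$R), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd is invariant under a common rigid motion", {
  set.seed(3)
  X <- matrix(rnorm(90, sd = 6), ncol = 3)
  Y <- X + matrix(rnorm(90, sd = 0.5), ncol = 3)
  base <- kabsch_superpose(X, Y)$rmsd
  R <- random_rotation(); t <- rnorm(3, sd = 30)
  moved <- kabsch_superpose(sweep(X %*% t(R), 2, -t),
                            sweep(Y %*% t(R), 2, -t))$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("principal frames match constructed axes and obey sign rules", {
  # near-linear cloud along x: e1 must be +x (residues ordered along +x)
  x <- seq(-10, 10, length.out = 60)
  cloud <- cbind(x, 0.4 * sin(seq_len(60)), 0.1 * cos(seq_len(60) * 2))
  fr <- principal_frame(cloud)
  expect_gt(abs(sum(fr$axes[, "e1"] * c(1, 0, 0))), cos(2 * pi / 180))
  expect_gt(sum(fr$axes[, "e1"] * c(1, 0, 0)), 0)
  # constructed ellipsoid axes recovered within 1 degree
  body <- make_rigid_body(200, c(10, 5, 2), seed = 4)
  fr2 <- principal_frame(body)
  expect_gt(sum(fr2$axes[, "e1"] * c(1, 0, 0)), cos(pi / 180))
  expect_gt(abs(sum(fr2$axes[, "e2"] * c(0, 1, 0))), cos(pi / 180))
  # right-handedness
  expect_equal(kirdock:::cross3(fr2$axes[, "e1"], fr2$axes[, "e2"]),
               unname(fr2$axes[, "e3"]), tolerance = 1e-12)
})

test_that("principal frames are equivariant under rotation, invariant under translation", {
  body <- make_rigid_body(150, c(12, 6, 3), seed = 9)
  fr <- principal_frame(body)
  R <- random_rotation(); t <- c(5, -40, 12)
  moved <- kirdock:::new_coordset(body$labels,
                                  sweep(body$xyz %*% t(R), 2, -t))
  fr2 <- principal_frame(moved, up = as.numeric(R %*% c(0, 0, 1)))
  expect_equal(unname(fr2$axes), unname(R %*% fr$axes), tolerance = 1e-9)
  expect_equal(fr2$centroid, as.numeric(R %*% fr$centroid + t),
               tolerance = 1e-9)
  expect_equal(fr2$evals, fr$evals, tolerance = 1e-9)
})

test_that("degenerate anisotropy raises a classed error", {
  octa <- rbind(diag(3), -diag(3)) * 5         # exactly isotropic covariance
  expect_error(principal_frame(octa), class = "kirdock_degenerate_frame")
  expect_error(principal_frame(matrix(rnorm(9), 3)),
               class = "kirdock_config_error")
})

test_that("swing-twist separates pure twist, pure swing, and compositions", {
  a <- c(0, 0, 1)
  st <- swing_twist(rotation_about_axis(a, 25), a)
  expect_equal(st$twist_deg, 25, tolerance = 1e-9)
  expect_equal(st$swing, diag(3), tolerance = 1e-9)
  perp <- c(1, 0, 0)
  st2 <- swing_twist(rotation_about_axis(perp, 25), a)
  expect_equal(st2$twist_deg, 0, tolerance = 1e-9)
  R <- rotation_about_axis(perp, 5) %*% rotation_about_axis(a, 10)
  st3 <- swing_twist(R, a)
  expect_equal(st3$twist_deg, 10, tolerance = 1e-6)
  expect_equal(st3$swing %*% st3$twist, R, tolerance = 1e-9)
  # swing axis is perpendicular to the twist axis
  qs <- kirdock:::rotation_to_quaternion(st3$swing)
  expect_lt(abs(sum(qs[2:4] * a)), 1e-9)
  expect_error(swing_twist(diag(c(1, 1, -1)), a),
               class = "kirdock_config_error")
})

test_that("twist about the full rotation axis equals the rotation angle", {
  set.seed(21)
  for (i in 1:50) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -170, 170)
    st <- swing_twist(rotation_about_axis(ax, ang), ax)
    expect_equal(st$twist_deg, ang, tolerance = 1e-8)
  }
})

test_that("transforms compose, invert, and preserve distances", {
  set.seed(2)
  X <- matrix(rnorm(60, sd = 5), ncol = 3)
  tf <- kirdock:::new_rigid_transform(random_rotation(), rnorm(3, sd = 10))
  Y <- apply_transform(X, tf)
  expect_equal(as.numeric(dist(Y)), as.numeric(dist(X)), tolerance = 1e-9)
  back <- apply_transform(Y, invert_transform(tf))
  expect_equal(back, X, tolerance = 1e-9)
  expect_length(transform_to_vector(tf), 12L)
})
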