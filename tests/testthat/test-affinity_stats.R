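test_that("bead normalization evaluates the background-corrected formula", {
  expect_equal(as.numeric(normalize_bead_mfi(1000, 100, 200, 50)), 750)
  expect_equal(as.numeric(normalize_bead_mfi(300, 300, 120, 120)), 0)
  # affine equivariance: shifting sample and background channels together
  # leaves the result unchanged
  base <- normalize_bead_mfi(850, 90, 140, 60)
  shifted <- normalize_bead_mfi(850 + 37, 90, 140 + 37, 60)
  expect_equal(as.numeric(shifted), as.numeric(base))
  # negative specific signals are retained and flagged
  neg <- normalize_bead_mfi(100, 200, 50, 40)
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "negative"))
  expect_error(normalize_bead_mfi(NA, 1, 1, 1), class = "kirdock_config_error")
  # arithmetic oracle over random tuples
  set.seed(14)
  v <- matrix(runif(4000, 0, 5000), ncol = 4)
  expect_equal(as.numeric(normalize_bead_mfi(v[, 1], v[, 2], v[, 3], v[, 4])),
               (v[, 1] - v[, 2]) - (v[, 3] - v[, 4]))
})

test_that("percent-of-max normalizes within replicates then averages", {
  expect_equal(unname(percent_of_max(matrix(c(2, 4, 8)))), c(25, 50, 100))
  two <- cbind(r1 = c(a = 10, b = 5), r2 = c(a = 40, b = 30))
  # by hand: a -> (100 + 100)/2, b -> (50 + 75)/2
  expect_equal(percent_of_max(two), c(a = 100, b = 62.5))
  # allotype achieving the max in every replicate is exactly 100
  expect_equal(unname(percent_of_max(two)["a"]), 100)
  # scale invariance per replicate; bounded by (0, 100]
  set.seed(15)
  m <- matrix(runif(30, 1, 1000), ncol = 3)
  scaled <- sweep(m, 2, c(2, 0.5, 10), "*")
  expect_equal(percent_of_max(scaled), percent_of_max(m))
  expect_true(all(percent_of_max(m) > 0 & percent_of_max(m) <= 100))
  expect_error(percent_of_max(cbind(c(0, 0), c(1, 2))),
               class = "kirdock_config_error")
})

test_that("tetramer staining is normalized by FLAG and by wild type", {
  expect_equal(normalize_tetramer(30, 60, 30, 60), 1)
  expect_equal(normalize_tetramer(20, 40, 40, 40), 0.5)
  expect_error(normalize_tetramer(20, 0, 40, 40), class = "kirdock_config_error")
  set.seed(16)
  tet <- runif(200, 1, 80); flag <- runif(200, 10, 90)
  wt_t <- 45; wt_f <- 60
  expect_equal(normalize_tetramer(tet, flag, wt_t, wt_f),
               (tet / flag) / (wt_t / wt_f))
})

test_that("steady-state KD fitting recovers the isotherm", {
  conc <- c(0, 50 / 2^(7:0))
  resp <- 100 * conc / (5 + conc)
  fit <- steady_state_kd(conc, resp)
  expect_true(fit$converged)
  expect_equal(fit$kd, 5, tolerance = 0.01)
  expect_equal(fit$rmax, 100, tolerance = 0.01)
  # KD and Rmax jointly recovered across a concentration sweep
  for (kd in c(1, 5, 25)) {
    f <- steady_state_kd(conc, 80 * conc / (kd + conc))
    expect_equal(f$kd, kd, tolerance = 1e-4)
    expect_equal(f$rmax, 80, tolerance = 1e-3)
  }
  expect_error(steady_state_kd(c(0, 1, 1, 1), c(0, 1, 1, 1)),
               class = "kirdock_config_error")
})

test_that("no-signal series reports non-convergence rather than crashing", {
  conc <- c(0, 50 / 2^(7:0))
  fit <- steady_state_kd(conc, rep(0, length(conc)))
  expect_false(fit$converged)
  expect_true(is.na(fit$kd))
})

test_that("truncated concentration ranges degrade KD identifiability", {
  kd <- 5
  full <- c(0, 50 / 2^(7:0))
  capped <- c(0, kd / 40, kd / 20, kd / 10)   # all far below KD
  noisy <- function(conc, seed) {
    set.seed(seed)
    100 * conc / (kd + conc) * (1 + rnorm(length(conc), sd = 0.02))
  }
  f_full <- steady_state_kd(rep(full, 2), noisy(rep(full, 2), 31))
  f_capped <- steady_state_kd(rep(capped, 2), noisy(rep(capped, 2), 31))
  rel <- function(f) f$sd / f$kd
  expect_true(!f_capped$converged || rel(f_capped) > 5 * rel(f_full))
})

test_that("summary-statistic t-tests match the textbook formula and t.test", {
  same <- two_sample_t(10, 1, 3, 10, 1, 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(two_sample_t(5, 0, 2, 5, 0, 2)$p_value, 1)
  expect_equal(two_sample_t(5, 0, 2, 7, 0, 2)$p_value, 0)
  # reported affinity difference for the P8G peptide variant
  p8g <- two_sample_t(18.9, 0.7, 2, 11.7, 0.8, 2)
  expect_equal(round(p8g$p_value, 2), 0.01)
  # random summary inputs vs the independent formula, pooled and Welch
  set.seed(17)
  for (i in 1:250) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.1, 3); s2 <- runif(1, 0.1, 3)
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    expect_equal(two_sample_t(m1, s1, n1, m2, s2, n2)$p_value,
                 oracle_t_p(m1, s1, n1, m2, s2, n2), tolerance = 1e-12)
    expect_equal(two_sample_t(m1, s1, n1, m2, s2, n2, pooled = FALSE)$p_value,
                 oracle_t_p(m1, s1, n1, m2, s2, n2, pooled = FALSE),
                 tolerance = 1e-12)
  }
  # Welch route against stats::t.test on raw data
  x <- rnorm(8, 1, 2); y <- rnorm(6, 0, 1)
  ours <- two_sample_t(mean(x), sd(x), 8, mean(y), sd(y), 6, pooled = FALSE)
  expect_equal(ours$p_value, t.test(x, y)$p.value, tolerance = 1e-12)
  ours_pooled <- two_sample_t(mean(x), sd(x), 8, mean(y), sd(y), 6)
  expect_equal(ours_pooled$p_value,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
})

test_that("two-stage FDR matches an independent step-up implementation", {
  all_null <- bky_fdr(rep(1, 6), Q = 0.05)
  expect_equal(sum(all_null$discoveries), 0L)
  expect_equal(all_null$q_values, rep(1, 6))
  set.seed(18)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    p <- if (runif(1) < 0.5) runif(m) else c(runif(ceiling(m / 2), 0, 0.01),
                                             runif(floor(m / 2)))
    Q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(bky_fdr(p, Q, q_values = FALSE)$discoveries,
                     oracle_bky_discoveries(p, Q))
  }
  expect_error(bky_fdr(numeric(0), 0.05), class = "kirdock_config_error")
  expect_error(bky_fdr(c(0.5, 1.2), 0.05), class = "kirdock_config_error")
})

test_that("FDR discoveries are monotone in Q and q-values are thresholds", {
  set.seed(19)
  p <- c(runif(4, 0, 0.02), runif(8))
  grid <- seq(0.005, 0.5, by = 0.005)
  counts <- vapply(grid, function(q)
    sum(bky_fdr(p, q, q_values = FALSE)$discoveries), numeric(1))
  expect_true(all(diff(counts) >= 0))
  res <- bky_fdr(p, Q = 0.05)
  # a test is a discovery at Q exactly when its q-value is <= Q
  expect_identical(res$discoveries, res$q_values <= 0.05 + 1e-9)
})

test_that("the published peptide-panel p-values give no discoveries at Q = 1%", {
  panel <- kir_affinity_panel()
  expect_equal(nrow(panel), 13L)
  determined <- panel[!is.na(panel$p_reported), ]
  expect_equal(nrow(determined), 11L)
  res <- bky_fdr(determined$p_reported, Q = 0.01)
  expect_equal(sum(res$discoveries), 0L)
  # recomputing the pooled t-tests from the printed summary statistics
  # reproduces the P8G row and still yields no discoveries at Q = 1%
  p_re <- mapply(function(m1, s1, m2, s2)
    two_sample_t(m1, s1, 2, m2, s2, 2)$p_value,
    determined$kd_2dl2, determined$sd_2dl2,
    determined$kd_2dl3, determined$sd_2dl3)
  expect_equal(round(p_re[determined$peptide == "P8G"], 2), 0.01,
               ignore_attr = TRUE)
  expect_equal(sum(bky_fdr(p_re, Q = 0.01)$discoveries), 0L)
  # reported q-values and recomputed q-values rank the comparisons alike
  # (ties in the printed column make exact order comparison meaningless)
  expect_gt(cor(res$q_values, determined$q_reported, method = "spearman"),
            0.95)
})
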