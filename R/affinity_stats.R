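# Binding-data computations: single-antigen-bead fluorescence
# normalization, percent-of-maximum panels, tetramer/FLAG normalization,
# steady-state 1:1 KD fitting, summary-statistic t-tests, and the
# Benjamini-Krieger-Yekutieli two-stage step-up FDR procedure.

#' Normalize single-antigen-bead fluorescence
#'
#' Background-corrected bead fluorescence:
#' `(S#N - SNC) - (BG#N - BGNC)`, where `S#N` is the sample-specific
#' trimmed-mean fluorescence for bead N, `SNC` the sample value for the
#' negative-control (nude) bead, `BG#N` the background (isotype-control)
#' value for bead N, and `BGNC` the background value for the
#' negative-control bead. Negative results are retained (flagged via the
#' `"negative"` attribute), not clamped.
#'
#' @param s_n,snc,bg_n,bgnc Numeric vectors (recycled) of the four channels.
#' @return Numeric vector of normalized fluorescence values, with attribute
#'   `negative` marking values below zero.
#' @export
normalize_bead_mfi <- function(s_n, snc, bg_n, bgnc) {
  vals <- cbind(s_n, snc, bg_n, bgnc)
  if (any(!is.finite(vals))) {
    kd_stop("bead fluorescence inputs must be finite", "kirdock_config_error")
  }
  out <- (vals[, 1] - vals[, 2]) - (vals[, 3] - vals[, 4])
  attr(out, "negative") <- out < 0
  out
}

#' Percent-of-maximum normalization of a binding panel
#'
#' Within each replicate (experiment), values are divided by that
#' replicate's maximum and scaled to percent; the per-allotype percentages
#' are then averaged across replicates.
#'
#' @param panel Numeric matrix (or data frame) with one row per allotype
#'   and one column per replicate; row names identify allotypes.
#' @return Named numeric vector: mean percent-of-maximum per allotype.
#' @export
percent_of_max <- function(panel) {
  m <- as.matrix(panel)
  stopifnot(ncol(m) >= 1L, nrow(m) >= 1L)
  maxima <- apply(m, 2, max)
  if (any(!is.finite(maxima)) || any(maxima <= 0)) {
    kd_stop("each replicate must have a positive maximum",
            "kirdock_config_error")
  }
  pct <- sweep(m, 2, maxima, "/") * 100
  rowMeans(pct)
}

#' Tetramer staining normalized to surface expression and wild type
#'
#' The fraction of tetramer-positive cells is divided by the fraction of
#' FLAG-positive cells (correcting for transfection efficiency) and the
#' resulting ratio normalized to the same ratio for the wild-type receptor.
#'
#' @param pct_tetramer,pct_flag Percent tetramer+ and percent FLAG+ for the
#'   mutant (vectors recycled together).
#' @param wt_tetramer,wt_flag The same quantities for wild type.
#' @return Relative binding (1 = wild-type-like).
#' @export
normalize_tetramer <- function(pct_tetramer, pct_flag, wt_tetramer, wt_flag) {
  if (any(pct_flag <= 0) || any(wt_flag <= 0)) {
    kd_stop("FLAG-positive percentage must be positive", "kirdock_config_error")
  }
  (pct_tetramer / pct_flag) / (wt_tetramer / wt_flag)
}

#' Fit a steady-state 1:1 binding isotherm
#'
#' Nonlinear least-squares fit of the Langmuir steady-state model
#' `Req(C) = Rmax * C / (KD + C)` to an equilibrium-response series, with
#' positive-bounded parameters. Initial values: `Rmax0` = maximum response,
#' `KD0` = concentration at half-maximal response (interpolated).
#'
#' @param conc Analyte concentrations (micromolar), at least 4 distinct.
#' @param response Equilibrium responses (RU), same length.
#' @return A `kd_fit`: list with `kd` (uM), `rmax` (RU), `sd` (standard
#'   deviation of the KD estimate from the fit covariance), `rss`,
#'   `converged` (logical) and `fit` (the `nls` object or `NULL`).
#' @export
steady_state_kd <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (any(conc < 0)) kd_stop("concentrations must be non-negative",
                             "kirdock_config_error")
  if (length(unique(conc)) < 4L) {
    kd_stop("need at least 4 distinct concentrations", "kirdock_config_error")
  }
  failed <- function() {
    structure(list(kd = NA_real_, rmax = NA_real_, sd = NA_real_,
                   rss = NA_real_, converged = FALSE, fit = NULL),
              class = "kd_fit")
  }
  rmax0 <- max(response)
  if (!is.finite(rmax0) || rmax0 <= 0) return(failed())
  half <- rmax0 / 2
  above <- conc[response >= half]
  kd0 <- if (length(above)) max(min(above), 1e-3) else max(conc) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ rmax * conc / (kd + conc),
                      start = list(rmax = rmax0, kd = kd0),
                      lower = c(rmax = 1e-9, kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  sd_kd <- sqrt(vc["kd", "kd"])
  conv <- isTRUE(fit$convInfo$isConv) && est["kd"] > 1e-8 && est["rmax"] > 1e-8
  structure(list(kd = unname(est["kd"]), rmax = unname(est["rmax"]),
                 sd = unname(sd_kd),
                 rss = sum(stats::resid(fit)^2), converged = conv, fit = fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("<kd_fit> KD = %.3g uM (SD %.2g), Rmax = %.3g RU\n",
                x$kd, x$sd, x$rmax))
  } else {
    cat("<kd_fit> not converged\n")
  }
  invisible(x)
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Classic pooled-variance unpaired t-test (default) or Welch's unequal-
#' variance variant, computed from group means, standard deviations and
#' sizes; two-sided p-value. With zero variance in both groups the p-value
#' is 1 for equal means and 0 in the unequal-mean limit.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics; `n1`, `n2`
#'   at least 2.
#' @param pooled Pooled-variance test if `TRUE` (default), Welch otherwise.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = TRUE) {
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    return(list(statistic = if (diff == 0) 0 else sign(diff) * Inf,
                df = n1 + n2 - 2,
                p_value = if (diff == 0) 1 else 0))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- diff / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# Benjamini-Hochberg step-up rejection count at level alpha.
bh_stepup <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok)) max(ok) else 0L
}

#' Two-stage step-up false discovery rate procedure
#'
#' The adaptive Benjamini-Krieger-Yekutieli procedure: a first-stage
#' Benjamini-Hochberg step-up at level `Q / (1 + Q)` estimates the number
#' of true nulls `m0 = m - r1`; a second-stage step-up at level
#' `Q * m / m0` yields the discoveries. Per-test q-values are the smallest
#' `Q` at which the test would be a discovery (found by bisection, using
#' the monotonicity of the procedure in `Q`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param Q Desired false discovery rate, in `(0, 1)`.
#' @param q_values Compute per-test q-values (default `TRUE`; disable in
#'   large simulations where only the discovery flags are needed).
#' @return An `fdr_result`: list with `p_values`, `q_values` (or `NULL`),
#'   `discoveries` (logical), `Q`, `m0` and `stage1_rejections`.
#' @export
bky_fdr <- function(p_values, Q = 0.05, q_values = TRUE) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) kd_stop("empty p-value vector", "kirdock_config_error")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    kd_stop("p-values must lie in [0, 1]", "kirdock_config_error")
  }
  stopifnot(Q > 0, Q < 1)
  m <- length(p)
  discover_at <- function(q) {
    r1 <- bh_stepup(p, q / (1 + q))
    m0 <- m - r1
    if (m0 == 0L) return(rep(TRUE, m))
    r2 <- bh_stepup(p, q * m / m0)
    if (r2 == 0L) return(rep(FALSE, m))
    thr <- sort(p)[r2]
    p <= thr
  }
  disc <- discover_at(Q)
  qv <- if (q_values) {
    pmin(vapply(seq_len(m), function(i) {
      lo <- 1e-8; hi <- 1 - 1e-8
      if (!discover_at(hi)[i]) return(1)
      for (iter in 1:50) {
        mid <- (lo + hi) / 2
        if (discover_at(mid)[i]) hi <- mid else lo <- mid
      }
      hi
    }, numeric(1)), 1)
  } else NULL
  r1 <- bh_stepup(p, Q / (1 + Q))
  structure(list(p_values = p, q_values = qv,
                 discoveries = disc, Q = Q, m0 = m - r1,
                 stage1_rejections = r1),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> %d tests, Q = %g: %d discoveries (m0 = %d)\n",
              length(x$p_values), x$Q, sum(x$discoveries), x$m0))
  invisible(x)
}

#' Published steady-state affinity panel for the RL9 peptide variants
#'
#' The reported steady-state dissociation constants (micromolar, mean and
#' SD of n = 2 injections) of KIR2DL2 and KIR2DL3 binding HLA-C*07:02
#' presenting the RL9 self-peptide and twelve P7/P8 substitutions, with the
#' reported per-comparison p and q values. Rows with undetermined binding
#' carry `NA`.
#'
#' @return Data frame with columns `peptide`, `kd_2dl2`, `sd_2dl2`,
#'   `kd_2dl3`, `sd_2dl3`, `n`, `p_reported`, `q_reported`.
#' @export
kir_affinity_panel <- function() {
  path <- system.file("extdata", "kir2dl2_2dl3_rl9_panel_kd.tsv",
                      package = "kirdock", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
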