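# Orchestration: configuration-driven runs producing machine-readable
# geometry and affinity reports. No logic lives here that is not a direct
# call into the analysis functions, so reports always equal library output.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) kd_stop(sprintf("config file '%s' not found",
                                              config), "kirdock_io_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) kd_stop("config must be a list or a YAML file path",
                                "kirdock_config_error")
  config
}

model_from_config <- function(entry) {
  if (is.null(entry$path)) kd_stop("config entry lacks a structure 'path'",
                                   "kirdock_config_error")
  roles <- entry$chains
  need <- c("hla", "b2m", "peptide", "kir")
  if (is.null(roles) || !all(need %in% names(roles))) {
    kd_stop(sprintf("config entry for '%s' must map chain roles %s",
                    entry$path, paste(need, collapse = ", ")),
            "kirdock_config_error")
  }
  struct <- parse_structure(entry$path,
                            dialect = if (is.null(entry$dialect)) "auto"
                                      else entry$dialect)
  args <- list(structure = struct, chains = roles)
  for (f in c("d1_range", "d2_range", "interdomain_range", "platform_range")) {
    if (!is.null(entry[[f]])) args[[f]] <- entry[[f]]
  }
  do.call(build_complex_model, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full docking-geometry comparison from a configuration
#'
#' Loads the reference and comparison complexes, computes the geometry
#' comparison, contacts, footprints and buried surface areas, and writes
#' deterministic TSV/JSON reports: `geometry.json`, `geometry.tsv`,
#' `contacts_ref.tsv` / `contacts_cmp.tsv`, `footprint_ref.tsv` /
#' `footprint_cmp.tsv` and `bsa.json`.
#'
#' @param config A list or YAML file path with entries `ref` and `cmp`
#'   (each: `path`, `chains` role map, optional residue ranges), `out_dir`,
#'   and optional `cutoff` (default 4.0) and `include_b2m` (default TRUE).
#' @return Invisibly, a list with the `geometry_comparison` and the output
#'   file paths.
#' @export
run_geometry <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$ref) || is.null(config$cmp)) {
    kd_stop("config must provide 'ref' and 'cmp' entries",
            "kirdock_config_error")
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) kd_stop("config must provide 'out_dir'",
                                "kirdock_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cutoff <- if (is.null(config$cutoff)) 4.0 else config$cutoff
  include_b2m <- if (is.null(config$include_b2m)) TRUE else config$include_b2m
  ref <- model_from_config(config$ref)
  cmp <- model_from_config(config$cmp)
  gc <- compare_complexes(ref, cmp)
  files <- c(geometry_json = file.path(out_dir, "geometry.json"),
             geometry_tsv = file.path(out_dir, "geometry.tsv"),
             bsa_json = file.path(out_dir, "bsa.json"))
  jsonlite::write_json(unclass(gc), files["geometry_json"],
                       auto_unbox = TRUE, digits = NA)
  write_tsv(as.data.frame(gc), files["geometry_tsv"])
  bsa <- list()
  for (side in c("ref", "cmp")) {
    model <- if (side == "ref") ref else cmp
    contacts <- find_contacts(model, cutoff = cutoff)
    b <- buried_surface_area(model, include_b2m = include_b2m)
    fp <- classify_footprint(contacts, model, bsa = b)
    f1 <- write_tsv(contacts, file.path(out_dir,
                                        sprintf("contacts_%s.tsv", side)))
    f2 <- write_tsv(fp$regions, file.path(out_dir,
                                          sprintf("footprint_%s.tsv", side)))
    files[paste0("contacts_", side)] <- f1
    files[paste0("footprint_", side)] <- f2
    bsa[[side]] <- list(bsa = b$bsa, receptor_side = b$bsa_side_a,
                        ligand_side = b$bsa_side_b,
                        include_b2m = include_b2m,
                        probe = b$probe, sample_points = b$sample_points)
  }
  jsonlite::write_json(bsa, files["bsa_json"], auto_unbox = TRUE, digits = NA)
  invisible(list(comparison = gc, files = files))
}

#' Run the affinity-statistics pipeline from a configuration
#'
#' Any combination of: steady-state KD fitting of response series
#' (`series_tsv`: columns `series`, `conc`, `response`), summary-statistic
#' t-tests (`ttest_tsv`: columns `label`, `mean1`, `sd1`, `n1`, `mean2`,
#' `sd2`, `n2`), and two-stage step-up FDR over p-values (`pvalues_tsv`:
#' columns `label`, `p`; or the p-values produced by the t-test step when
#' `ttest_tsv` is given and `pvalues_tsv` is not). Writes `kd_fits.tsv`,
#' `tests.tsv` and `fdr.json` as applicable.
#'
#' @param config A list or YAML file path with `out_dir`, optional
#'   `series_tsv`, `ttest_tsv`, `pvalues_tsv`, `Q` (default 0.01) and
#'   `pooled` (default TRUE).
#' @return Invisibly, a list of computed tables and output paths.
#' @export
run_affinity <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) kd_stop("config must provide 'out_dir'",
                                "kirdock_config_error")
  if (is.null(config$series_tsv) && is.null(config$ttest_tsv) &&
      is.null(config$pvalues_tsv)) {
    kd_stop("config must provide at least one of series_tsv, ttest_tsv, pvalues_tsv",
            "kirdock_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Q <- if (is.null(config$Q)) 0.01 else config$Q
  pooled <- if (is.null(config$pooled)) TRUE else config$pooled
  out <- list(files = character())
  if (!is.null(config$series_tsv)) {
    ser <- utils::read.delim(config$series_tsv, stringsAsFactors = FALSE)
    fits <- lapply(split(ser, ser$series), function(d) {
      f <- steady_state_kd(d$conc, d$response)
      data.frame(series = d$series[1], kd = f$kd, rmax = f$rmax, sd = f$sd,
                 converged = f$converged)
    })
    kd_tab <- do.call(rbind, fits)
    rownames(kd_tab) <- NULL
    p <- write_tsv(kd_tab, file.path(out_dir, "kd_fits.tsv"))
    out$kd_fits <- kd_tab; out$files["kd_fits"] <- p
  }
  pvals <- NULL
  if (!is.null(config$ttest_tsv)) {
    tt <- utils::read.delim(config$ttest_tsv, stringsAsFactors = FALSE)
    tests <- do.call(rbind, lapply(seq_len(nrow(tt)), function(i) {
      r <- tt[i, ]
      res <- two_sample_t(r$mean1, r$sd1, r$n1, r$mean2, r$sd2, r$n2,
                          pooled = pooled)
      data.frame(label = r$label, statistic = res$statistic, df = res$df,
                 p = res$p_value)
    }))
    p <- write_tsv(tests, file.path(out_dir, "tests.tsv"))
    out$tests <- tests; out$files["tests"] <- p
    pvals <- stats::setNames(tests$p, tests$label)
  }
  if (!is.null(config$pvalues_tsv)) {
    pv <- utils::read.delim(config$pvalues_tsv, stringsAsFactors = FALSE)
    if (nrow(pv) == 0L) kd_stop("empty p-value file", "kirdock_config_error")
    pvals <- stats::setNames(pv$p, pv$label)
  }
  if (!is.null(pvals)) {
    fdr <- bky_fdr(unname(pvals), Q = Q)
    payload <- list(Q = Q, m = length(pvals), m0 = fdr$m0,
                    n_discoveries = sum(fdr$discoveries),
                    tests = data.frame(label = names(pvals),
                                       p = fdr$p_values, q = fdr$q_values,
                                       discovery = fdr$discoveries))
    fp <- file.path(out_dir, "fdr.json")
    jsonlite::write_json(payload, fp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    out$fdr <- fdr; out$files["fdr"] <- fp
  }
  invisible(out)
}
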