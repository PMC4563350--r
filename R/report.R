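# Report writer: benchmark summary table, signal-noise correlation table,
# and a JSON manifest sufficient to re-run the study.

#' Write study tables and a reproducibility manifest
#'
#' Writes up to three files into `dir`: `summary.csv` (one row per model:
#' `model, rmse, mape, mae, rrmse, min_rmse, max_rmse`),
#' `correlations.csv` (long table `series_id, model, method, correlation`,
#' only when `correlations` is supplied), and `manifest.json` (the
#' simulation spec, the method list, the benchmark, replicate count and
#' package version) — re-running [run_simulation_study()] from the
#' manifest's spec reproduces the summary exactly.
#'
#' @param study A `study_result` from [run_simulation_study()].
#' @param dir Output directory (created if missing).
#' @param correlations Optional data frame from
#'   [signal_noise_correlations()] (rows from several series/models may be
#'   concatenated).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(study, dir, correlations = NULL) {
  stopifnot(inherits(study, "study_result"))
  if (nrow(study$rmse_matrix) == 0L) stop("empty study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p1 <- file.path(dir, "summary.csv")
  utils::write.csv(study$summary[, c("model", "rmse", "mape", "mae",
                                     "rrmse", "min_rmse", "max_rmse")],
                   p1, row.names = FALSE)
  paths <- c(paths, p1)

  if (!is.null(correlations)) {
    need <- c("series_id", "model", "method", "correlation")
    if (!all(need %in% names(correlations)))
      stop("correlations must have columns ",
           paste(need, collapse = ", "))
    p2 <- file.path(dir, "correlations.csv")
    utils::write.csv(correlations[, need], p2, row.names = FALSE)
    paths <- c(paths, p2)
  }

  spec <- study$spec
  manifest <- list(
    spec = list(
      amplitude_A = spec$amplitude_A, lambda = spec$lambda,
      n_points = spec$n_points, x_start = spec$x_start,
      x_end = spec$x_end,
      segments = lapply(spec$segments, function(s)
        list(start = s$start, end = s$end, sigma = s$sigma)),
      n_reps = spec$n_reps, seed = spec$seed
    ),
    methods = study$summary$model,
    benchmark = study$benchmark,
    window = study$window,
    n_replicates_scored = nrow(study$rmse_matrix),
    n_replicates_dropped = study$n_failed,
    wilcoxon_p = study$wilcoxon_p,
    package_version = as.character(utils::packageVersion("gradsig"))
  )
  p3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p3)
  invisible(paths)
}
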