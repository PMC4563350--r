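# Error metrics used to score signal extraction against the known truth
# curve of a simulated replicate.

#' Root mean squared error
#' @param estimate,truth Numeric vectors of equal length.
#' @return `sqrt(mean((estimate - truth)^2))`.
#' @export
rmse <- function(estimate, truth) {
  e <- as.numeric(estimate)
  s <- as.numeric(truth)
  if (length(e) != length(s)) stop("length mismatch")
  if (length(e) < 1L) stop("empty input")
  sqrt(mean((e - s)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return `mean(abs(estimate - truth))`.
#' @export
mae <- function(estimate, truth) {
  e <- as.numeric(estimate)
  s <- as.numeric(truth)
  if (length(e) != length(s)) stop("length mismatch")
  if (length(e) < 1L) stop("empty input")
  mean(abs(e - s))
}

#' Mean absolute percentage error
#' @inheritParams rmse
#' @return `100 * mean(abs(truth - estimate) / abs(truth))`, in percent.
#'   Errors if any truth value is zero (an exponential truth curve never
#'   is).
#' @export
mape <- function(estimate, truth) {
  e <- as.numeric(estimate)
  s <- as.numeric(truth)
  if (length(e) != length(s)) stop("length mismatch")
  if (length(e) < 1L) stop("empty input")
  if (any(s == 0)) stop("truth contains zero; MAPE undefined")
  100 * mean(abs(s - e) / abs(s))
}

#' Relative RMSE of an alternate extractor against the SDD benchmark
#'
#' Aggregates per-replicate RMSEs of an alternate method and of the SDD
#' benchmark into a single ratio. The alternate method outperforms the
#' benchmark when the ratio is below 1. Two aggregation modes are
#' provided: `ratio_of_means` (ratio of the mean RMSEs; the default) and
#' `mean_of_ratios` (mean of the per-replicate ratios). For constant
#' inputs the two coincide.
#'
#' @param rmse_alt,rmse_sdd Per-replicate RMSE vectors of equal length.
#' @param mode `"ratio_of_means"` or `"mean_of_ratios"`.
#' @return A dimensionless ratio.
#' @export
rrmse <- function(rmse_alt, rmse_sdd,
                  mode = c("ratio_of_means", "mean_of_ratios")) {
  mode <- match.arg(mode)
  a <- as.numeric(rmse_alt)
  b <- as.numeric(rmse_sdd)
  if (length(a) != length(b)) stop("replicate counts differ")
  if (any(b <= 0)) stop("benchmark RMSE must be positive")
  if (mode == "ratio_of_means") mean(a) / mean(b) else mean(a / b)
}

#' Percent improvement implied by a relative RMSE
#'
#' @param rrmse_value A relative RMSE.
#' @return `(1 - rrmse_value) * 100`: the percentage by which the
#'   alternate method outperforms the benchmark (negative when it is
#'   worse).
#' @export
improvement_pct <- function(rrmse_value) (1 - as.numeric(rrmse_value)) * 100
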