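# Fractionally integrated ARIMA extraction. The stepwise scheme:
#   1. estimate the fractional differencing order d from an ARFIMA(2,d,0)
#      profile fit,
#   2. fractionally difference the series with that d,
#   3. select an ARMA(p, q) for the differenced series by the AIC grid,
#   4. re-estimate d jointly with the selected (p, q) and refit.
# The fractional differencing operator and the profile optimisation are
# implemented here; the inner ARMA fits use stats::arima(). The series is
# demeaned before fractional differencing (the standard convention for
# truncated fractional differencing, which assumes zero presample
# values).

#' Fractional differencing
#'
#' Applies the truncated binomial expansion of `(1 - B)^d` to a series:
#' `z_t = sum_{k=0}^{t-1} pi_k y_{t-k}` with `pi_0 = 1` and
#' `pi_k = pi_{k-1} (k - 1 - d) / k`. `d = 0` is the identity; negative d
#' fractionally integrates, which is how long-memory test series are
#' generated.
#'
#' @param x Numeric series.
#' @param d Differencing order, usually in `(-0.5, 1)`.
#' @return The differenced series, same length as `x`.
#' @export
frac_diff <- function(x, d) {
  x <- as.numeric(x)
  n <- length(x)
  if (!is.finite(d)) stop("d must be finite")
  if (d == 0) return(x)
  k <- seq_len(n - 1L)
  pi_k <- c(1, cumprod((k - 1 - d) / k))
  # z = convolution of x with pi, truncated at the series start
  as.numeric(stats::filter(c(rep(0, n - 1L), x), filter = pi_k,
                           sides = 1L))[n:(2L * n - 1L)]
}

# Gaussian profile objective for d on the demeaned series: fractionally
# difference, fit ARMA(p, q) by conditional sum of squares, return
# -loglik. Inf on failure.
arfima_profile_obj <- function(d, ym, p, q, method = "CSS") {
  z <- frac_diff(ym, d)
  fit <- tryCatch(
    suppressWarnings(stats::arima(z, order = c(p, 0L, q),
                                  include.mean = FALSE, method = method)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$loglik)) return(Inf)
  -fit$loglik
}

# Profile estimate of d for fixed ARMA orders. The CSS profile in d can
# be multimodal and ragged (the inner ARMA optimiser has local optima of
# its own), so a coarse grid pass picks the basin and a bounded local
# search refines it.
estimate_frac_d <- function(ym, p = 2L, q = 0L,
                            interval = c(-0.49, 0.99), step = 0.1) {
  grid <- seq(interval[1L], interval[2L], by = step)
  vals <- vapply(grid, arfima_profile_obj, numeric(1), ym = ym, p = p, q = q)
  if (!any(is.finite(vals)))
    stop("fractional differencing order could not be estimated")
  i <- which.min(vals)
  lo <- max(interval[1L], grid[i] - step)
  hi <- min(interval[2L], grid[i] + step)
  opt <- stats::optimize(arfima_profile_obj, interval = c(lo, hi),
                         ym = ym, p = p, q = q, tol = 1e-4)
  if (opt$objective <= vals[i]) opt$minimum else grid[i]
}

# Final (p, q) fit at a given d; NULL on failure.
arfima_final_fit <- function(ym, d, p, q) {
  z <- frac_diff(ym, d)
  fit <- tryCatch(
    suppressWarnings(stats::arima(z, order = c(p, 0L, q),
                                  include.mean = FALSE,
                                  method = "CSS-ML")),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      suppressWarnings(stats::arima(z, order = c(p, 0L, q),
                                    include.mean = FALSE, method = "CSS")),
      error = function(e) NULL)
  fit
}

#' ARFIMA signal extraction with stepwise fractional differencing
#'
#' Estimates the fractional order d from an ARFIMA(2, d, 0) profile
#' likelihood, fractionally differences the (demeaned) series, selects
#' the ARMA(p, q) of the differenced series by the AIC grid of
#' [fit_arima_auto()], then re-estimates d jointly with the selected
#' orders and refits the full model by maximum likelihood. If the joint
#' re-estimate ends in a worse likelihood basin than the initial d (the
#' profile is not unimodal), the initial d is kept. The extracted signal
#' is the in-sample one-step fitted values `y - e_t`, where the e_t are
#' the innovations of the full model — the innovations of the
#' fractionally differenced series are exactly the one-step prediction
#' errors of the original series.
#'
#' @param series Numeric series (or [expression_profile()]) of length
#'   `>= 30`.
#' @param max_p,max_q Order-grid bounds for the ARMA step (defaults 5).
#' @param positions Positions to attach to the extraction.
#' @return A `baseline_fit` with model `"arfima"`; `orders` records `p`,
#'   the fractional `d`, and `q`. Errors if the estimated d leaves
#'   `(-0.5, 1)`.
#' @export
fit_arfima <- function(series, max_p = 5L, max_q = 5L, positions = NULL) {
  if (inherits(series, "expression_profile")) {
    if (is.null(positions)) positions <- series$positions
    series <- series$intensities
  }
  y <- as.numeric(series)
  n <- length(y)
  if (n < 30L) stop("need at least 30 observations")
  if (is.null(positions)) positions <- seq_len(n)
  ym <- y - mean(y)

  d0 <- estimate_frac_d(ym, p = 2L, q = 0L)
  z0 <- frac_diff(ym, d0)
  sel <- fit_arima_auto(z0, max_p = max_p, max_q = max_q, d = 0L)
  p <- sel$orders$p
  q <- sel$orders$q

  d1 <- estimate_frac_d(ym, p = p, q = q)
  fit1 <- arfima_final_fit(ym, d1, p, q)
  fit0 <- if (abs(d1 - d0) > 1e-6) arfima_final_fit(ym, d0, p, q) else NULL
  pick <- function(f) if (is.null(f)) -Inf else f$loglik
  if (pick(fit0) > pick(fit1)) {
    d <- d0; fit <- fit0
  } else {
    d <- d1; fit <- fit1
  }
  if (is.null(fit)) stop("ARFIMA estimation failed to converge")
  if (d <= -0.5 || d >= 1)
    stop("estimated fractional order d = ", signif(d, 4),
         " outside (-0.5, 1)")
  e <- as.numeric(stats::residuals(fit))
  fitted <- y - e
  aic <- arima_selection_aic(fit$loglik, p, q, k = 0) + 2  # + d parameter
  extraction <- signal_extraction(
    method = "arfima", positions = positions,
    signal = fitted, residual = e,
    meta = list(p = p, d = d, q = q)
  )
  new_baseline_fit(model = "arfima",
                   orders = list(p = p, d = d, q = q),
                   aic = aic, extraction = extraction)
}
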