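# Automatic ARIMA signal extraction: the differencing order d comes from
# repeated KPSS tests, and (p, q, constant) from an AIC grid search. The
# inner (p, d, q) fits are maximum-likelihood state-space fits from
# stats::arima(); the selection loop, the AIC bookkeeping and the
# extraction contract live here.

#' AIC used for ARIMA order selection
#'
#' `AIC = -2 log(L) + 2 (p + q + P + Q + k)` with `k = 1` when a constant
#' is included and 0 otherwise. Seasonal orders P, Q are carried for
#' completeness; spatial profiles have no season so they are 0 throughout
#' the package.
#'
#' @param loglik Maximised log-likelihood.
#' @param p,q Nonseasonal AR and MA orders.
#' @param P,Q Seasonal AR and MA orders.
#' @param k 1 if a constant/drift is included, else 0.
#' @return The AIC value.
#' @export
arima_selection_aic <- function(loglik, p, q, P = 0, Q = 0, k = 0) {
  -2 * loglik + 2 * (p + q + P + Q + k)
}

#' Baseline model fit
#'
#' Common wrapper for the comparison extractors (ARIMA, ARFIMA, ETS,
#' neural autoregression): selected orders, the selection criterion value,
#' and the resulting [signal_extraction()].
#' @keywords internal
new_baseline_fit <- function(model, orders, aic, extraction) {
  structure(list(model = model, orders = orders, aic = aic,
                 extraction = extraction),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s", x$model))
  ord <- x$orders
  if (length(ord))
    cat(" [", paste(names(ord), unlist(lapply(ord, function(v)
      paste(signif(unlist(v), 4), collapse = " "))),
      sep = "=", collapse = ", "), "]", sep = "")
  if (is.finite(x$aic)) cat(sprintf(", AIC = %.2f", x$aic))
  cat("\n")
  invisible(x)
}

# Number of KPSS-mandated differences (0..max_d) at significance `alpha`.
ndiffs_kpss <- function(y, max_d = 2L, alpha = 0.05) {
  d <- 0L
  while (d < max_d && kpss_test(y)$p_value < alpha) {
    y <- diff(y)
    d <- d + 1L
  }
  d
}

# One candidate (p, d, q) fit; returns NULL on failure. A constant is an
# intercept when d = 0 and a drift regressor when d = 1.
fit_arima_candidate <- function(y, p, d, q, constant, method = "CSS-ML") {
  xreg <- NULL
  include.mean <- FALSE
  if (constant) {
    if (d == 0L) include.mean <- TRUE
    else if (d == 1L) xreg <- matrix(seq_along(y), dimnames = list(NULL, "drift"))
    else return(NULL)                       # no constant for d >= 2
  }
  fit <- tryCatch(
    suppressWarnings(stats::arima(y, order = c(p, d, q), xreg = xreg,
                                  include.mean = include.mean,
                                  method = method)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  k <- as.integer(constant)
  list(fit = fit, p = p, d = d, q = q, constant = constant,
       aic = arima_selection_aic(fit$loglik, p, q, k = k))
}

#' Automatic ARIMA signal extraction
#'
#' Selects the differencing order d by repeated KPSS tests (difference
#' until the test no longer rejects level stationarity, at most `max_d`
#' times), then minimises the selection AIC (see [arima_selection_aic()])
#' over the grid `p = 0..max_p`, `q = 0..max_q`, constant in/out. The
#' extracted signal is the series of in-sample one-step fitted values
#' (observed minus one-step innovation).
#'
#' @param series Numeric series (or [expression_profile()]) of length
#'   `>= 10`.
#' @param max_p,max_q Upper bounds of the order grid (defaults 5).
#' @param d Optional override of the differencing order; `NULL` (default)
#'   selects it by KPSS.
#' @param unit_root_alpha Significance level of the KPSS differencing
#'   decision.
#' @param positions Positions to attach to the extraction (taken from the
#'   profile when one is supplied; defaults to `1..N`).
#' @return A `baseline_fit` with model `"arima"`; `orders` records
#'   `(p, d, q)` and the constant flag.
#' @export
fit_arima_auto <- function(series, max_p = 5L, max_q = 5L, d = NULL,
                           unit_root_alpha = 0.05, positions = NULL) {
  if (inherits(series, "expression_profile")) {
    if (is.null(positions)) positions <- series$positions
    series <- series$intensities
  }
  y <- as.numeric(series)
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  if (is.null(positions)) positions <- seq_len(n)
  if (max_p < 0L || max_q < 0L) stop("max orders must be >= 0")
  if (is.null(d)) d <- ndiffs_kpss(y, alpha = unit_root_alpha)
  d <- as.integer(d)

  best <- NULL
  for (p in 0:max_p) for (q in 0:max_q) for (constant in c(FALSE, TRUE)) {
    if (constant && d >= 2L) next
    cand <- fit_arima_candidate(y, p, d, q, constant)
    if (is.null(cand)) next
    if (is.null(best) || cand$aic < best$aic) best <- cand
  }
  if (is.null(best)) stop("no ARIMA candidate converged")

  fitted <- y - as.numeric(stats::residuals(best$fit))
  extraction <- signal_extraction(
    method = "arima", positions = positions,
    signal = fitted, residual = y - fitted,
    meta = list(p = best$p, d = best$d, q = best$q,
                constant = best$constant)
  )
  new_baseline_fit(
    model = "arima",
    orders = list(p = best$p, d = best$d, q = best$q,
                  constant = best$constant),
    aic = best$aic, extraction = extraction
  )
}
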