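# Exponential smoothing state-space (ETS) extraction. Candidate models
# are the non-seasonal cells of the ETS taxonomy: additive or
# multiplicative error crossed with no / additive / damped-additive
# trend. Smoothing parameters and initial states are estimated by maximum
# likelihood and the winner is chosen by AIC. Implemented as innovations
# state-space recursions; a spatial profile has no season, so no seasonal
# component is ever considered.

# One pass of the innovations recursion. error: "A" or "M"; trend: "N",
# "A" (phi = 1) or "Ad". Returns one-step predictions mu_t, innovations
# e_t (relative for multiplicative error), or NULL if a multiplicative
# model hits a non-positive prediction.
#' ETS innovations filter
#'
#' Runs the one-step state-space recursion of a single ETS model with
#' fixed parameters over a series: level (and optionally damped trend)
#' updates driven by the one-step innovation. Mostly useful for inspecting
#' a fitted model; [fit_ets()] wraps the parameter estimation.
#'
#' @param y Numeric series.
#' @param error `"A"` (additive) or `"M"` (multiplicative) error.
#' @param trend `"N"`, `"A"` or `"Ad"` (damped).
#' @param alpha,beta Level and trend smoothing parameters.
#' @param phi Damping parameter (used by `"Ad"`; `"A"` fixes it at 1).
#' @param l0,b0 Initial level and trend states.
#' @return List with `fitted` (one-step predictions mu_t) and `resid`
#'   (innovations; relative errors under multiplicative error), or `NULL`
#'   when a multiplicative-error recursion produces a non-positive
#'   prediction.
#' @export
ets_filter <- function(y, error = "A", trend = "N", alpha = 0.5,
                       beta = 0.1, phi = 1, l0 = y[1], b0 = 0) {
  n <- length(y)
  mu <- numeric(n)
  e <- numeric(n)
  l <- l0
  b <- if (trend == "N") 0 else b0
  ph <- switch(trend, N = 0, A = 1, Ad = phi)
  for (t in seq_len(n)) {
    base <- l + ph * b
    mu[t] <- base
    if (error == "A") {
      e[t] <- y[t] - base
      l <- base + alpha * e[t]
      if (trend != "N") b <- ph * b + beta * e[t]
    } else {
      if (!is.finite(base) || base <= 0) return(NULL)
      e[t] <- (y[t] - base) / base
      l <- base * (1 + alpha * e[t])
      if (trend != "N") b <- ph * b + beta * base * e[t]
    }
    if (!is.finite(l)) return(NULL)
  }
  list(fitted = mu, resid = e)
}

# -2 log-likelihood of the innovations model (up to a constant shared by
# all candidates): n log(sum e^2) + 2 sum log|mu| for multiplicative
# error, n log(sum e^2) for additive.
ets_neg2loglik <- function(y, flt, error) {
  n <- length(y)
  sse <- sum(flt$resid^2)
  val <- n * log(max(sse, 1e-300))
  if (error == "M") val <- val + 2 * sum(log(abs(flt$fitted)))
  val
}

# Fit one (error, trend) cell by Nelder-Mead over transformed parameters.
ets_fit_one <- function(y, error, trend) {
  n <- length(y)
  # initial states from a linear fit to the first few points
  m <- min(10L, n)
  cf <- stats::lm.fit(cbind(1, seq_len(m) - 1), y[seq_len(m)])$coefficients
  l0_init <- cf[1L]
  b0_init <- if (trend == "N") 0 else cf[2L]
  if (error == "M" && l0_init <= 0) l0_init <- max(y[1L], 1e-3)

  has_trend <- trend != "N"
  damped <- trend == "Ad"
  # par: qlogis(alpha), qlogis(beta/alpha), l0, b0, qlogis((phi-.8)/.18)
  par <- c(stats::qlogis(0.5), stats::qlogis(0.2), l0_init)
  if (has_trend) par <- c(par, b0_init)
  if (damped) par <- c(par, stats::qlogis(0.5))

  unpack <- function(par) {
    alpha <- stats::plogis(par[1L]) * 0.9998 + 1e-4
    beta <- alpha * (stats::plogis(par[2L]) * 0.9998 + 1e-4)
    l0 <- par[3L]
    b0 <- if (has_trend) par[4L] else 0
    phi <- if (damped) 0.8 + 0.18 * stats::plogis(par[5L]) else 1
    list(alpha = alpha, beta = beta, l0 = l0, b0 = b0, phi = phi)
  }
  obj <- function(par) {
    p <- unpack(par)
    flt <- ets_filter(y, error, trend, p$alpha, p$beta, p$phi, p$l0, p$b0)
    if (is.null(flt)) return(1e10)
    ets_neg2loglik(y, flt, error)
  }
  opt <- tryCatch(
    stats::optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  p <- unpack(opt$par)
  flt <- ets_filter(y, error, trend, p$alpha, p$beta, p$phi, p$l0, p$b0)
  if (is.null(flt)) return(NULL)
  n_par <- 1L + has_trend + damped          # alpha (+ beta) (+ phi)
  n_state <- 1L + has_trend                 # l0 (+ b0)
  aic <- ets_neg2loglik(y, flt, error) + 2 * (n_par + n_state + 1L)
  list(error = error, trend = trend, par = p, filter = flt, aic = aic)
}

#' ETS signal extraction
#'
#' Enumerates the non-seasonal ETS models (additive or multiplicative
#' error; none, additive or damped trend), estimates each by maximum
#' likelihood, and keeps the model with the smallest AIC. Multiplicative
#' error variants are only considered for strictly positive series. The
#' extracted signal is the in-sample one-step predictions of the winning
#' model.
#'
#' @param series Numeric series (or [expression_profile()]) of length
#'   `>= 10`.
#' @param positions Positions to attach to the extraction.
#' @return A `baseline_fit` with model `"ets"`; `orders` records the
#'   error/trend spec and the estimated smoothing parameters.
#' @export
fit_ets <- function(series, positions = NULL) {
  if (inherits(series, "expression_profile")) {
    if (is.null(positions)) positions <- series$positions
    series <- series$intensities
  }
  y <- as.numeric(series)
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  if (is.null(positions)) positions <- seq_len(n)

  errors <- if (all(y > 0)) c("A", "M") else "A"
  best <- NULL
  for (err in errors) for (tr in c("N", "A", "Ad")) {
    cand <- ets_fit_one(y, err, tr)
    if (is.null(cand)) next
    if (is.null(best) || cand$aic < best$aic) best <- cand
  }
  if (is.null(best)) stop("all ETS candidates failed")

  fitted <- best$filter$fitted
  extraction <- signal_extraction(
    method = "ets", positions = positions,
    signal = fitted, residual = y - fitted,
    meta = list(spec = paste0(best$error, best$trend, "N"),
                alpha = best$par$alpha,
                beta = if (best$trend == "N") NA_real_ else best$par$beta,
                phi = if (best$trend == "Ad") best$par$phi else NA_real_)
  )
  new_baseline_fit(
    model = "ets",
    orders = list(spec = paste0(best$error, best$trend, "N"),
                  alpha = best$par$alpha),
    aic = best$aic, extraction = extraction
  )
}
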