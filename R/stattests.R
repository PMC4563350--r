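# Unit-root tests used by the automatic ARIMA selection (KPSS) and the
# residual diagnostics (ADF). Both follow the standard regression-based
# constructions with p-values obtained by interpolation in the published
# critical-value tables; p-values are clamped to the table range.

#' KPSS test for level stationarity
#'
#' Null hypothesis: the series is (level-)stationary. The statistic is
#' `sum(S_t^2) / (n^2 * lrv)` where S_t are partial sums of the residuals
#' from regressing on a constant and `lrv` is the Bartlett-kernel long-run
#' variance with truncation lag `trunc(4 * (n/100)^(1/4))`. The p-value is
#' interpolated in the asymptotic critical values (0.347, 0.463, 0.574,
#' 0.739 at 10/5/2.5/1 percent) and clamped to `[0.01, 0.10]`.
#'
#' @param x Numeric series.
#' @return List with `statistic`, `p_value`, `trunc_lag`.
#' @export
kpss_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("series too short for a KPSS test")
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  s2 <- sum(e^2) / n
  if (l > 0) {
    for (h in seq_len(l)) {
      w <- 1 - h / (l + 1)
      s2 <- s2 + 2 * w * sum(e[(h + 1):n] * e[1:(n - h)]) / n
    }
  }
  stat <- sum(s^2) / (n^2 * s2)
  crit <- c(0.347, 0.463, 0.574, 0.739)
  pvals <- c(0.10, 0.05, 0.025, 0.01)
  p <- stats::approx(crit, pvals, xout = stat, rule = 2)$y
  list(statistic = stat, p_value = p, trunc_lag = l)
}

# Dickey-Fuller tau table for the regression with constant and linear
# trend (Banerjee, Dolado, Galbraith & Hendry 1993, Table 4.2), indexed by
# sample size and tail probability.
.adf_tau3 <- list(
  n = c(25, 50, 100, 250, 500, 1e5),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  tab = rbind(
    c(-4.38, -3.95, -3.60, -3.24, -1.14, -0.80, -0.50, -0.15),
    c(-4.15, -3.80, -3.50, -3.18, -1.19, -0.87, -0.58, -0.24),
    c(-4.04, -3.73, -3.45, -3.15, -1.22, -0.90, -0.62, -0.28),
    c(-3.99, -3.69, -3.43, -3.13, -1.23, -0.92, -0.64, -0.31),
    c(-3.98, -3.68, -3.42, -3.13, -1.24, -0.93, -0.65, -0.32),
    c(-3.96, -3.66, -3.41, -3.12, -1.25, -0.94, -0.66, -0.33)
  )
)

#' Augmented Dickey-Fuller test for a unit root
#'
#' Null hypothesis: the series has a unit root. Regresses the first
#' difference on the lagged level, a constant, a linear trend, and `k`
#' lagged differences (default `trunc((n - 1)^(1/3))`), and refers the
#' t-statistic of the lagged level to the Dickey-Fuller distribution via
#' 2-d interpolation in the tabulated quantiles. P-values are clamped to
#' `[0.01, 0.99]`.
#'
#' @param x Numeric series, length `>= 20`.
#' @param k Number of lagged differences in the regression.
#' @return List with `statistic`, `p_value`, `lag_order`.
#' @export
adf_test <- function(x, k = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20L) stop("series too short for an ADF test (need N >= 20)")
  if (is.null(k)) k <- trunc((n - 1)^(1 / 3))
  k <- as.integer(k)
  dx <- diff(x)
  m <- length(dx)
  idx <- (k + 1L):m
  yl <- x[idx]                       # lagged level x_{t-1}
  dy <- dx[idx]                      # response: diff at t
  tt <- idx                          # linear trend
  X <- cbind(1, yl, tt)
  if (k > 0L)
    for (j in seq_len(k)) X <- cbind(X, dx[idx - j])
  fit <- stats::lm.fit(X, dy)
  res <- fit$residuals
  df <- length(dy) - ncol(X)
  s2 <- sum(res^2) / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * xtxinv[2L, 2L])
  stat <- fit$coefficients[2L] / se

  tbl <- .adf_tau3
  # interpolate across sample sizes, then across the statistic
  row <- vapply(seq_along(tbl$p), function(j)
    stats::approx(tbl$n, tbl$tab[, j], xout = n, rule = 2)$y, numeric(1))
  p <- stats::approx(row, tbl$p, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, lag_order = k)
}
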