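#' Fitted SDD exponential gradient
#'
#' Result of fitting `B(x) = A * exp(-(x - x_anterior) / lambda)` to a
#' profile. `x_anterior` is the smallest position in the profile, so the
#' amplitude always refers to the anterior-most observed point.
#'
#' @param amplitude_A Fitted amplitude (AU), `> 0`.
#' @param lambda Fitted length constant (percent egg length), `> 0`.
#' @param method `"anterior_efold"` or `"least_squares"`.
#' @param x_anterior Anterior reference position.
#' @param profile The profile the fit was computed from.
#' @param meta Extra fit information (residual sum of squares, ...).
#' @return An object of class `sdd_fit`; `fitted_signal` holds the implied
#'   signal on the profile's grid.
#' @keywords internal
new_sdd_fit <- function(amplitude_A, lambda, method, x_anterior, profile,
                        meta = list()) {
  if (!is.finite(amplitude_A) || amplitude_A <= 0)
    stop("fitted amplitude must be > 0")
  if (!is.finite(lambda) || lambda <= 0)
    stop("fitted length constant must be > 0")
  fitted_signal <- amplitude_A *
    exp(-(profile$positions - x_anterior) / lambda)
  structure(
    list(amplitude_A = amplitude_A, lambda = lambda, method = method,
         x_anterior = x_anterior, fitted_signal = fitted_signal,
         positions = profile$positions, observed = profile$intensities,
         meta = meta),
    class = "sdd_fit"
  )
}

#' @export
print.sdd_fit <- function(x, ...) {
  cat(sprintf("<sdd_fit> method = %s: A = %.4g AU, lambda = %.4g %%EL\n",
              x$method, x$amplitude_A, x$lambda))
  invisible(x)
}

#' Fit the SDD gradient by the anterior 1/e-crossing rule
#'
#' The textbook characterisation of the exponential gradient: the amplitude
#' A is read off the observed intensity at the anterior-most position, and
#' the length constant lambda is the distance at which the intensity first
#' drops to A/e, with linear interpolation between the bracketing grid
#' points. With noisy data the first crossing from the anterior is used.
#' This is the benchmark extractor of the package: it inherits the noise of
#' the two points it touches, which is exactly why it smooths poorly.
#'
#' @param profile An [expression_profile()] with positive anterior
#'   intensity.
#' @return An `sdd_fit` with method `"anterior_efold"`.
#' @export
fit_sdd_anterior_efold <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  x <- profile$positions
  y <- profile$intensities
  a <- y[1L]
  if (a <= 0) stop("anterior intensity must be > 0")
  level <- a / exp(1)
  below <- which(y <= level)
  below <- below[below > 1L]
  if (length(below) == 0L)
    stop("no e-fold crossing: intensity never drops to A/e; ",
         "lambda is undefined for this profile")
  j <- below[1L]
  # linear interpolation between the last point above the level and the
  # first point at/below it
  x_star <- if (y[j] == level) x[j] else {
    i <- j - 1L
    x[i] + (x[j] - x[i]) * (y[i] - level) / (y[i] - y[j])
  }
  lambda <- x_star - x[1L]
  new_sdd_fit(a, lambda, "anterior_efold", x_anterior = x[1L],
              profile = profile,
              meta = list(crossing_position = x_star))
}

#' Fit the SDD gradient by nonlinear least squares
#'
#' Minimises `sum (y_i - A * exp(-(x_i - x_anterior) / lambda))^2` with a
#' Levenberg-Marquardt optimiser, initialised from the log-linear
#' regression of `log(y)` on `x` over the points with positive intensity
#' (those points are excluded from the initialisation only; the nonlinear
#' fit uses all points).
#'
#' @param profile An [expression_profile()] with at least 3 points of
#'   positive intensity.
#' @return An `sdd_fit` with method `"least_squares"`; `meta$rss` holds the
#'   residual sum of squares.
#' @export
fit_sdd_least_squares <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  x <- profile$positions
  y <- profile$intensities
  x0 <- x[1L]
  pos <- y > 0
  if (sum(pos) < 3L) stop("need at least 3 points with positive intensity")
  init <- stats::lm.fit(cbind(1, x[pos] - x0), log(y[pos]))$coefficients
  a0 <- exp(unname(init[1L]))
  lam0 <- if (is.finite(init[2L]) && init[2L] < 0) -1 / unname(init[2L]) else
    diff(range(x)) / 2
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - x0) / lambda),
    data = data.frame(x = x, y = y),
    start = list(A = a0, lambda = lam0),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  new_sdd_fit(cf[["A"]], cf[["lambda"]], "least_squares",
              x_anterior = x0, profile = profile,
              meta = list(rss = sum(stats::residuals(fit)^2)))
}

#' Evaluate a fitted SDD gradient at given positions
#'
#' @param fit An `sdd_fit`.
#' @param positions Positions (percent egg length).
#' @return Intensities `A * exp(-(x - x_anterior) / lambda)`.
#' @export
predict_sdd <- function(fit, positions) {
  stopifnot(inherits(fit, "sdd_fit"))
  fit$amplitude_A * exp(-(as.numeric(positions) - fit$x_anterior) /
                          fit$lambda)
}

#' Convert an SDD fit to a signal extraction
#'
#' @param fit An `sdd_fit`.
#' @return A [signal_extraction()] whose method label is
#'   `"sdd_<fit method>"`.
#' @export
as_signal_extraction <- function(fit) {
  stopifnot(inherits(fit, "sdd_fit"))
  signal_extraction(
    method = paste0("sdd_", fit$method), positions = fit$positions,
    signal = fit$fitted_signal,
    residual = fit$observed - fit$fitted_signal,
    meta = list(amplitude_A = fit$amplitude_A, lambda = fit$lambda)
  )
}
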