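#' Signal extraction result
#'
#' The common return type of every extractor in the package: the observed
#' series split additively into an extracted signal and a residual (noise)
#' series, `observed = signal + residual` element-wise.
#'
#' @param method Character label of the extraction method.
#' @param positions AP positions of the series (percent egg length).
#' @param signal Extracted signal (AU).
#' @param residual Residual series (AU), same length as `signal`.
#' @param meta Named list of free-form method parameters (window length,
#'   selected orders, seeds, ...).
#' @return An object of class `signal_extraction`.
#' @export
signal_extraction <- function(method, positions, signal, residual,
                              meta = list()) {
  signal <- as.numeric(signal)
  residual <- as.numeric(residual)
  positions <- as.numeric(positions)
  if (length(signal) != length(residual))
    stop("signal and residual lengths differ")
  if (length(positions) != length(signal))
    stop("positions and series lengths differ")
  structure(
    list(method = as.character(method)[1L], positions = positions,
         signal = signal, residual = residual, meta = meta),
    class = "signal_extraction"
  )
}

#' @export
print.signal_extraction <- function(x, ...) {
  cat(sprintf("<signal_extraction> method = %s, N = %d\n",
              x$method, length(x$signal)))
  cat(sprintf("  residual sd = %.4g AU\n", stats::sd(x$residual)))
  invisible(x)
}

#' @export
as.data.frame.signal_extraction <- function(x, ...) {
  data.frame(position = x$positions,
             observed = x$signal + x$residual,
             signal = x$signal,
             residual = x$residual)
}

# Observed series an extraction was computed from.
observed_series <- function(x) x$signal + x$residual
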