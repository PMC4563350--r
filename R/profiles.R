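#' One-dimensional expression profile
#'
#' Container for a single anterior-posterior (AP) expression profile: an
#' ordered set of positions along the AP axis, in percent egg length, paired
#' with fluorescence intensities in arbitrary units (AU). A profile may hold
#' measured data, a simulated noise-free truth curve, or a simulated noisy
#' replicate.
#'
#' @param positions Numeric vector of AP positions (percent egg length).
#'   Need not be sorted; the constructor sorts.
#' @param intensities Numeric vector of intensities (AU), same length as
#'   `positions`. All values must be finite.
#' @param series_id Character label for the series (embryo id or replicate
#'   tag).
#' @param provenance One of `"measured"`, `"simulated_truth"`,
#'   `"simulated_noisy"`.
#'
#' @return An object of class `expression_profile`: a list with elements
#'   `series_id`, `positions`, `intensities`, `provenance`.
#' @export
#' @examples
#' p <- expression_profile(c(10, 20, 30), c(100, 50, 25), "ex")
#' length(p)
expression_profile <- function(positions, intensities, series_id = "series",
                               provenance = c("measured", "simulated_truth",
                                              "simulated_noisy")) {
  provenance <- match.arg(provenance)
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (length(positions) < 3L)
    stop("a profile needs at least 3 points, got ", length(positions))
  if (!all(is.finite(positions)))
    stop("non-finite positions")
  if (!all(is.finite(intensities)))
    stop("non-finite intensities")
  ord <- order(positions)
  positions <- positions[ord]
  intensities <- intensities[ord]
  if (anyDuplicated(positions))
    stop("duplicate positions; average them first (see read_profile)")
  structure(
    list(series_id = as.character(series_id)[1L],
         positions = positions,
         intensities = intensities,
         provenance = provenance),
    class = "expression_profile"
  )
}

#' @export
length.expression_profile <- function(x) length(x$positions)

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s (%s): N = %d, AP range [%g, %g] %%EL\n",
              x$series_id, x$provenance, length(x),
              x$positions[1L], x$positions[length(x)]))
  invisible(x)
}

#' @export
as.data.frame.expression_profile <- function(x, ...) {
  data.frame(position = x$positions, intensity = x$intensities)
}

#' Read an expression profile from a delimited text file
#'
#' Two dialects are supported. `two_column` is a CSV with a
#' `position,intensity` header (extra columns ignored). `flyex_like` is a
#' best-effort reader for whitespace-delimited exports of quantitative
#' expression databases: column indices for position and intensity are
#' configurable because the exact export layout varies.
#'
#' Rows with non-finite intensity or position are dropped, and the number of
#' dropped rows is reported on standard error. Rows sharing an identical
#' position (per-nucleus scatter data can have ties) are averaged, with a
#' warning, so that downstream extractors always receive a single-valued
#' sequence.
#'
#' @param path Path to the file.
#' @param dialect `"two_column"` (comma-delimited, `position,intensity`
#'   header) or `"flyex_like"` (whitespace-delimited, header optional).
#' @param position_col,intensity_col Column indices used by the
#'   `flyex_like` dialect (defaults 1 and 2).
#' @param series_id Label for the profile; defaults to the file name.
#' @return An [expression_profile()].
#' @export
read_profile <- function(path, dialect = c("two_column", "flyex_like"),
                         position_col = 1L, intensity_col = 2L,
                         series_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(series_id))
    series_id <- sub("\\.[^.]*$", "", basename(path))

  if (dialect == "two_column") {
    df <- utils::read.csv(path, header = TRUE, strip.white = TRUE)
    need <- c("position", "intensity")
    if (!all(need %in% names(df)))
      stop("two_column dialect requires a 'position,intensity' header")
    pos <- as.numeric(df$position)
    int <- as.numeric(df$intensity)
  } else {
    lines <- readLines(path, n = 50L)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (length(lines) == 0L) stop("no data lines in ", path)
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(trimws(lines[1L]), "[,[:space:]]+")[[1L]][1L])))
    df <- utils::read.table(path, header = has_header,
                            comment.char = "#", fill = TRUE)
    if (max(position_col, intensity_col) > ncol(df))
      stop("file has only ", ncol(df), " columns")
    pos <- as.numeric(df[[position_col]])
    int <- as.numeric(df[[intensity_col]])
  }

  keep <- is.finite(pos) & is.finite(int)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("read_profile: dropped ", n_dropped,
            " row(s) with non-finite values from ", basename(path))
  pos <- pos[keep]
  int <- int[keep]

  if (anyDuplicated(pos)) {
    warning("read_profile: averaged intensities at duplicated positions in ",
            basename(path))
    int <- as.numeric(tapply(int, pos, mean))
    pos <- sort(unique(pos))
  }
  if (length(pos) < 3L)
    stop("fewer than 3 valid rows in ", path)
  expression_profile(pos, int, series_id = series_id,
                     provenance = "measured")
}

#' Restrict a profile to an AP window
#'
#' Keeps points with `lo <= position <= hi` (both boundaries inclusive).
#' Quantitative Bicoid studies conventionally analyse the 20-80 percent
#' egg-length window, where nuclear intensities are reliably measured.
#'
#' @param profile An [expression_profile()].
#' @param lo,hi Window boundaries in percent egg length, `lo < hi`.
#' @return The cropped [expression_profile()].
#' @export
crop_to_ap_window <- function(profile, lo = 20, hi = 80) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!(lo < hi)) stop("need lo < hi")
  keep <- profile$positions >= lo & profile$positions <= hi
  if (sum(keep) == 0L)
    stop("AP window [", lo, ", ", hi, "] contains no data points")
  expression_profile(profile$positions[keep], profile$intensities[keep],
                     series_id = profile$series_id,
                     provenance = profile$provenance)
}

#' Write a signal extraction to a CSV file
#'
#' Writes columns `position, observed, signal, residual` at full precision
#' (15 significant digits), so that [read_extraction()] round-trips the
#' numbers losslessly.
#'
#' @param result A [signal_extraction()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_extraction <- function(result, path) {
  stopifnot(inherits(result, "signal_extraction"))
  n <- length(result$signal)
  if (n == 0L) stop("empty extraction")
  df <- data.frame(
    position = result$positions,
    observed = result$signal + result$residual,
    signal = result$signal,
    residual = result$residual
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("position,observed,signal,residual", con)
  body <- apply(format(df, digits = 15, scientific = FALSE,
                       trim = TRUE), 1L, paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' Read a signal extraction written by [write_extraction()]
#'
#' @param path Path to the CSV file.
#' @param method Method label to attach to the result.
#' @return A [signal_extraction()].
#' @export
read_extraction <- function(path, method = "unknown") {
  df <- utils::read.csv(path)
  need <- c("position", "observed", "signal", "residual")
  if (!all(need %in% names(df)))
    stop("not an extraction file: missing columns")
  signal_extraction(method = method, positions = df$position,
                    signal = df$signal, residual = df$residual)
}
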