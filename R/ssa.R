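#' Embed a series into its Hankel trajectory matrix
#'
#' Maps a length-N series into the L x K trajectory matrix whose columns
#' are the K = N - L + 1 lagged vectors `(y_j, ..., y_{j+L-1})`. The matrix
#' is Hankel: entry (i, j) depends only on i + j.
#'
#' @param series Numeric series of length N.
#' @param window_length_L Window length L, `2 <= L <= N - 1`.
#' @return An object of class `trajectory_matrix`: list with `values`
#'   (L x K matrix), `window_length_L`, `series_length_N`.
#' @export
ssa_embed <- function(series, window_length_L) {
  y <- as.numeric(series)
  n <- length(y)
  l <- as.integer(window_length_L)
  if (l < 2L || l > n - 1L)
    stop("window length L must satisfy 2 <= L <= N - 1 (N = ", n, ")")
  if (!all(is.finite(y))) stop("series has non-finite values")
  k <- n - l + 1L
  x <- matrix(0, nrow = l, ncol = k)
  for (j in seq_len(k)) x[, j] <- y[j:(j + l - 1L)]
  structure(list(values = x, window_length_L = l, series_length_N = n),
            class = "trajectory_matrix")
}

#' Singular value decomposition of a trajectory matrix
#'
#' Decomposes the trajectory matrix X into its elementary rank-one terms
#' `X = sum_i sqrt(lambda_i) U_i V_i^T`, where lambda_i are the eigenvalues
#' of `X X^T` in decreasing order, U_i the orthonormal left singular
#' vectors and `V_i = X^T U_i / sqrt(lambda_i)`. Singular values below
#' `tol` times the largest are treated as numerically zero when counting
#' the rank d.
#'
#' @param X A `trajectory_matrix` from [ssa_embed()].
#' @param tol Relative rank tolerance (default `1e-11`).
#' @return An object of class `ssa_decomposition`: list with
#'   `singular_values` (decreasing), `left_vectors` (L x d), and
#'   `right_vectors` (K x d) matrices, `rank_d`, plus the embedding
#'   geometry (`window_length_L`, `series_length_N`).
#' @export
ssa_decompose <- function(X, tol = 1e-11) {
  stopifnot(inherits(X, "trajectory_matrix"))
  if (!all(is.finite(X$values))) stop("non-finite trajectory matrix")
  s <- svd(X$values)
  d <- sum(s$d > tol * s$d[1L])
  d <- max(d, 1L)
  structure(
    list(singular_values = s$d, left_vectors = s$u, right_vectors = s$v,
         rank_d = d, window_length_L = X$window_length_L,
         series_length_N = X$series_length_N),
    class = "ssa_decomposition"
  )
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat(sprintf("<ssa_decomposition> L = %d, N = %d, rank d = %d\n",
              x$window_length_L, x$series_length_N, x$rank_d))
  cat("  leading singular values:",
      paste(signif(utils::head(x$singular_values, 5L), 4), collapse = ", "),
      "\n")
  invisible(x)
}

# Diagonal averaging (hankelization): average the anti-diagonals of an
# L x K matrix into a series of length L + K - 1.
diagonal_average <- function(m) {
  l <- nrow(m)
  k <- ncol(m)
  n <- l + k - 1L
  idx <- as.vector(row(m) + col(m) - 1L)
  counts <- tabulate(idx, nbins = n)
  sums <- as.numeric(rowsum(as.vector(m), group = idx))
  sums / counts
}

#' Reconstruct a grouped SSA component as a series
#'
#' Sums the elementary matrices with indices in `group` and transforms the
#' sum back into a series by diagonal averaging (anti-diagonal means).
#' Reconstructing over all of `1..rank_d` returns the original series up to
#' floating-point error.
#'
#' @param decomp An [ssa_decompose()] result.
#' @param group Integer indices of eigentriples, a subset of `1..rank_d`.
#' @return Numeric series of length N.
#' @export
ssa_reconstruct <- function(decomp, group) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  group <- as.integer(group)
  if (length(group) == 0L) stop("empty group")
  if (any(group < 1L | group > decomp$rank_d))
    stop("group indices must lie in 1..rank_d (d = ", decomp$rank_d, ")")
  u <- decomp$left_vectors[, group, drop = FALSE]
  v <- decomp$right_vectors[, group, drop = FALSE]
  s <- decomp$singular_values[group]
  m <- u %*% (s * t(v))
  diagonal_average(m)
}

#' Extract the trend from a profile by singular spectrum analysis
#'
#' The SSA extractor: embed the intensity series in its trajectory matrix,
#' take the SVD, keep the leading `n_components` eigentriples (the first
#' eigentriple usually carries the trend of a monotone gradient), and map
#' them back to a series by diagonal averaging. Whatever is not kept is the
#' residual, interpreted as noise.
#'
#' @param profile An [expression_profile()].
#' @param window_length_L Window length; default `floor(N / 2)`, standard
#'   SSA practice which maximises the separability of components.
#' @param n_components Number of leading eigentriples kept as signal
#'   (default 1).
#' @return A [signal_extraction()] with method `"ssa"`; `meta` records `L`,
#'   the group, and the leading singular values.
#' @export
#' @examples
#' pr <- generate_replicate(simulation_spec(n_reps = 1), 0)$noisy
#' ex <- extract_signal_ssa(pr)
#' ex
extract_signal_ssa <- function(profile, window_length_L = NULL,
                               n_components = 1L) {
  stopifnot(inherits(profile, "expression_profile"))
  y <- profile$intensities
  n <- length(y)
  if (is.null(window_length_L)) window_length_L <- floor(n / 2)
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")
  X <- ssa_embed(y, window_length_L)
  dec <- ssa_decompose(X)
  group <- seq_len(min(n_components, dec$rank_d))
  signal <- ssa_reconstruct(dec, group)
  signal_extraction(
    method = "ssa", positions = profile$positions,
    signal = signal, residual = y - signal,
    meta = list(window_length_L = X$window_length_L, group = group,
                rank_d = dec$rank_d,
                singular_values = utils::head(dec$singular_values, 10L))
  )
}

# Anti-diagonal multiplicity weights w_i = min(i, L, K, N - i + 1),
# 1-based i, used by the w-correlation.
w_weights <- function(n, l) {
  k <- n - l + 1L
  i <- seq_len(n)
  pmin(i, l, k, n - i + 1L)
}

#' Weighted correlation between two series components
#'
#' The w-correlation weighs each time point by the number of times it
#' appears on an anti-diagonal of the L-trajectory matrix,
#' `w_i = min(i, L, K, N - i + 1)`. Two SSA components are well separable
#' when their w-correlation is near zero.
#'
#' @param series_a,series_b Numeric series of equal length N.
#' @param window_length_L Window length L, `2 <= L <= N - 1`.
#' @return A number in `[-1, 1]`.
#' @export
w_correlation <- function(series_a, series_b, window_length_L) {
  a <- as.numeric(series_a)
  b <- as.numeric(series_b)
  n <- length(a)
  if (length(b) != n) stop("series lengths differ")
  l <- as.integer(window_length_L)
  if (l < 2L || l > n - 1L) stop("invalid window length")
  w <- w_weights(n, l)
  na <- sum(w * a * a)
  nb <- sum(w * b * b)
  if (na <= 0 || nb <= 0) stop("zero weighted norm")
  sum(w * a * b) / sqrt(na * nb)
}
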