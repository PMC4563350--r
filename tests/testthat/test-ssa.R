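test_that("embedding builds the Hankel trajectory matrix", {
  X <- ssa_embed(c(1, 2, 3, 4), 2)
  expect_equal(X$values, rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(dim(ssa_embed(1:5, 3)$values), c(3L, 3L))
  expect_error(ssa_embed(1:5, 1), "window length")
  expect_error(ssa_embed(1:5, 5), "window length")

  # a geometric series has unit Hankel rank
  y <- 3 * 0.9^(0:49)
  sv <- svd(ssa_embed(y, 25)$values)$d
  expect_lt(sv[2], 1e-10 * sv[1])
})

test_that("the SVD step matches an independent eigen-solver", {
  set.seed(11)
  X <- ssa_embed(stats::rnorm(13), 6)          # 6 x 8 Hankel matrix
  dec <- ssa_decompose(X)
  # eigenvalues of X X^T are the squared singular values
  ev <- eigen(tcrossprod(X$values), symmetric = TRUE)$values
  expect_equal(dec$singular_values^2, ev, tolerance = 1e-8)
  expect_false(is.unsorted(rev(dec$singular_values)))
  # sum of elementary matrices reconstructs X
  recon <- dec$left_vectors %*% (dec$singular_values * t(dec$right_vectors))
  expect_lt(norm(recon - X$values, "F") / norm(X$values, "F"), 1e-10)
  # orthonormal singular vectors
  expect_equal(crossprod(dec$left_vectors), diag(6), tolerance = 1e-8)
  expect_equal(crossprod(dec$right_vectors), diag(6), tolerance = 1e-8)
  # a constant series has exactly one positive singular value
  dc <- ssa_decompose(ssa_embed(rep(5, 10), 4))
  expect_equal(dc$rank_d, 1L)
})

test_that("diagonal averaging inverts embedding and averages anti-diagonals", {
  expect_equal(gradsig:::diagonal_average(rbind(c(1, 2), c(3, 4))),
               c(1, 2.5, 4))
  set.seed(21)
  y <- stats::rnorm(40)
  dec <- ssa_decompose(ssa_embed(y, 17))
  expect_equal(ssa_reconstruct(dec, seq_len(dec$rank_d)), y,
               tolerance = 1e-9)
  expect_error(ssa_reconstruct(dec, integer(0)), "empty")
  expect_error(ssa_reconstruct(dec, dec$rank_d + 1L), "rank_d")
})

test_that("reconstruction is additive over any partition of components", {
  set.seed(31)
  y <- stats::rnorm(30)
  dec <- ssa_decompose(ssa_embed(y, 12))
  d <- dec$rank_d
  cut <- sample(seq_len(d - 1L), 1)
  part <- ssa_reconstruct(dec, 1:cut) + ssa_reconstruct(dec, (cut + 1):d)
  expect_equal(part, y, tolerance = 1e-9)
})

test_that("finite-rank series are recovered exactly by few eigentriples", {
  # one exponential -> one component
  y1 <- sdd_curve(10, 20, seq(0, 60, by = 1))
  dec <- ssa_decompose(ssa_embed(y1, 30))
  expect_lt(max(abs(ssa_reconstruct(dec, 1) - y1)), 1e-8)
  # sums of m distinct exponentials -> m components (m <= 3)
  x <- seq(0, 60, by = 1)
  rates <- c(10, 25, 40)
  for (m in 2:3) {
    ym <- Reduce(`+`, lapply(rates[1:m], function(l) sdd_curve(5, l, x)))
    decm <- ssa_decompose(ssa_embed(ym, 30))
    expect_lt(max(abs(ssa_reconstruct(decm, 1:m) - ym)), 1e-7)
    expect_lt(decm$singular_values[m + 1], 1e-9 * decm$singular_values[1])
  }
})

test_that("the SSA extractor separates trend from noise on profiles", {
  # noiseless exponential: first eigentriple is the whole signal
  pr <- fixture_exponential(A = 10, lambda = 20, x = seq(0, 60, by = 1))
  ex <- extract_signal_ssa(pr, window_length_L = 30, n_components = 1)
  expect_lt(max(abs(ex$residual)), 1e-8)
  expect_equal(ex$signal + ex$residual, pr$intensities, tolerance = 1e-9)

  # keeping every component reproduces the observations
  r <- fixture_replicate()
  full <- extract_signal_ssa(r$noisy, n_components = length(r$noisy))
  expect_lt(max(abs(full$residual)), 1e-8)

  # on a noisy replicate the extraction beats the raw observations
  ex_n <- extract_signal_ssa(r$noisy)
  expect_lt(rmse(ex_n$signal, r$truth$intensities),
            rmse(r$noisy$intensities, r$truth$intensities))
})

test_that("w-correlation weights count anti-diagonal multiplicities", {
  # enumeration oracle for the weights
  count_weights <- function(n, l) {
    k <- n - l + 1L
    w <- integer(n)
    for (li in 1:l) for (ki in 1:k) {
      i <- li + ki - 1L
      w[i] <- w[i] + 1L
    }
    w
  }
  expect_equal(gradsig:::w_weights(4, 2), count_weights(4, 2))
  expect_equal(gradsig:::w_weights(4, 2), c(1, 2, 2, 1))
  for (n in c(7, 12)) for (l in c(2, 5)) {
    expect_equal(gradsig:::w_weights(n, l), count_weights(n, l))
  }

  set.seed(41)
  y <- stats::rnorm(20)
  expect_equal(w_correlation(y, y, 8), 1)
  expect_equal(w_correlation(y, -y, 8), -1)
  expect_equal(w_correlation(y, 2 * y, 8), 1)
  expect_error(w_correlation(rep(0, 20), y, 8), "zero weighted norm")

  # SSA leaves signal and noise nearly w-orthogonal on the default fixture
  r <- fixture_replicate()
  ex <- extract_signal_ssa(r$noisy)
  L <- ex$meta$window_length_L
  expect_lt(abs(w_correlation(ex$signal, ex$residual, L)), 0.1)
})
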