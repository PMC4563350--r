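# Feed-forward neural autoregression: the series is regressed on its own
# p lags through a small multi-layer perceptron with logistic hidden
# units and a linear output, trained from many random starting weights;
# the extracted signal is the average of the restarts' in-sample
# predictions. The network is implemented here because the extractor must
# support more than one hidden layer (the study selects a two-hidden-layer
# configuration).

logistic <- function(z) 1 / (1 + exp(-z))

# Pack/unpack weights for a layered net with sizes c(p, h1, ..., 1).
mlp_n_par <- function(sizes) {
  sum((sizes[-length(sizes)] + 1L) * sizes[-1L])
}

mlp_unpack <- function(par, sizes) {
  out <- vector("list", length(sizes) - 1L)
  off <- 0L
  for (i in seq_along(out)) {
    nin <- sizes[i]
    nout <- sizes[i + 1L]
    w <- matrix(par[off + seq_len(nin * nout)], nin, nout)
    off <- off + nin * nout
    b <- par[off + seq_len(nout)]
    off <- off + nout
    out[[i]] <- list(w = w, b = b)
  }
  out
}

# Forward pass; hidden layers logistic, output linear. Returns the
# activations of every layer (needed for backprop).
mlp_forward <- function(layers, x) {
  a <- list(x)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    z <- a[[i]] %*% layers[[i]]$w +
      matrix(layers[[i]]$b, nrow(x), length(layers[[i]]$b), byrow = TRUE)
    a[[i + 1L]] <- if (i < nl) logistic(z) else z
  }
  a
}

# Mean-squared-error loss and its analytic gradient, for stats::optim.
mlp_loss <- function(par, sizes, x, y) {
  layers <- mlp_unpack(par, sizes)
  a <- mlp_forward(layers, x)
  pred <- a[[length(a)]][, 1L]
  mean((pred - y)^2)
}

mlp_grad <- function(par, sizes, x, y) {
  layers <- mlp_unpack(par, sizes)
  a <- mlp_forward(layers, x)
  m <- nrow(x)
  nl <- length(layers)
  pred <- a[[nl + 1L]][, 1L]
  delta <- matrix(2 * (pred - y) / m, ncol = 1L)   # dL/dz at linear output
  grad <- numeric(length(par))
  off <- length(par)
  for (i in nl:1) {
    gw <- t(a[[i]]) %*% delta
    gb <- colSums(delta)
    nout <- length(gb)
    grad[(off - nout + 1L):off] <- gb
    off <- off - nout
    nw <- length(gw)
    grad[(off - nw + 1L):off] <- as.vector(gw)
    off <- off - nw
    if (i > 1L) {
      act <- a[[i]]
      delta <- (delta %*% t(layers[[i]]$w)) * act * (1 - act)
    }
  }
  grad
}

#' Neural autoregression signal extraction
#'
#' Trains a feed-forward network on lagged copies of the series: inputs
#' are the p previous values, hidden units apply the logistic function,
#' and the output is linear. Because the loss surface is multimodal, the
#' network is retrained from `n_restarts` random weight initialisations
#' and the extracted signal is the mean of the restarts' in-sample
#' predictions. The first p positions have no lagged predictors and carry
#' the observed values (zero residual) by convention.
#'
#' Inputs and targets are standardised before training and predictions
#' back-transformed. Defaults: p is the AIC-optimal linear AR order capped
#' at 8 (at least 1); the hidden layout is two layers of sizes
#' `(k, ceiling(k / 2))` with `k = ceiling((p + 1) / 2)`.
#'
#' @param series Numeric series (or [expression_profile()]).
#' @param n_lags_p Number of lags p; `NULL` selects it as above.
#' @param hidden_layout Integer vector of hidden-layer sizes; `NULL` gives
#'   the two-layer default.
#' @param n_restarts Number of random restarts (default 25).
#' @param seed Integer seed; restart r derives its own stream from
#'   `(seed, r)`.
#' @param positions Positions to attach to the extraction.
#' @param maxit BFGS iteration cap per restart.
#' @return A `baseline_fit` with model `"nn"`; `extraction$meta`
#'   records the layout and the per-restart in-sample RMSEs against the
#'   observed series.
#' @export
fit_nn_autoregression <- function(series, n_lags_p = NULL,
                                  hidden_layout = NULL, n_restarts = 25L,
                                  seed = 1L, positions = NULL,
                                  maxit = 300L) {
  if (inherits(series, "expression_profile")) {
    if (is.null(positions)) positions <- series$positions
    series <- series$intensities
  }
  y <- as.numeric(series)
  n <- length(y)
  if (is.null(positions)) positions <- seq_len(n)

  if (is.null(n_lags_p)) {
    ar_fit <- tryCatch(
      stats::ar(y, aic = TRUE, order.max = min(8L, n - 2L)),
      error = function(e) NULL)
    n_lags_p <- if (is.null(ar_fit)) 1L else max(1L, ar_fit$order)
  }
  p <- as.integer(n_lags_p)
  if (n <= p + 5L) stop("series too short for ", p, " lags")
  if (is.null(hidden_layout)) {
    k <- ceiling((p + 1) / 2)
    hidden_layout <- c(k, ceiling(k / 2))
  }
  hidden_layout <- as.integer(hidden_layout)
  if (any(hidden_layout < 1L)) stop("hidden layer sizes must be >= 1")
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("n_restarts must be >= 1")

  mu <- mean(y)
  sdy <- stats::sd(y)
  if (sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  m <- n - p
  X <- matrix(0, m, p)
  for (j in seq_len(p)) X[, j] <- ys[(p - j + 1L):(n - j)]
  tgt <- ys[(p + 1L):n]

  sizes <- c(p, hidden_layout, 1L)
  npar <- mlp_n_par(sizes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  preds <- matrix(NA_real_, m, n_restarts)
  ok <- logical(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(replicate_seed(seed, r))
    par0 <- stats::runif(npar, -0.7, 0.7)
    opt <- tryCatch(
      stats::optim(par0, mlp_loss, mlp_grad, sizes = sizes, x = X, y = tgt,
                   method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !all(is.finite(opt$par))) next
    layers <- mlp_unpack(opt$par, sizes)
    a <- mlp_forward(layers, X)
    preds[, r] <- a[[length(a)]][, 1L]
    ok[r] <- TRUE
  }
  if (!any(ok)) stop("all neural-network restarts failed to train")
  preds <- preds[, ok, drop = FALSE]

  back <- function(v) v * sdy + mu
  restart_rmse <- apply(preds, 2L, function(v)
    sqrt(mean((back(v) - y[(p + 1L):n])^2)))
  mean_pred <- back(rowMeans(preds))
  signal <- c(y[seq_len(p)], mean_pred)

  extraction <- signal_extraction(
    method = "nn", positions = positions,
    signal = signal, residual = y - signal,
    meta = list(p = p, hidden_layout = hidden_layout,
                n_restarts_trained = sum(ok),
                restart_rmse = restart_rmse, seed = seed)
  )
  new_baseline_fit(
    model = "nn",
    orders = list(p = p, hidden_layout = hidden_layout,
                  n_restarts = n_restarts),
    aic = NA_real_, extraction = extraction
  )
}
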