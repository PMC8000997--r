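# Layer primitives for the metric-embedding network.
#
# Batches are stored as 3-D arrays with dim c(channels, length, batch) so
# that the channel index varies fastest (column-major R layout); the
# convolution forward/backward passes then reduce to one matrix product
# per layer via an im2col expansion with a loop only over kernel taps.

#' One-dimensional convolution (flipped-kernel definition)
#'
#' Computes y_j = sum_i x_i * h_{j-i}: the kernel is flipped and slid along
#' the input, the textbook signal-processing convolution. The network's
#' convolutional layers use cross-correlation (no flip) as deep-learning
#' frameworks do; for learned kernels the two are equivalent up to a flip
#' of the kernel, and this standalone operator documents the relation.
#'
#' @param x input vector.
#' @param h kernel vector, `length(h) <= length(x)`.
#' @param mode `"full"` (length `length(x) + length(h) - 1`) or `"same"`
#'   (central crop to `length(x)`).
#' @return The convolved sequence.
#' @export
#' @examples
#' conv1d_forward(c(1, 2, 3), c(1, 2))        # 1 4 7 6
conv1d_forward <- function(x, h, mode = c("full", "same")) {
  mode <- match.arg(mode)
  if (length(h) == 0) stop("kernel must be non-empty")
  if (length(h) > length(x)) stop("kernel longer than input")
  nx <- length(x); nh <- length(h)
  y <- numeric(nx + nh - 1)
  for (i in seq_len(nh)) {
    y[i:(i + nx - 1)] <- y[i:(i + nx - 1)] + h[i] * x
  }
  if (mode == "same") {
    start <- (nh - 1) %/% 2 + 1
    y <- y[start:(start + nx - 1)]
  }
  y
}

#' Batch normalization over a batch of vectors
#'
#' In train mode, normalizes with the batch mean and (population) variance
#' and updates exponential running statistics; in eval mode, normalizes
#' with the running statistics. Then scales and shifts by the learnable
#' gamma and beta.
#'
#' @param X numeric matrix, one observation per row (single channel).
#' @param gamma,beta scale and shift parameters.
#' @param eps numerical-stability constant.
#' @param mode `"train"` or `"eval"`.
#' @param running list with `mean` and `var`, used/updated across calls.
#' @param momentum running-statistics update weight.
#' @return List with `out` (same shape as `X`) and updated `running`.
#' @export
#' @examples
#' batchnorm_forward(matrix(c(1, 2, 3)))$out
batchnorm_forward <- function(X, gamma = 1, beta = 0, eps = 1e-5,
                              mode = c("train", "eval"),
                              running = list(mean = 0, var = 1),
                              momentum = 0.1) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  m <- length(X)
  if (mode == "train") {
    if (m < 2) stop("train-mode batch normalization needs at least 2 values")
    mu <- mean(X)
    v <- mean((X - mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  list(out = gamma * (X - mu) / sqrt(v + eps) + beta, running = running)
}

#' Parametric rectified linear unit
#'
#' `max(0, y) + a * min(0, y)`; the negative slope `a` is a learnable
#' parameter in the network (initialised at 0.25). `a = 0` reduces to ReLU.
#'
#' @param y numeric input (vectorised).
#' @param a negative slope.
#' @return Activated values.
#' @export
#' @examples
#' prelu(c(2, -2), a = 0.25)
prelu <- function(y, a = 0.25) {
  pmax(y, 0) + a * pmin(y, 0)
}

# ---- internal network layers (cross-correlation, with backward passes) ----

# im2col: X (C_in, L, B), zero 'same' padding, kernel size k ->
# M ((C_in * k), (L * B)) with M[(u-1)*C_in + c, ] = Xpad[c, t + u - 1, b].
im2col <- function(X, k) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  p <- (k - 1) %/% 2
  Xp <- array(0, dim = c(C, L + 2 * p, B))
  Xp[, (p + 1):(p + L), ] <- X
  M <- matrix(0, nrow = C * k, ncol = L * B)
  for (u in seq_len(k)) {
    M[((u - 1) * C + 1):(u * C), ] <- Xp[, u:(u + L - 1), , drop = FALSE]
  }
  M
}

col2im <- function(dM, C, L, B, k) {
  p <- (k - 1) %/% 2
  dXp <- array(0, dim = c(C, L + 2 * p, B))
  for (u in seq_len(k)) {
    slice <- array(dM[((u - 1) * C + 1):(u * C), ], dim = c(C, L, B))
    dXp[, u:(u + L - 1), ] <- dXp[, u:(u + L - 1), , drop = FALSE] + slice
  }
  dXp[, (p + 1):(p + L), , drop = FALSE]
}

# W: (C_in * k) x C_out matrix; b: length C_out.
nn_conv_forward <- function(X, W, b, k) {
  d <- dim(X)
  M <- im2col(X, k)
  Y <- crossprod(W, M) + b        # (C_out, L * B)
  list(out = array(Y, dim = c(length(b), d[2], d[3])),
       cache = list(M = M, dims = d, k = k))
}

nn_conv_backward <- function(dY, W, cache) {
  d <- cache$dims
  C_out <- ncol(W)
  dYm <- matrix(dY, nrow = C_out)
  dW <- tcrossprod(cache$M, dYm)  # (C_in*k, C_out)
  db <- rowSums(dYm)
  dM <- W %*% dYm
  dX <- col2im(dM, d[1], d[2], d[3], cache$k)
  list(dX = dX, dW = dW, db = db)
}

# Per-channel batch normalization on (C, L, B) arrays.
nn_bn_forward <- function(X, gamma, beta, running_mean, running_var,
                          mode, eps = 1e-5, momentum = 0.1) {
  d <- dim(X)
  Xm <- matrix(X, nrow = d[1])    # (C, L * B)
  if (mode == "train") {
    if (d[3] * d[2] < 2) stop("batch too small for train-mode batch norm")
    mu <- rowMeans(Xm)
    v <- rowMeans((Xm - mu)^2)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  Xhat <- (Xm - mu) * inv_sd
  out <- array(gamma * Xhat + beta, dim = d)
  list(out = out,
       cache = list(Xhat = Xhat, inv_sd = inv_sd, dims = d),
       running_mean = running_mean, running_var = running_var)
}

nn_bn_backward <- function(dY, gamma, cache) {
  d <- cache$dims
  m <- d[2] * d[3]
  dYm <- matrix(dY, nrow = d[1])
  dgamma <- rowSums(dYm * cache$Xhat)
  dbeta <- rowSums(dYm)
  # standard batchnorm backward, per channel
  dXhat <- dYm * gamma
  dX <- cache$inv_sd *
    (dXhat - rowMeans(dXhat) - cache$Xhat * rowMeans(dXhat * cache$Xhat))
  list(dX = array(dX, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# PReLU with one learnable slope per channel; X is (C, L, B).
nn_prelu_forward <- function(X, a) {
  d <- dim(X)
  Xm <- matrix(X, nrow = d[1])
  out <- pmax(Xm, 0) + a * pmin(Xm, 0)
  list(out = array(out, dim = d), cache = list(Xm = Xm, dims = d))
}

nn_prelu_backward <- function(dY, a, cache) {
  d <- cache$dims
  dYm <- matrix(dY, nrow = d[1])
  neg <- cache$Xm < 0
  dX <- dYm * ifelse(neg, a, 1)
  da <- rowSums(dYm * cache$Xm * neg)
  list(dX = array(dX, dim = d), da = da)
}

# Pooling, window 2, stride 2; trailing odd sample dropped (floor(L/2)).
nn_pool_forward <- function(X, type = c("max", "average")) {
  type <- match.arg(type)
  d <- dim(X)
  Lo <- d[2] %/% 2
  A <- X[, seq(1, 2 * Lo, by = 2), , drop = FALSE]
  Bm <- X[, seq(2, 2 * Lo, by = 2), , drop = FALSE]
  if (type == "max") {
    takeA <- A >= Bm
    out <- ifelse(takeA, A, Bm)
    cache <- list(takeA = takeA, dims = d, Lo = Lo, type = type)
  } else {
    out <- (A + Bm) / 2
    cache <- list(dims = d, Lo = Lo, type = type)
  }
  list(out = out, cache = cache)
}

nn_pool_backward <- function(dY, cache) {
  d <- cache$dims; Lo <- cache$Lo
  dX <- array(0, dim = d)
  if (cache$type == "max") {
    dX[, seq(1, 2 * Lo, by = 2), ] <- dY * cache$takeA
    dX[, seq(2, 2 * Lo, by = 2), ] <- dY * !cache$takeA
  } else {
    dX[, seq(1, 2 * Lo, by = 2), ] <- dY / 2
    dX[, seq(2, 2 * Lo, by = 2), ] <- dY / 2
  }
  dX
}
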