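test_that("convolution matches worked examples and the brute-force oracle", {
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 2)), c(1, 4, 7, 6))
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 1)), c(1, 3, 5, 3))
  x <- rnorm(20)
  expect_equal(conv1d_forward(x, 1), x)
  expect_error(conv1d_forward(x, numeric(0)), "non-empty")

  set.seed(42)
  for (rep in 1:100) {
    nx <- sample(3:20, 1)
    nh <- sample(1:nx, 1)
    x <- rnorm(nx); h <- rnorm(nh)
    full <- conv1d_forward(x, h, "full")
    expect_equal(full, conv_bruteforce(x, h), tolerance = 1e-12)
    expect_length(full, nx + nh - 1)
    same <- conv1d_forward(x, h, "same")
    start <- (nh - 1) %/% 2 + 1
    expect_equal(same, full[start:(start + nx - 1)])
  }
})

test_that("batch normalization matches its defining equations", {
  out <- batchnorm_forward(matrix(c(1, 2, 3)))$out
  # reference value rounded from single-precision arithmetic; the exact
  # double-precision result is -1.2247357
  expect_equal(as.numeric(out), c(-1.224734, 0, 1.224734), tolerance = 1e-5)

  # gamma = 0 collapses to beta
  expect_equal(as.numeric(batchnorm_forward(matrix(rnorm(8)), gamma = 0,
                                            beta = 2.5)$out),
               rep(2.5, 8))

  # near-identity on standardized input
  set.seed(1)
  x <- rnorm(500); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_lt(max(abs(batchnorm_forward(matrix(x))$out - x)), 1e-4)

  expect_error(batchnorm_forward(matrix(1), mode = "train"), "at least 2")

  # eval mode uses running statistics, not the batch
  ev <- batchnorm_forward(matrix(c(10, 20)), mode = "eval",
                          running = list(mean = 0, var = 1))
  expect_equal(as.numeric(ev$out), c(10, 20), tolerance = 1e-4)
})

test_that("PReLU follows max(0,y) + a*min(0,y)", {
  expect_equal(prelu(2, 0.25), 2)
  expect_equal(prelu(-2, 0.25), -0.5)
  expect_equal(prelu(-2, 0), 0)
  y <- rnorm(50)
  expect_equal(prelu(y, 0.3), pmax(y, 0) + 0.3 * pmin(y, 0))
})

test_that("train-mode batch norm standardizes each channel", {
  set.seed(7)
  X <- array(rnorm(3 * 20 * 8, mean = 2, sd = 3), dim = c(3, 20, 8))
  g <- c(1.5, 1, 0.5); b <- c(0, 1, -1)
  out <- pvcmetric:::nn_bn_forward(X, g, b, rep(0, 3), rep(1, 3),
                                   mode = "train")$out
  m <- matrix(out, nrow = 3)
  expect_equal(rowMeans(m), b, tolerance = 1e-3)
  expect_equal(sqrt(rowMeans((m - b)^2)), abs(g), tolerance = 1e-3)
})

test_that("pooling halves the length along the published trajectory", {
  expect_identical(embedder_config()$trajectory,
                   c(216L, 108L, 54L, 27L, 13L, 6L, 3L, 1L))
  expect_error(embedder_config(channels = c(4, 4), kernel_sizes = c(5, 5),
                               input_length = 3),
               "too short")
})

test_that("network layer gradients match finite differences", {
  # spot-check the backward passes that training relies on
  set.seed(5)
  X <- array(rnorm(2 * 6 * 3), dim = c(2, 6, 3))
  k <- 3
  W <- matrix(rnorm(2 * k * 2, sd = 0.5), nrow = 2 * k)
  b <- rnorm(2)
  loss_of <- function(W) {
    out <- pvcmetric:::nn_conv_forward(X, W, b, k)$out
    sum(out^2)
  }
  fw <- pvcmetric:::nn_conv_forward(X, W, b, k)
  bk <- pvcmetric:::nn_conv_backward(2 * fw$out, W, fw$cache)
  eps <- 1e-6
  for (idx in c(1, 4, 7)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    expect_equal(bk$dW[idx], (loss_of(Wp) - loss_of(Wm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  # input gradient
  loss_x <- function(X) sum(pvcmetric:::nn_conv_forward(X, W, b, k)$out^2)
  for (idx in c(2, 11, 30)) {
    Xp <- X; Xp[idx] <- Xp[idx] + eps
    Xm <- X; Xm[idx] <- Xm[idx] - eps
    expect_equal(bk$dX[idx], (loss_x(Xp) - loss_x(Xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("a reduced forward pass equals a hand-rolled layer composition", {
  # 2-group embedder on a 16-sample toy input, eval mode, checked against
  # an oracle composed from the standalone layer operations
  cfg <- embedder_config(channels = c(2, 2), kernel_sizes = c(3, 3),
                         input_length = 16)
  model <- build_embedder(cfg, seed = 9)
  x <- sin(seq(0, 3, length.out = 16))
  E <- pvcmetric:::embedder_forward(model, matrix(x, nrow = 1), "eval")$E

  # oracle: cross-correlation = flipped-kernel convolution with rev(h)
  xcorr_same <- function(x, h) conv1d_forward(x, rev(h), "same")
  p <- model$params
  act <- list(x)  # channel list
  for (tag in c("g1_1", "g1_2", "g2_1", "g2_2")) {
    W <- p[[paste0(tag, "_W")]]
    cin <- length(act); k <- nrow(W) / cin
    outs <- list()
    for (co in 1:ncol(W)) {
      acc <- rep(p[[paste0(tag, "_b")]][co], length(act[[1]]))
      for (ci in seq_len(cin)) {
        taps <- W[seq(ci, by = cin, length.out = k), co]
        acc <- acc + xcorr_same(act[[ci]], taps)
      }
      # eval-mode batch norm with initial running stats (mean 0, var 1)
      acc <- batchnorm_forward(matrix(acc), gamma = p[[paste0(tag, "_gamma")]][co],
                               beta = p[[paste0(tag, "_beta")]][co],
                               mode = "eval")$out
      outs[[co]] <- prelu(as.numeric(acc), p[[paste0(tag, "_a")]][co])
    }
    act <- outs
    if (tag %in% c("g1_2", "g2_2")) {
      act <- lapply(act, function(v) {
        n2 <- (length(v) %/% 2) * 2
        pmax(v[seq(1, n2, by = 2)], v[seq(2, n2, by = 2)])
      })
    }
  }
  oracle <- vapply(act, mean, numeric(1))  # time-averaged embedding
  expect_equal(as.numeric(E), oracle, tolerance = 1e-10)
})
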