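# The metric-embedding network: stacked convolutional groups mapping a
# fixed-length heartbeat to an F-dimensional feature vector, trained with
# the mined triplet margin loss.

#' Specification of one convolutional group
#'
#' A group is conv -> batch norm -> PReLU -> conv -> batch norm -> PReLU ->
#' pool(2, stride 2). Both convolutions share the kernel size and channel
#' count; 'same' zero padding keeps the temporal length unchanged, so only
#' the pool halves it.
#'
#' @param channels number of kernels (output channels), >= 1.
#' @param kernel_size odd kernel length in samples.
#' @param pool `"max"` or `"average"`.
#' @return Object of class `conv_group_spec`.
#' @export
conv_group_spec <- function(channels, kernel_size, pool = c("max", "average")) {
  pool <- match.arg(pool)
  if (channels < 1) stop("channels must be >= 1")
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  structure(list(channels = channels, kernel_size = kernel_size, pool = pool),
            class = "conv_group_spec")
}

#' Embedding network configuration
#'
#' The default is the eight-group architecture: with 'same'-padded
#' convolutions and pool size 2, a 433-sample beat shrinks along
#' 433 -> 216 -> 108 -> 54 -> 27 -> 13 -> 6 -> 3 -> 1, and the embedding is
#' the channel activations at the single remaining time step, so the
#' feature count F equals the last group's kernel count (default 32).
#' Fewer groups are allowed for scaled-down models; if the final temporal
#' length exceeds 1 the activations are averaged over time.
#'
#' @param channels integer vector of per-group kernel counts; the last
#'   entry is the feature dimension F.
#' @param kernel_sizes odd kernel sizes, same length as `channels`.
#' @param pool pooling type used by every group, `"max"` or `"average"`.
#' @param input_length beat length in samples (default 433).
#' @return Object of class `embedder_config` with `groups`,
#'   `feature_dim`, `input_length` and the pooled length trajectory.
#' @export
#' @examples
#' embedder_config()$trajectory           # 216 108 54 27 13 6 3 1
#' embedder_config(channels = c(8, 8, 8), kernel_sizes = c(17, 9, 5))
embedder_config <- function(channels = c(32, 32, 64, 64, 128, 128, 32, 32),
                            kernel_sizes = c(33, 17, 17, 9, 9, 5, 5, 3),
                            pool = c("max", "average"),
                            input_length = 433) {
  pool <- match.arg(pool)
  if (length(channels) != length(kernel_sizes))
    stop("channels and kernel_sizes must have the same length")
  groups <- mapply(conv_group_spec, channels, kernel_sizes,
                   MoreArgs = list(pool = pool), SIMPLIFY = FALSE)
  L <- as.integer(input_length)
  trajectory <- integer(length(groups))
  for (i in seq_along(groups)) {
    L <- L %/% 2L
    trajectory[i] <- L
  }
  if (L < 1)
    stop("input_length too short for ", length(groups), " pooling stages")
  structure(list(groups = groups,
                 feature_dim = channels[length(channels)],
                 input_length = input_length,
                 trajectory = trajectory),
            class = "embedder_config")
}

#' Training configuration for the embedder
#'
#' Defaults follow the selected operating point: batch size 32, cosine
#' triplet margin 0.1 with miner slack epsilon 0, Adam at learning rate
#' 1e-4 with no weight decay. Training stops early when the epoch loss
#' stops improving.
#'
#' @param batch_size mini-batch size.
#' @param margin triplet loss margin, > 0.
#' @param epsilon miner slack, >= 0.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient.
#' @param epochs maximum number of epochs.
#' @param patience epochs without loss improvement before stopping.
#' @param seed integer seed for weight init and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, margin = 0.1, epsilon = 0,
                         learning_rate = 1e-4, weight_decay = 0,
                         epochs = 40, patience = 5, seed = 1) {
  if (margin <= 0) stop("margin must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(batch_size = batch_size, margin = margin, epsilon = epsilon,
                 optimizer = "adam", learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = epochs,
                 patience = patience, seed = seed),
            class = "train_config")
}

#' Build an untrained embedder
#'
#' Weights use uniform fan-in initialisation, batch-norm scale/shift start
#' at 1/0, PReLU slopes at 0.25.
#'
#' @param config an [embedder_config()].
#' @param seed integer seed for the weight draw.
#' @return Object of class `embedder` holding parameters, running
#'   batch-norm statistics and the config.
#' @export
build_embedder <- function(config = embedder_config(), seed = 1) {
  stopifnot(inherits(config, "embedder_config"))
  with_seed(seed, {
    params <- list()
    running <- list()
    c_in <- 1
    for (i in seq_along(config$groups)) {
      g <- config$groups[[i]]
      for (half in 1:2) {
        cin <- if (half == 1) c_in else g$channels
        fan_in <- cin * g$kernel_size
        bound <- 1 / sqrt(fan_in)
        tag <- paste0("g", i, "_", half)
        params[[paste0(tag, "_W")]] <-
          matrix(stats::runif(fan_in * g$channels, -bound, bound),
                 nrow = fan_in)
        params[[paste0(tag, "_b")]] <- rep(0, g$channels)
        params[[paste0(tag, "_gamma")]] <- rep(1, g$channels)
        params[[paste0(tag, "_beta")]] <- rep(0, g$channels)
        params[[paste0(tag, "_a")]] <- rep(0.25, g$channels)
        running[[paste0(tag, "_mean")]] <- rep(0, g$channels)
        running[[paste0(tag, "_var")]] <- rep(1, g$channels)
      }
      c_in <- g$channels
    }
    structure(list(params = params, running = running, config = config),
              class = "embedder")
  })
}

#' @export
print.embedder <- function(x, ...) {
  ch <- vapply(x$config$groups, `[[`, numeric(1), "channels")
  cat(sprintf(
    "<embedder> %d groups (channels %s), F = %d, input length %d\n",
    length(ch), paste(ch, collapse = "-"), x$config$feature_dim,
    x$config$input_length))
  invisible(x)
}

# Forward pass. X: (n x input_length) matrix. Returns embeddings (n x F),
# layer caches (train mode) and the model with updated running stats.
embedder_forward <- function(model, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  cfg <- model$config
  if (ncol(X) != cfg$input_length)
    stop("beat length ", ncol(X), " != configured input_length ",
         cfg$input_length)
  B <- nrow(X)
  A <- array(t(X), dim = c(1, cfg$input_length, B))
  caches <- list()
  p <- model$params
  for (i in seq_along(cfg$groups)) {
    g <- cfg$groups[[i]]
    for (half in 1:2) {
      tag <- paste0("g", i, "_", half)
      cv <- nn_conv_forward(A, p[[paste0(tag, "_W")]],
                            p[[paste0(tag, "_b")]], g$kernel_size)
      bn <- nn_bn_forward(cv$out, p[[paste0(tag, "_gamma")]],
                          p[[paste0(tag, "_beta")]],
                          model$running[[paste0(tag, "_mean")]],
                          model$running[[paste0(tag, "_var")]], mode)
      if (mode == "train") {
        model$running[[paste0(tag, "_mean")]] <- bn$running_mean
        model$running[[paste0(tag, "_var")]] <- bn$running_var
      }
      pr <- nn_prelu_forward(bn$out, p[[paste0(tag, "_a")]])
      caches[[paste0(tag, "_conv")]] <- cv$cache
      caches[[paste0(tag, "_bn")]] <- bn$cache
      caches[[paste0(tag, "_prelu")]] <- pr$cache
      A <- pr$out
    }
    pl <- nn_pool_forward(A, g$pool)
    caches[[paste0("g", i, "_pool")]] <- pl$cache
    A <- pl$out
  }
  d <- dim(A)  # (F, L_final, B)
  E <- if (d[2] == 1) t(matrix(A, nrow = d[1])) else
    t(apply(A, c(1, 3), mean))
  list(E = E, caches = caches, model = model, out_dim = d)
}

# Backward pass from dE (n x F) to parameter gradients.
embedder_backward <- function(model, caches, dE, out_dim) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  dA <- if (out_dim[2] == 1) {
    array(t(dE), dim = out_dim)
  } else {
    # embedding averaged over time: spread gradient uniformly
    big <- array(0, dim = out_dim)
    for (l in seq_len(out_dim[2])) big[, l, ] <- t(dE) / out_dim[2]
    big
  }
  for (i in rev(seq_along(cfg$groups))) {
    g <- cfg$groups[[i]]
    dA <- nn_pool_backward(dA, caches[[paste0("g", i, "_pool")]])
    for (half in 2:1) {
      tag <- paste0("g", i, "_", half)
      pr <- nn_prelu_backward(dA, p[[paste0(tag, "_a")]],
                              caches[[paste0(tag, "_prelu")]])
      grads[[paste0(tag, "_a")]] <- pr$da
      bn <- nn_bn_backward(pr$dX, p[[paste0(tag, "_gamma")]],
                           caches[[paste0(tag, "_bn")]])
      grads[[paste0(tag, "_gamma")]] <- bn$dgamma
      grads[[paste0(tag, "_beta")]] <- bn$dbeta
      cv <- nn_conv_backward(bn$dX, p[[paste0(tag, "_W")]],
                             caches[[paste0(tag, "_conv")]])
      grads[[paste0(tag, "_W")]] <- cv$dW
      grads[[paste0(tag, "_b")]] <- cv$db
      dA <- cv$dX
    }
  }
  grads
}

#' Train the embedder with mined triplet margin loss
#'
#' Per epoch: shuffle, split into mini-batches, embed (train-mode batch
#' norm), mine pairs with the multi-similarity rule, average the triplet
#' margin loss over active triples, backpropagate, and take an Adam step.
#' Training stops early once the epoch loss has not improved for
#' `patience` epochs. With a fixed seed the loss history is reproducible.
#'
#' @param beats a [heartbeat_set()] containing both classes (beats should
#'   already be amplitude-normalised, see [normalize_beats()]).
#' @param cfg a [train_config()].
#' @param ecfg an [embedder_config()] matching the beat window length.
#' @return The trained `embedder`; `$history` holds per-epoch mean loss
#'   and mined-triplet counts.
#' @export
train_embedder <- function(beats, cfg = train_config(),
                           ecfg = embedder_config(window_of(beats))) {
  stopifnot(inherits(beats, "heartbeat_set"), inherits(cfg, "train_config"))
  labels <- as.character(beats$label)
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes (no negative pairs ",
         "can be mined from a single class)")
  X <- beats$samples
  model <- build_embedder(ecfg, seed = cfg$seed)
  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        n_triplets = integer(0))
  best <- Inf; stall <- 0
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(X))
      losses <- c(); tripcount <- 0
      starts <- seq(1, length(ord), by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        if (length(idx) < 2) next
        fw <- embedder_forward(model, X[idx, , drop = FALSE], "train")
        model <- fw$model
        bl <- batch_loss_grad(fw$E, labels[idx], cfg$margin, cfg$epsilon)
        losses <- c(losses, bl$loss)
        tripcount <- tripcount + bl$n_triplets
        if (bl$n_triplets == 0 || all(bl$grad == 0)) next
        grads <- embedder_backward(model, fw$caches, bl$grad, fw$out_dim)
        adam$t <- adam$t + 1
        for (nm in names(grads)) {
          gr <- grads[[nm]]
          if (cfg$weight_decay > 0) gr <- gr + cfg$weight_decay *
              model$params[[nm]]
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * gr
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * gr^2
          mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
          vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      epoch_loss <- mean(losses)
      history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                           n_triplets = tripcount))
      if (epoch_loss < best - 1e-6) {
        best <- epoch_loss
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= cfg$patience) break
      }
    }
  })
  model$history <- history
  model$train_config <- cfg
  model
}

window_of <- function(beats) {
  stopifnot(inherits(beats, "heartbeat_set"))
  beats$window
}

#' Embed heartbeats with a trained model
#'
#' Deterministic eval-mode forward pass (running batch-norm statistics).
#'
#' @param beats a [heartbeat_set()] or a numeric matrix of beats (rows).
#' @param model a trained `embedder`.
#' @param chunk beats per forward pass (memory control).
#' @return Numeric matrix, one length-F embedding per row.
#' @export
embed <- function(beats, model, chunk = 512) {
  stopifnot(inherits(model, "embedder"))
  X <- if (inherits(beats, "heartbeat_set")) beats$samples else
    as.matrix(beats)
  if (ncol(X) != model$config$input_length)
    stop("beat length ", ncol(X), " != configured input_length ",
         model$config$input_length)
  out <- matrix(0, nrow(X), model$config$feature_dim)
  starts <- seq(1, nrow(X), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1, nrow(X))
    out[idx, ] <- embedder_forward(model, X[idx, , drop = FALSE], "eval")$E
  }
  out
}
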