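# Independent brute-force oracles. Each is a literal transcription of the
# defining equations with plain loops, kept free of the package's
# vectorised code paths.

# Flipped-kernel convolution: y_j = sum_i x_i * h_{j-i}.
conv_bruteforce <- function(x, h) {
  nx <- length(x); nh <- length(h)
  y <- numeric(nx + nh - 1)
  for (j in seq_along(y)) {
    acc <- 0
    for (i in seq_len(nx)) {
      k <- j - i + 1
      if (k >= 1 && k <= nh) acc <- acc + x[i] * h[k]
    }
    y[j] <- acc
  }
  y
}

# Multi-similarity pair selection by exhaustive scan.
mine_bruteforce <- function(E, labels, epsilon) {
  n <- nrow(E)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) S[i, j] <- cosine_similarity(E[i, ], E[j, ])
  pos <- vector("list", n); neg <- vector("list", n)
  for (i in 1:n) {
    same <- setdiff(which(labels == labels[i]), i)
    diff <- which(labels != labels[i])
    pos[[i]] <- integer(0); neg[[i]] <- integer(0)
    if (length(same) == 0 || length(diff) == 0) next
    for (j in diff) if (S[i, j] > min(S[i, same]) - epsilon)
      neg[[i]] <- c(neg[[i]], j)
    for (j in same) if (S[i, j] < max(S[i, diff]) + epsilon)
      pos[[i]] <- c(pos[[i]], j)
  }
  list(pos = pos, neg = neg, S = S)
}

# Mean triplet margin loss over exhaustively enumerated triples.
loss_bruteforce <- function(E, labels, margin, epsilon) {
  m <- mine_bruteforce(E, labels, epsilon)
  losses <- c(); n_tri <- 0
  for (a in seq_len(nrow(E))) {
    for (p in m$pos[[a]]) for (ng in m$neg[[a]]) {
      n_tri <- n_tri + 1
      losses <- c(losses, max((m$S[a, ng] - m$S[a, p]) + margin, 0))
    }
  }
  active <- losses[losses > 0]
  list(loss = if (length(active) > 0) mean(active) else 0,
       n_triplets = n_tri)
}

# KNN by sorting every cosine distance, even vote splits broken by the
# nearest neighbour.
knn_bruteforce <- function(train_emb, train_labels, query_emb, K) {
  out <- character(nrow(query_emb))
  for (q in seq_len(nrow(query_emb))) {
    d <- numeric(nrow(train_emb))
    for (i in seq_len(nrow(train_emb)))
      d[i] <- 1 - cosine_similarity(query_emb[q, ], train_emb[i, ])
    nb <- order(d)[1:K]
    tab <- table(train_labels[nb])
    winners <- names(tab)[tab == max(tab)]
    out[q] <- if (length(winners) == 1) winners else train_labels[nb[1]]
  }
  out
}

# Mean within-class minus mean between-class cosine similarity.
cosine_gap <- function(E, labels) {
  Z <- E / sqrt(rowSums(E^2))
  S <- tcrossprod(Z)
  same <- outer(labels, labels, "==") & upper.tri(S)
  diff <- outer(labels, labels, "!=") & upper.tri(S)
  mean(S[same]) - mean(S[diff])
}
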