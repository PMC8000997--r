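# Cosine similarity, multi-similarity pair mining, and the triplet margin
# loss -- the mathematical core of the metric-learning objective.

#' Cosine similarity of two vectors
#'
#' @param x,y numeric vectors of equal length with non-zero norm.
#' @return `(x . y) / (|x| |y|)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1)) # 1/sqrt(2)
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for zero vectors")
  sum(x * y) / (nx * ny)
}

# Row-normalize an embedding matrix and return the full similarity matrix.
cosine_sim_matrix <- function(E) {
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for zero vectors")
  Z <- E / nrm
  S <- tcrossprod(Z)
  list(S = S, Z = Z, nrm = nrm)
}

#' Multi-similarity pair mining
#'
#' For each anchor i, a cross-class point j is selected as a negative if
#' its similarity exceeds the anchor's hardest (lowest) same-class
#' similarity minus epsilon; a same-class point j is selected as a positive
#' if its similarity falls below the anchor's hardest (highest) cross-class
#' similarity plus epsilon. Self-pairs are excluded. Anchors lacking a
#' same-class or cross-class partner select nothing on the affected side.
#'
#' @param embeddings numeric matrix, one embedding per row (L2-normalised
#'   internally before similarities are taken).
#' @param labels class label per row.
#' @param epsilon non-negative slack; larger values admit more pairs.
#' @return Object of class `mined_pairs`: list with per-anchor integer
#'   vectors `pos` and `neg`, and `single_class` flag set when no
#'   cross-class pair exists at all.
#' @export
mine_pairs <- function(embeddings, labels, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  E <- as.matrix(embeddings)
  n <- nrow(E)
  if (length(labels) != n) stop("labels length must match embeddings")
  S <- cosine_sim_matrix(E)$S
  labels <- as.character(labels)
  pos <- vector("list", n)
  neg <- vector("list", n)
  single_class <- length(unique(labels)) < 2
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- same[same != i]
    diff <- which(labels != labels[i])
    if (length(same) > 0 && length(diff) > 0) {
      hardest_pos <- min(S[i, same])
      hardest_neg <- max(S[i, diff])
      neg[[i]] <- diff[S[i, diff] > hardest_pos - epsilon]
      pos[[i]] <- same[S[i, same] < hardest_neg + epsilon]
    } else {
      pos[[i]] <- integer(0)
      neg[[i]] <- integer(0)
    }
  }
  structure(list(pos = pos, neg = neg, single_class = single_class),
            class = "mined_pairs")
}

#' Triplet margin loss on similarities
#'
#' `max{(s_an - s_ap) + margin, 0}`: zero once the anchor-positive
#' similarity beats the anchor-negative similarity by at least the margin.
#'
#' @param s_ap anchor-positive similarity (vectorised).
#' @param s_an anchor-negative similarity (vectorised).
#' @param margin required similarity gap, > 0.
#' @return Non-negative loss value(s).
#' @export
#' @examples
#' triplet_margin_loss(0.9, 0.2, margin = 0.1) # 0
triplet_margin_loss <- function(s_ap, s_an, margin) {
  if (margin <= 0) stop("margin must be > 0")
  pmax((s_an - s_ap) + margin, 0)
}

# Enumerate all (anchor, positive, negative) triples from mined pairs.
triplets_from_pairs <- function(mined) {
  n <- length(mined$pos)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- mined$pos[[i]]; ng <- mined$neg[[i]]
    if (length(p) > 0 && length(ng) > 0) {
      grid <- expand.grid(p = p, n = ng, KEEP.OUT.ATTRS = FALSE)
      out[[i]] <- cbind(a = i, p = grid$p, n = grid$n)
    }
  }
  do.call(rbind, out)
}

#' Mean triplet margin loss over a mined batch
#'
#' Mines pairs, enumerates every (anchor, positive, negative) triple, and
#' averages the triplet margin loss over the triples with non-zero loss
#' (the convention of the miner-plus-loss pairing: satisfied triples do not
#' dilute the mean). Returns 0 when no triples are mined.
#'
#' @param embeddings numeric matrix, one embedding per row.
#' @param labels class label per row.
#' @param margin loss margin, > 0.
#' @param epsilon miner slack, >= 0.
#' @return List with `loss` and `n_triplets` (all mined triples).
#' @export
batch_loss <- function(embeddings, labels, margin = 0.1, epsilon = 0) {
  res <- batch_loss_grad(embeddings, labels, margin, epsilon,
                         want_grad = FALSE)
  list(loss = res$loss, n_triplets = res$n_triplets)
}

# Loss plus gradient with respect to the raw (unnormalised) embeddings.
batch_loss_grad <- function(embeddings, labels, margin, epsilon,
                            want_grad = TRUE) {
  E <- as.matrix(embeddings)
  sim <- cosine_sim_matrix(E)
  S <- sim$S; Z <- sim$Z
  mined <- mine_pairs(E, labels, epsilon)
  tri <- triplets_from_pairs(mined)
  if (is.null(tri) || nrow(tri) == 0) {
    return(list(loss = 0, n_triplets = 0L,
                grad = if (want_grad) matrix(0, nrow(E), ncol(E))))
  }
  l <- triplet_margin_loss(S[tri[, c("a", "p"), drop = FALSE]],
                           S[tri[, c("a", "n"), drop = FALSE]], margin)
  active <- l > 0
  m_active <- sum(active)
  loss <- if (m_active > 0) mean(l[active]) else 0
  grad <- NULL
  if (want_grad) {
    dZ <- matrix(0, nrow(E), ncol(E))
    if (m_active > 0) {
      w <- 1 / m_active
      act <- tri[active, , drop = FALSE]
      # dl/ds_an = +w, dl/ds_ap = -w; s_ij = Z_i . Z_j, accumulated by row
      add_by <- function(dZ, M, idx) {
        rs <- rowsum(M, idx)
        rows <- as.integer(rownames(rs))
        dZ[rows, ] <- dZ[rows, , drop = FALSE] + rs
        dZ
      }
      dZ <- add_by(dZ, w * (Z[act[, "n"], , drop = FALSE] -
                              Z[act[, "p"], , drop = FALSE]), act[, "a"])
      dZ <- add_by(dZ, w * Z[act[, "a"], , drop = FALSE], act[, "n"])
      dZ <- add_by(dZ, -w * Z[act[, "a"], , drop = FALSE], act[, "p"])
    }
    # back through row normalization: dE_i = (dZ_i - Z_i (Z_i . dZ_i))/|E_i|
    inner <- rowSums(dZ * Z)
    grad <- (dZ - Z * inner) / sim$nrm
  }
  list(loss = loss, n_triplets = nrow(tri), grad = grad)
}
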