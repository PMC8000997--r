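# KNN classification over embeddings and the five confusion-matrix
# metrics, plus the sweep harnesses for the ablation experiments.

#' K-nearest-neighbour prediction over embeddings
#'
#' Distance is `1 - cosine similarity` by default, matching the geometry
#' the embedder was trained in; Euclidean distance is available by flag.
#' `K = 1` returns the nearest neighbour's label; `K > 1` takes a majority
#' vote among the K nearest, with an even split broken by the nearest
#' neighbour's label (consistent with the K = 1 limit).
#'
#' @param train_emb matrix of training embeddings (rows).
#' @param train_labels class label per training row.
#' @param query_emb matrix of query embeddings (rows).
#' @param K number of votes, `1 <= K <= nrow(train_emb)`.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_emb, train_labels, query_emb, K = 1,
                        metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  train_emb <- as.matrix(train_emb); query_emb <- as.matrix(query_emb)
  if (nrow(train_emb) == 0) stop("empty training set")
  if (K < 1 || K > nrow(train_emb))
    stop("K must be between 1 and the number of training points")
  train_labels <- as.character(train_labels)
  if (metric == "cosine") {
    nt <- sqrt(rowSums(train_emb^2)); nq <- sqrt(rowSums(query_emb^2))
    if (any(nt == 0) || any(nq == 0))
      stop("cosine distance undefined for zero vectors")
    D <- 1 - tcrossprod(query_emb / nq, train_emb / nt)
  } else {
    D <- outer(rowSums(query_emb^2), rowSums(train_emb^2), `+`) -
      2 * tcrossprod(query_emb, train_emb)
  }
  apply(D, 1, function(d) {
    nb <- order(d)[seq_len(K)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else train_labels[nb[1]]
  })
}

#' Confusion matrix with PVC as the positive class
#'
#' @param true_labels,pred_labels equal-length label vectors with values
#'   in `{"normal", "pvc"}` (or a factor thereof).
#' @return Object of class `confusion_matrix` with fields `tn`, `fp`,
#'   `fn`, `tp`.
#' @export
confusion <- function(true_labels, pred_labels) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  pos_t <- true_labels == "pvc"; pos_p <- pred_labels == "pvc"
  structure(list(tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p),
                 fn = sum(pos_t & !pos_p), tp = sum(pos_t & pos_p)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param tn,fp,fn,tp non-negative counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  if (any(c(tn, fp, fn, tp) < 0)) stop("counts must be non-negative")
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("normal", "pvc"),
                              truth = c("normal", "pvc")))
  print(m)
  invisible(x)
}

#' Five evaluation metrics from a confusion matrix
#'
#' Accuracy, sensitivity (PVC recall), specificity (normal recall),
#' positive prediction P+ (PVC precision) and negative prediction P-
#' (normal precision), each in percent. A metric whose denominator is zero
#' is reported as `NA`, never silently as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return Object of class `metrics_report`: list with `acc`, `se`, `sp`,
#'   `p_plus`, `p_minus` (percent).
#' @export
#' @examples
#' beat_metrics(confusion_counts(tn = 33824, fp = 44, fn = 65, tp = 2483))
beat_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) stop("empty confusion matrix")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(acc = 100 * (cm$tp + cm$tn) / total,
                 se = rate(cm$tp, cm$tp + cm$fn),
                 sp = rate(cm$tn, cm$tn + cm$fp),
                 p_plus = rate(cm$tp, cm$tp + cm$fp),
                 p_minus = rate(cm$tn, cm$tn + cm$fn),
                 cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Acc %.4f%%  Se %.4f%%  Sp %.4f%%  P+ %.4f%%  P- %.4f%%\n",
    x$acc, x$se, x$sp, x$p_plus, x$p_minus))
  invisible(x)
}

metrics_row <- function(rep) {
  data.frame(tn = rep$cm$tn, fp = rep$cm$fp, fn = rep$cm$fn, tp = rep$cm$tp,
             acc = rep$acc, se = rep$se, sp = rep$sp,
             p_plus = rep$p_plus, p_minus = rep$p_minus)
}

# Train, embed and evaluate once; shared by run_sweep and run_pipeline.
train_and_eval <- function(train_beats, test_beats, cfg, ecfg, K = 1) {
  model <- train_embedder(train_beats, cfg, ecfg)
  tr_emb <- embed(train_beats, model)
  te_emb <- embed(test_beats, model)
  pred <- knn_predict(tr_emb, train_beats$label, te_emb, K)
  rep <- beat_metrics(confusion(test_beats$label, pred))
  list(model = model, train_emb = tr_emb, test_emb = te_emb,
       pred = pred, report = rep)
}

#' Ablation sweeps over pipeline hyper-parameters
#'
#' Re-trains and evaluates the pipeline per grid point for the `denoise`,
#' `features`, `pooling`, and `margin_epsilon` sweeps; the `K` sweep
#' trains one embedder and varies only the classifier's K. Each row of
#' the returned table carries the grid point, the confusion counts, and
#' the five metrics.
#'
#' @param kind one of `"denoise"`, `"features"`, `"pooling"`,
#'   `"margin_epsilon"`, `"K"`.
#' @param grid the grid: feature counts for `features`; pooling names for
#'   `pooling`; a data.frame with `margin`, `epsilon` columns for
#'   `margin_epsilon`; K values for `K`; for `denoise`, a list of
#'   [denoise_config()] objects (names label the rows).
#' @param data list with `train` and `test` [heartbeat_set()]s; for the
#'   `denoise` sweep, lists with raw `record`/`annotations` per split.
#' @param cfg a [train_config()].
#' @param ecfg base [embedder_config()].
#' @param K classifier parameter for the non-K sweeps.
#' @return data.frame, one row per grid point.
#' @export
run_sweep <- function(kind = c("denoise", "features", "pooling",
                               "margin_epsilon", "K"),
                      grid, data, cfg = train_config(),
                      ecfg = embedder_config(), K = 1) {
  kind <- match.arg(kind)
  if (length(grid) == 0) stop("empty sweep grid")
  rows <- list()
  if (kind == "K") {
    res <- train_and_eval(data$train, data$test, cfg, ecfg, K = 1)
    for (k in grid) {
      pred <- knn_predict(res$train_emb, data$train$label, res$test_emb, k)
      rep <- beat_metrics(confusion(data$test$label, pred))
      rows[[length(rows) + 1]] <- cbind(data.frame(K = k), metrics_row(rep))
    }
  } else if (kind == "features") {
    for (f in grid) {
      ch <- vapply(ecfg$groups, `[[`, numeric(1), "channels")
      ks <- vapply(ecfg$groups, `[[`, numeric(1), "kernel_size")
      ch[length(ch)] <- f
      ecfg_f <- embedder_config(ch, ks, ecfg$groups[[1]]$pool,
                                ecfg$input_length)
      rep <- train_and_eval(data$train, data$test, cfg, ecfg_f, K)$report
      rows[[length(rows) + 1]] <-
        cbind(data.frame(n_features = f), metrics_row(rep))
    }
  } else if (kind == "pooling") {
    for (pl in grid) {
      ch <- vapply(ecfg$groups, `[[`, numeric(1), "channels")
      ks <- vapply(ecfg$groups, `[[`, numeric(1), "kernel_size")
      ecfg_p <- embedder_config(ch, ks, pl, ecfg$input_length)
      rep <- train_and_eval(data$train, data$test, cfg, ecfg_p, K)$report
      rows[[length(rows) + 1]] <-
        cbind(data.frame(pooling = pl), metrics_row(rep))
    }
  } else if (kind == "margin_epsilon") {
    grid <- as.data.frame(grid)
    for (r in seq_len(nrow(grid))) {
      cfg_r <- cfg
      cfg_r$margin <- grid$margin[r]
      cfg_r$epsilon <- grid$epsilon[r]
      rep <- train_and_eval(data$train, data$test, cfg_r, ecfg, K)$report
      rows[[length(rows) + 1]] <-
        cbind(data.frame(margin = grid$margin[r],
                         epsilon = grid$epsilon[r]), metrics_row(rep))
    }
  } else { # denoise
    for (nm in names(grid)) {
      dcfg <- grid[[nm]]
      prep <- function(split) {
        rec <- apply_denoise(split$record, dcfg)
        normalize_beats(extract_beats(rec, split$annotations,
                                      window = ecfg$input_length))
      }
      rep <- train_and_eval(prep(data$train), prep(data$test),
                            cfg, ecfg, K)$report
      rows[[length(rows) + 1]] <-
        cbind(data.frame(denoise = nm), metrics_row(rep))
    }
  }
  do.call(rbind, rows)
}
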