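test_that("KNN handles exact matches and vote ties as documented", {
  train <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  labels <- c("pvc", "normal", "normal")
  expect_identical(knn_predict(train, labels, rbind(c(1, 0)), K = 1), "pvc")

  # K = 2: votes split 1-1, the nearer neighbour (pvc) wins
  q <- rbind(c(0.9, 0.3))
  expect_identical(knn_predict(train, labels, q, K = 2), "pvc")

  expect_error(knn_predict(train[0, , drop = FALSE], character(0), q, 1),
               "empty")
  expect_error(knn_predict(train, labels, q, K = 4), "between")
})

test_that("KNN equals the exhaustive-sort oracle on random instances", {
  set.seed(321)
  for (rep in 1:70) {
    tr <- random_embeddings(50, 8)
    qu <- matrix(rnorm(30 * 8), 30, 8)
    for (K in c(1, 3, 5)) {
      expect_identical(knn_predict(tr$E, tr$labels, qu, K),
                       knn_bruteforce(tr$E, tr$labels, qu, K))
    }
  }
})

test_that("euclidean metric flag gives nearest-by-L2 labels", {
  train <- rbind(c(0, 0), c(10, 10))
  labels <- c("normal", "pvc")
  expect_identical(knn_predict(train, labels, rbind(c(1, 1)), 1,
                               metric = "euclidean"), "normal")
})

test_that("confusion counts follow the positive-class convention", {
  cm <- confusion(rep(c("pvc", "normal"), c(3, 7)),
                  rep(c("pvc", "normal"), c(3, 7)))
  expect_identical(c(cm$tp, cm$tn, cm$fp, cm$fn), c(3L, 7L, 0L, 0L))

  t2 <- c("normal", "normal", "pvc", "pvc", "pvc")
  p2 <- c("normal", "pvc", "pvc", "pvc", "normal")
  cm2 <- confusion(t2, p2)
  expect_identical(c(cm2$tn, cm2$fp, cm2$fn, cm2$tp), c(1L, 1L, 1L, 2L))

  flipped <- confusion(t2, ifelse(t2 == "pvc", "normal", "pvc"))
  expect_identical(c(flipped$tp, flipped$tn), c(0L, 0L))

  expect_error(confusion(t2, p2[1:3]), "equal length")
})

test_that("the five metrics match their formulas and edge rules", {
  rep1 <- beat_metrics(confusion_counts(tn = 33824, fp = 44, fn = 65,
                                        tp = 2483))
  expect_equal(rep1$acc, 99.7007, tolerance = 5e-5)
  expect_equal(rep1$se, 97.4490, tolerance = 5e-5)
  expect_equal(rep1$sp, 99.8701, tolerance = 5e-5)
  expect_equal(rep1$p_plus, 98.2588, tolerance = 5e-5)
  expect_equal(rep1$p_minus, 99.8082, tolerance = 5e-5)

  perfect <- beat_metrics(confusion_counts(50, 0, 0, 50))
  expect_equal(unlist(perfect[c("acc", "se", "sp", "p_plus", "p_minus")]),
               c(acc = 100, se = 100, sp = 100, p_plus = 100,
                 p_minus = 100))

  # undefined metrics are NA, never 0
  no_pos <- beat_metrics(confusion_counts(tn = 10, fp = 0, fn = 0, tp = 0))
  expect_true(is.na(no_pos$se))
  expect_true(is.na(no_pos$p_plus))
  expect_error(beat_metrics(confusion_counts(0, 0, 0, 0)), "empty")

  # exact integer identity: acc * total = 100 * (TP + TN)
  cm <- confusion_counts(tn = 123, fp = 7, fn = 11, tp = 59)
  total <- 123 + 7 + 11 + 59
  expect_equal(beat_metrics(cm)$acc * total, 100 * (59 + 123))
})

test_that("metrics of a self-comparison are all 100", {
  t <- sample(c("normal", "pvc"), 30, replace = TRUE)
  t[1:2] <- c("normal", "pvc")  # both classes present
  r <- beat_metrics(confusion(t, t))
  expect_equal(c(r$acc, r$se, r$sp, r$p_plus, r$p_minus), rep(100, 5))
})

test_that("K sweep reuses one embedder and emits one row per K", {
  beats <- make_beats(36, seed = 61)
  test_beats <- make_beats(24, seed = 62)
  tab <- run_sweep("K", grid = c(1, 3, 5),
                   data = list(train = beats, test = test_beats),
                   cfg = train_config(epochs = 2),
                   ecfg = tiny_embedder_config())
  expect_identical(tab$K, c(1, 3, 5))
  expect_true(all(tab$tn + tab$fp + tab$fn + tab$tp == 24))
  expect_error(run_sweep("K", grid = numeric(0), data = NULL), "empty")
})

test_that("neighbourhood stability: predictions change only where the
           K-neighbourhood differs", {
  set.seed(99)
  tr <- random_embeddings(40, 6)
  qu <- matrix(rnorm(25 * 6), 25, 6)
  p1 <- knn_predict(tr$E, tr$labels, qu, 1)
  p3 <- knn_predict(tr$E, tr$labels, qu, 3)
  nt <- sqrt(rowSums(tr$E^2)); nq <- sqrt(rowSums(qu^2))
  D <- 1 - tcrossprod(qu / nq, tr$E / nt)
  for (q in which(p1 != p3)) {
    nb3 <- order(D[q, ])[1:3]
    # a flip requires the added neighbours to outvote the nearest
    expect_false(all(tr$labels[nb3] == tr$labels[nb3[1]]))
  }
})
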