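simple_labeled <- function(pos_scores, neg_scores) {
  n <- length(pos_scores) + length(neg_scores)
  pairs <- tibble::tibble(
    protein_a = sprintf("A%03d", seq_len(n)),
    protein_b = sprintf("B%03d", seq_len(n))
  )
  list(
    labels = dplyr::mutate(pairs, label = rep(
      c("pos", "neg"), c(length(pos_scores), length(neg_scores))
    )),
    scores = dplyr::mutate(pairs, score = c(pos_scores, neg_scores))
  )
}

test_that("confusion counts match direct enumeration and boundary cutoffs", {
  fx <- simple_labeled(c(10, 1), 5)
  cm <- confusion_at_cutoff(fx$labels, fx$scores, 6)
  expect_equal(cm[c("tp", "fn", "fp", "tn")], tibble::tibble(
    tp = 1L, fn = 1L, fp = 0L, tn = 1L
  ), ignore_attr = TRUE)

  low <- confusion_at_cutoff(fx$labels, fx$scores, 0)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  high <- confusion_at_cutoff(fx$labels, fx$scores, 100)
  expect_equal(high$sensitivity, 0)
  expect_equal(high$specificity, 1)
})

test_that("unscored labeled pairs count as never-called and are reported", {
  fx <- simple_labeled(c(10, 1), 5)
  scores <- fx$scores[-2, ] # drop the score of the second positive
  cm <- confusion_at_cutoff(fx$labels, scores, 0.5)
  expect_equal(cm$n_unscored, 1L)
  expect_equal(cm$tp, 1L)
  expect_equal(cm$fn, 1L)
  expect_error(
    confusion_at_cutoff(fx$labels[0, ], fx$scores, 1),
    "no labeled pairs"
  )
})

test_that("ROC reproduces the closed-form fixtures", {
  fx <- simple_labeled(c(3, 1), c(2, 0))
  roc <- roc_curve(fx$labels, fx$scores)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$points$fpr[[1]], 0)
  expect_equal(roc$points$tpr[[1]], 0)
  expect_equal(roc$points$fpr[[nrow(roc$points)]], 1)
  expect_equal(roc$points$tpr[[nrow(roc$points)]], 1)

  sep <- simple_labeled(c(9, 8, 7), c(3, 2, 1))
  expect_equal(roc_curve(sep$labels, sep$scores)$auc, 1.0)

  ties <- simple_labeled(rep(2, 4), rep(2, 6))
  expect_equal(roc_curve(ties$labels, ties$scores)$auc, 0.5)

  one_class <- simple_labeled(c(1, 2), numeric(0))
  expect_error(roc_curve(one_class$labels, one_class$scores), "positive")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic on random fixtures", {
  for (seed in 1:40) {
    fx <- random_labeled_scores(seed)
    roc <- roc_curve(fx$labels, fx$scores)
    pos <- fx$scores$score[fx$labels$label == "pos"]
    neg <- fx$scores$score[fx$labels$label == "neg"]
    expect_equal(roc$auc, oracle_auc(pos, neg),
      tolerance = 1e-9, info = paste("seed", seed)
    )
  }
})

test_that("label flip mirrors the AUC and monotone transforms leave it unchanged", {
  for (seed in 1:10) {
    fx <- random_labeled_scores(seed)
    auc <- roc_curve(fx$labels, fx$scores)$auc
    flipped <- dplyr::mutate(
      fx$labels, label = ifelse(label == "pos", "neg", "pos")
    )
    expect_equal(roc_curve(flipped, fx$scores)$auc, 1 - auc)

    transformed <- dplyr::mutate(fx$scores, score = exp(3 * score + 1))
    roc_t <- roc_curve(fx$labels, transformed)
    expect_equal(roc_t$auc, auc)
    expect_equal(
      roc_t$points[c("tpr", "fpr")],
      roc_curve(fx$labels, fx$scores)$points[c("tpr", "fpr")]
    )
  }
})

test_that("TP/FP ratio handles exhaustion and matches label-shuffle expectation", {
  fx <- simple_labeled(10, 5)
  out <- tp_fp_ratio_curve(fx$labels, fx$scores, c(1, 7))
  expect_equal(out$ratio, c(1, Inf))
  none <- tp_fp_ratio_curve(fx$labels, fx$scores, c(11))
  expect_true(is.nan(none$ratio))
  expect_error(
    tp_fp_ratio_curve(fx$labels, fx$scores, c(3, 2)), "ascending"
  )

  # shuffled labels: ratio approximates the positive/negative prevalence
  set.seed(8)
  n <- 1000
  pairs <- tibble::tibble(
    protein_a = sprintf("A%04d", 1:n), protein_b = sprintf("B%04d", 1:n)
  )
  labels <- dplyr::mutate(pairs, label = sample(rep(
    c("pos", "neg"), c(400, 600)
  )))
  scores <- dplyr::mutate(pairs, score = runif(n, 0, 10))
  out <- tp_fp_ratio_curve(labels, scores, c(1, 3, 5))
  expect_true(all(abs(out$ratio - 400 / 600) < 0.15))
})

test_that("holdout evaluation guards against gold-standard leakage", {
  fx <- simple_labeled(c(10, 8), c(2, 1))
  train <- fx$labels[1:2, c("protein_a", "protein_b")]
  expect_error(
    holdout_evaluate(fx$scores, fx$labels, train),
    "overlap"
  )
  disjoint_train <- tibble::tibble(protein_a = "Z1", protein_b = "Z2")
  out <- holdout_evaluate(fx$scores, fx$labels, disjoint_train)
  expect_equal(out$summary$auc, 1)
  expect_equal(out$summary$n_overlap, 0L)

  flipped <- dplyr::mutate(
    fx$labels, label = ifelse(label == "pos", "neg", "pos")
  )
  out_f <- holdout_evaluate(fx$scores, flipped, disjoint_train)
  expect_equal(out_f$summary$auc, 1 - out$summary$auc)
})

test_that("validation cutoff selection maximizes F1", {
  fx <- simple_labeled(c(10, 9, 8, 2), c(3, 1, 1, 1))
  sel <- choose_cutoff(fx$labels, fx$scores)
  cm <- confusion_at_cutoff(fx$labels, fx$scores, sel$cutoff)
  f1_at <- function(ct) {
    c <- confusion_at_cutoff(fx$labels, fx$scores, ct)
    2 * c$tp / (2 * c$tp + c$fp + c$fn)
  }
  others <- vapply(unique(fx$scores$score), f1_at, numeric(1))
  expect_true(all(f1_at(sel$cutoff) >= others - 1e-12))
  # optimum calls everything down to the stray positive at 2 (F1 8/9)
  expect_equal(cm$tp, 4L)
  expect_equal(cm$fp, 1L)
})

test_that("AUC agrees with an independent library implementation", {
  for (seed in 1:5) {
    fx <- random_labeled_scores(seed)
    ours <- roc_curve(fx$labels, fx$scores)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = fx$labels$label, predictor = fx$scores$score,
      levels = c("neg", "pos"), direction = "<", quiet = TRUE
    )))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})
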