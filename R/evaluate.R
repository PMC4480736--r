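# Join labeled pairs with scores; unscored labeled pairs get score 0 so
# they can never be called positive (real classifier abstentions).
labeled_scores <- function(labels, scores) {
  stopifnot(all(c("protein_a", "protein_b", "label") %in% names(labels)))
  if (!all(labels$label %in% c("pos", "neg"))) {
    stop("labels must be 'pos' or 'neg'", call. = FALSE)
  }
  if (nrow(labels) == 0) {
    stop("no labeled pairs: rates are undefined", call. = FALSE)
  }
  score_col <- if ("lr_combined" %in% names(scores)) {
    "lr_combined"
  } else {
    "score"
  }
  joined <- as_tibble(labels[c("protein_a", "protein_b", "label")]) %>%
    left_join(
      tibble(
        protein_a = scores$protein_a, protein_b = scores$protein_b,
        score = scores[[score_col]]
      ),
      by = c("protein_a", "protein_b")
    )
  n_unscored <- sum(is.na(joined$score))
  joined$score[is.na(joined$score)] <- 0
  attr(joined, "n_unscored") <- n_unscored
  joined
}

#' Confusion counts at a score cutoff
#'
#' Calls every labeled pair with score at or above the cutoff positive and
#' tabulates true/false positives and negatives. Sensitivity is
#' `TP / positives` and specificity `1 - FP / negatives`, with positives
#' and negatives the label totals. Labeled pairs missing from the score
#' table are treated as score 0 (never called) and their number reported.
#'
#' @param labels Pair data frame with a `label` column (`"pos"`/`"neg"`).
#' @param scores Pair data frame with `lr_combined` (or `score`) column.
#' @param cutoff Numeric decision threshold (`score >= cutoff` is called).
#' @return One-row tibble: `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `n_unscored`.
#' @export
confusion_at_cutoff <- function(labels, scores, cutoff) {
  joined <- labeled_scores(labels, scores)
  called <- joined$score >= cutoff
  pos <- joined$label == "pos"
  tp <- sum(called & pos)
  fp <- sum(called & !pos)
  fn <- sum(!called & pos)
  tn <- sum(!called & !pos)
  tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (fp + tn > 0) 1 - fp / (fp + tn) else NA_real_,
    n_unscored = attr(joined, "n_unscored")
  )
}

#' ROC curve and AUC for scored pairs
#'
#' Sweeps every distinct score as a cutoff, records one
#' (false-positive rate, true-positive rate) point per cutoff with the
#' (0,0) and (1,1) endpoints, and integrates the area under the curve by
#' the trapezoidal rule. With ties handled by the trapezoid across the tie
#' group, the AUC equals the Mann-Whitney probability that a random
#' positive outscores a random negative (ties counting one half).
#'
#' @inheritParams confusion_at_cutoff
#' @return A `ppi_roc` object: list with `points` (tibble `cutoff`, `tp`,
#'   `fp`, `tn`, `fn`, `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`,
#'   `n_unscored`.
#' @examples
#' labels <- tibble::tibble(
#'   protein_a = "A", protein_b = c("B", "C", "D", "E"),
#'   label = c("pos", "pos", "neg", "neg")
#' )
#' scores <- tibble::tibble(
#'   protein_a = "A", protein_b = c("B", "C", "D", "E"),
#'   score = c(3, 1, 2, 0)
#' )
#' roc_curve(labels, scores)$auc # 0.75
#' @export
roc_curve <- function(labels, scores) {
  joined <- labeled_scores(labels, scores)
  n_pos <- sum(joined$label == "pos")
  n_neg <- sum(joined$label == "neg")
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires at least one positive and one negative label",
      call. = FALSE
    )
  }
  ord <- order(joined$score, decreasing = TRUE)
  s <- joined$score[ord]
  is_pos <- joined$label[ord] == "pos"
  # cumulative counts at each distinct cutoff (last index of each tie group)
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(is_pos)[last_of_group]
  cum_fp <- cumsum(!is_pos)[last_of_group]
  points <- tibble(
    cutoff = c(Inf, s[last_of_group]),
    tp = c(0, cum_tp), fp = c(0, cum_fp)
  ) %>%
    mutate(
      tn = n_neg - fp, fn = n_pos - tp,
      tpr = tp / n_pos, fpr = fp / n_neg
    )
  if (points$fpr[nrow(points)] != 1 || points$tpr[nrow(points)] != 1) {
    points <- bind_rows(points, tibble(
      cutoff = -Inf, tp = n_pos, fp = n_neg, tn = 0, fn = 0,
      tpr = 1, fpr = 1
    ))
  }
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) +
    points$tpr[-1]) / 2)
  structure(
    list(
      points = points, auc = auc, n_pos = n_pos, n_neg = n_neg,
      n_unscored = attr(joined, "n_unscored")
    ),
    class = "ppi_roc"
  )
}

#' @export
print.ppi_roc <- function(x, ...) {
  cat(
    "ROC curve:", nrow(x$points), "points, AUC =",
    format(x$auc, digits = 4), "(", x$n_pos, "positives,",
    x$n_neg, "negatives )\n"
  )
  invisible(x)
}

#' TP/FP ratio as a function of the LR cutoff
#'
#' The reliability diagnostic behind cutoff selection: at each cutoff, the
#' ratio of true to false positives among the called pairs. `Inf` marks
#' cutoffs with true positives but no false positives; `NaN` marks cutoffs
#' that call nothing.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Ascending positive cutoff vector.
#' @return Tibble: `cutoff`, `tp`, `fp`, `ratio`.
#' @export
tp_fp_ratio_curve <- function(labels, scores, cutoffs) {
  if (any(cutoffs <= 0) || is.unsorted(cutoffs)) {
    stop("`cutoffs` must be positive and ascending", call. = FALSE)
  }
  joined <- labeled_scores(labels, scores)
  pos <- joined$label == "pos"
  purrr::map_dfr(cutoffs, function(ct) {
    called <- joined$score >= ct
    tp <- sum(called & pos)
    fp <- sum(called & !pos)
    tibble(
      cutoff = ct, tp = tp, fp = fp,
      ratio = if (tp + fp == 0) NaN else tp / fp
    )
  })
}

#' Evaluate scores on a held-out standard test set
#'
#' Guards against leakage: test pairs overlapping the training gold
#' standards beyond `max_overlap` (as a fraction of the test set) cause a
#' refusal that reports the overlap. Otherwise returns the ROC on the
#' held-out labeled pairs only.
#'
#' @param scores Scored pair table (`lr_combined` or `score`).
#' @param test_set Labeled pair table (`protein_a`, `protein_b`, `label`).
#' @param train_pairs Pair table(s) used for training (e.g. the union of
#'   GSP and GSN); a list is unioned.
#' @param max_overlap Maximum tolerated overlap fraction (default 0).
#' @return List: `roc` (a `ppi_roc`), `summary` (one-row tibble with
#'   `auc`, `n_test`, `n_overlap`, `n_unscored`).
#' @export
holdout_evaluate <- function(scores, test_set, train_pairs,
                             max_overlap = 0) {
  if (is.data.frame(train_pairs)) {
    train_pairs <- list(train_pairs)
  }
  train_keys <- unique(unlist(lapply(train_pairs, pair_keys)))
  test_keys <- pair_keys(test_set)
  n_overlap <- sum(test_keys %in% train_keys)
  frac <- n_overlap / max(1, nrow(test_set))
  if (frac > max_overlap) {
    stop(
      "test set overlaps training gold standards: ", n_overlap, " of ",
      nrow(test_set), " pairs (", sprintf("%.1f%%", 100 * frac),
      " > allowed ", sprintf("%.1f%%", 100 * max_overlap), ")",
      call. = FALSE
    )
  }
  roc <- roc_curve(test_set, scores)
  list(
    roc = roc,
    summary = tibble(
      auc = roc$auc, n_test = nrow(test_set), n_overlap = n_overlap,
      n_unscored = roc$n_unscored
    )
  )
}

#' Choose an LR cutoff on validation data
#'
#' Sweeps all distinct scores of the validation pairs and returns the
#' cutoff maximizing the F1 score (harmonic mean of precision and
#' sensitivity). Ties are broken toward the larger (stricter) cutoff.
#'
#' @inheritParams confusion_at_cutoff
#' @return List: `cutoff`, `table` (tibble of cutoff, tp, fp, fn, f1).
#' @export
choose_cutoff <- function(labels, scores) {
  joined <- labeled_scores(labels, scores)
  cuts <- sort(unique(joined$score), decreasing = TRUE)
  pos <- joined$label == "pos"
  tab <- purrr::map_dfr(cuts, function(ct) {
    called <- joined$score >= ct
    tp <- sum(called & pos)
    fp <- sum(called & !pos)
    fn <- sum(!called & pos)
    tibble(
      cutoff = ct, tp = tp, fp = fp, fn = fn,
      f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    )
  })
  best <- tab[tab$f1 == max(tab$f1), ]
  list(cutoff = max(best$cutoff), table = tab)
}
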