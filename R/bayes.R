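#' Estimate per-bin likelihood ratios from the gold standards
#'
#' For each evidence type and bin, counts gold-standard positive and
#' negative pairs falling in the bin and estimates
#' `LR = P(bin | positive) / P(bin | negative)` with Laplace-style
#' smoothing: `P(bin | positive) = (pos + c) / (N_pos + B * c)` where `B`
#' is the number of bins of that evidence and `c` the pseudocount
#' (analogously for negatives). Gold pairs with missing evidence are
#' excluded from that evidence's denominators, so the per-class bin
#' probabilities sum to one over binned pairs.
#'
#' @param evidence_bins Long binned-evidence tibble (`protein_a`,
#'   `protein_b`, `evidence`, `bin`) covering at least the gold-standard
#'   pairs.
#' @param gsp,gsn Canonical positive / negative pair data frames
#'   (disjoint, non-empty).
#' @param schemes Named list of `ppi_binning_scheme` (from
#'   [bin_evidence()]); defines the full bin vocabulary `B` per evidence,
#'   including bins with zero gold counts.
#' @param pseudocount Smoothing pseudocount per bin (default 0.5); keeps
#'   every LR finite and positive.
#' @return A `ppi_lr_table` tibble: `evidence`, `bin`, `pos_count`,
#'   `neg_count`, `p_pos`, `p_neg`, `lr`; attributes `pseudocount` and
#'   `class_totals`.
#' @export
estimate_lr_table <- function(evidence_bins, gsp, gsn, schemes,
                              pseudocount = 0.5) {
  if (nrow(gsp) == 0 || nrow(gsn) == 0) {
    stop("gold-standard sets must be non-empty", call. = FALSE)
  }
  gsp_keys <- pair_keys(gsp)
  gsn_keys <- pair_keys(gsn)
  if (any(gsp_keys %in% gsn_keys)) {
    stop("gold-standard positive and negative sets overlap", call. = FALSE)
  }
  if (pseudocount < 0) {
    stop("`pseudocount` must be >= 0", call. = FALSE)
  }
  keys <- pair_keys(evidence_bins)
  rows <- list()
  totals <- list()
  for (ev in names(schemes)) {
    labels <- schemes[[ev]]$labels
    ev_bins <- evidence_bins[evidence_bins$evidence == ev, ]
    ev_keys <- keys[evidence_bins$evidence == ev]
    pos_bins <- ev_bins$bin[ev_keys %in% gsp_keys]
    neg_bins <- ev_bins$bin[ev_keys %in% gsn_keys]
    if (length(pos_bins) == 0 && length(neg_bins) == 0) {
      warning("evidence '", ev, "' has no binned gold-standard pairs ",
        "and is omitted from the likelihood table",
        call. = FALSE
      )
      next
    }
    pos <- table(factor(pos_bins, levels = labels))
    neg <- table(factor(neg_bins, levels = labels))
    b <- length(labels)
    p_pos <- (as.numeric(pos) + pseudocount) /
      (sum(pos) + b * pseudocount)
    p_neg <- (as.numeric(neg) + pseudocount) /
      (sum(neg) + b * pseudocount)
    rows[[ev]] <- tibble(
      evidence = ev, bin = labels,
      pos_count = as.integer(pos), neg_count = as.integer(neg),
      p_pos = p_pos, p_neg = p_neg,
      lr = p_pos / p_neg
    )
    totals[[ev]] <- tibble(
      evidence = ev,
      n_pos_binned = sum(pos), n_neg_binned = sum(neg)
    )
  }
  if (length(rows) == 0) {
    stop("no evidence type has binned gold-standard pairs", call. = FALSE)
  }
  out <- bind_rows(rows)
  if (any(!is.finite(out$lr) | out$lr <= 0)) {
    stop("likelihood ratios must be positive and finite; ",
      "use a positive pseudocount when bins have zero counts",
      call. = FALSE
    )
  }
  structure(
    out,
    class = c("ppi_lr_table", class(out)),
    pseudocount = pseudocount,
    class_totals = bind_rows(totals)
  )
}

#' Combine per-evidence likelihood ratios under naive Bayes
#'
#' Conditional independence of the evidence types given interaction status
#' lets the composite likelihood ratio factor into a product of
#' per-evidence LRs. Missing evidence contributes a factor of 1 (it is
#' uninformative, not incriminating) and is not counted in
#' `n_evidence_used`. Posterior odds are `prior_odds * lr_combined`;
#' because the prior odds are a constant, ranking and thresholding operate
#' on the composite LR itself.
#'
#' @param pairs Canonical pair data frame defining the scored universe
#'   (pairs with no evidence rows receive the empty product, LR 1).
#' @param evidence_bins Long binned-evidence tibble for these pairs.
#' @param lr_table A `ppi_lr_table`.
#' @param prior_odds Prior odds of interaction (default 1; reported
#'   separately from the LR).
#' @return A `ppi_scores` tibble: pair columns, per-evidence factor
#'   columns (`lr_coexpr`, ...), `lr_combined`, `n_evidence_used`,
#'   `posterior_odds`.
#' @export
combine_lr <- function(pairs, evidence_bins, lr_table, prior_odds = 1) {
  stopifnot(prior_odds > 0)
  pairs <- as_tibble(pairs[c("protein_a", "protein_b")])
  ev_present <- unique(lr_table$evidence)
  bins <- evidence_bins %>%
    filter(evidence %in% ev_present) %>%
    semi_join(pairs, by = c("protein_a", "protein_b"))
  unmatched <- anti_join(bins, lr_table, by = c("evidence", "bin"))
  if (nrow(unmatched) > 0) {
    stop(
      "bin '", unmatched$bin[[1]], "' of evidence '",
      unmatched$evidence[[1]], "' is absent from the likelihood table",
      call. = FALSE
    )
  }
  factors <- bins %>%
    inner_join(
      select(lr_table, evidence, bin, lr),
      by = c("evidence", "bin")
    ) %>%
    select(protein_a, protein_b, evidence, factor_value = lr) %>%
    tidyr::pivot_wider(
      names_from = evidence, values_from = factor_value,
      names_prefix = "lr_"
    )
  out <- left_join(pairs, factors, by = c("protein_a", "protein_b"))
  factor_cols <- paste0("lr_", ev_present)
  for (fc in setdiff(factor_cols, names(out))) {
    out[[fc]] <- NA_real_
  }
  fmat <- as.matrix(out[factor_cols])
  out$n_evidence_used <- as.integer(rowSums(!is.na(fmat)))
  fmat[is.na(fmat)] <- 1
  out$lr_combined <- apply(fmat, 1, prod)
  out$posterior_odds <- prior_odds * out$lr_combined
  structure(
    out,
    class = c("ppi_scores", class(out)),
    prior_odds = prior_odds
  )
}

#' Assemble the predicted interaction network at an LR cutoff
#'
#' The network is the union of the prediction set (pairs whose composite
#' LR meets the cutoff; ties included) and the gold-standard positive set,
#' with provenance marking whether each edge was predicted, curated, or
#' both. The default cutoff of 117 is the operating point used for the
#' original apoptotic network; it is fully configurable and
#' [choose_cutoff()] provides data-driven selection diagnostics.
#'
#' @param scores A `ppi_scores` tibble (or any pair table with
#'   `lr_combined`).
#' @param gsp Canonical gold-standard positive pairs.
#' @param lr_cutoff Positive LR threshold (default 117).
#' @return A `ppi_network` tibble: pair columns, `lr_combined` (`NA` for
#'   curated edges outside the scored universe), `provenance` in
#'   `predicted` / `gold_positive` / `both`; attributes `lr_cutoff` and
#'   `nodes`.
#' @export
predict_network <- function(scores, gsp, lr_cutoff = 117) {
  if (!is.numeric(lr_cutoff) || lr_cutoff <= 0) {
    stop("`lr_cutoff` must be positive", call. = FALSE)
  }
  predicted <- scores %>%
    filter(lr_combined >= lr_cutoff) %>%
    select(protein_a, protein_b, lr_combined)
  gsp_tbl <- as_tibble(gsp[c("protein_a", "protein_b")]) %>%
    distinct(protein_a, protein_b)
  pred_keys <- pair_keys(predicted)
  gsp_keys <- pair_keys(gsp_tbl)
  scored_lr <- setNames(scores$lr_combined, pair_keys(scores))
  gold_only <- gsp_tbl[!gsp_keys %in% pred_keys, ]
  edges <- bind_rows(
    predicted %>% mutate(
      provenance = if_else(pred_keys %in% gsp_keys, "both", "predicted")
    ),
    gold_only %>% mutate(
      lr_combined = unname(scored_lr[pair_keys(gold_only)]),
      provenance = "gold_positive"
    )
  ) %>% arrange(protein_a, protein_b)
  structure(
    edges,
    class = c("ppi_network", class(edges)),
    lr_cutoff = lr_cutoff,
    nodes = sort(unique(c(edges$protein_a, edges$protein_b)))
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(
    "Protein interaction network:", nrow(x), "edges over",
    length(attr(x, "nodes")), "proteins (LR cutoff",
    attr(x, "lr_cutoff"), ")\n"
  )
  print(count(as_tibble(x), provenance))
  invisible(x)
}
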