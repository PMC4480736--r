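#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC curve
#'
#' @param x A `ppi_roc`.
#' @param ... Unused.
#' @return The per-cutoff points tibble (`cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `tpr`, `fpr`).
#' @export
tidy.ppi_roc <- function(x, ...) {
  x$points
}

#' @rdname tidy.ppi_roc
#' @return For `glance()`: a one-row tibble with `auc`, `n_pos`, `n_neg`,
#'   `n_unscored`.
#' @export
glance.ppi_roc <- function(x, ...) {
  tibble(
    auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
    n_unscored = x$n_unscored
  )
}

#' Tidy a SAM fit
#'
#' @param x A `ppi_sam`.
#' @param ... Unused.
#' @return Per-gene tibble (`gene_id`, `d`, `s`, `rank`, `significant`,
#'   `direction`).
#' @export
tidy.ppi_sam <- function(x, ...) {
  x$genes
}

#' @rdname tidy.ppi_sam
#' @return For `glance()`: one-row tibble with the chosen `delta`, the
#'   estimated FDR, `pi0`, both cutoffs and the call count.
#' @export
glance.ppi_sam <- function(x, ...) {
  tibble(
    delta = x$delta, fdr_estimate = x$fdr_estimate, pi0 = x$pi0,
    cut_up = x$cut_up, cut_low = x$cut_low,
    n_significant = sum(x$genes$significant),
    n_permutations = x$n_permutations, target_fdr = x$target_fdr
  )
}

#' Tidy a likelihood-ratio table
#'
#' @param x A `ppi_lr_table`.
#' @param ... Unused.
#' @return The per-bin tibble itself (evidence, bin, counts,
#'   probabilities, LR).
#' @export
tidy.ppi_lr_table <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.ppi_lr_table
#' @export
glance.ppi_lr_table <- function(x, ...) {
  as_tibble(x) %>%
    group_by(evidence) %>%
    summarise(
      n_bins = dplyr::n(),
      min_lr = min(lr), max_lr = max(lr),
      dynamic_range = max(lr) / min(lr),
      .groups = "drop"
    )
}

#' Summaries of a predicted network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return One-row tibble: node and edge counts by provenance and the
#'   cutoff used.
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(
    n_nodes = length(attr(x, "nodes")),
    n_edges = nrow(x),
    n_predicted = sum(x$provenance == "predicted"),
    n_gold_only = sum(x$provenance == "gold_positive"),
    n_both = sum(x$provenance == "both"),
    lr_cutoff = attr(x, "lr_cutoff")
  )
}

#' @rdname glance.ppi_network
#' @export
glance.ppi_hub_report <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    n_proteins = nrow(x),
    n_classical = sum(x$hub_class == "classical"),
    n_novel = sum(x$hub_class == "novel"),
    degree_threshold = thr$degree,
    links_threshold_classical = thr$links_classical,
    links_threshold_novel = thr$links_novel,
    k_core_min = thr$k_core_min
  )
}
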