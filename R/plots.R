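#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `ppi_roc`.
#' @param ... Unused.
#' @return A ggplot: TPR versus FPR with the chance diagonal and the AUC
#'   in the subtitle.
#' @export
autoplot.ppi_roc <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$fpr, y = .data$tpr)
  ) +
    ggplot2::geom_abline(
      slope = 1, intercept = 0, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate",
      y = "True-positive rate",
      title = "Receiver operating characteristic",
      subtitle = sprintf(
        "AUC = %.3f (%d positives, %d negatives)",
        object$auc, object$n_pos, object$n_neg
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-bin likelihood ratios
#'
#' One panel per evidence type; the horizontal line at LR = 1 marks
#' uninformative bins.
#'
#' @param object A `ppi_lr_table`.
#' @param ... Unused.
#' @return A ggplot of log10 LR per bin, faceted by evidence type.
#' @export
autoplot.ppi_lr_table <- function(object, ...) {
  tab <- as_tibble(object) %>%
    group_by(evidence) %>%
    mutate(bin = factor(bin, levels = unique(bin))) %>%
    ungroup()
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$bin, y = .data$lr)
  ) +
    ggplot2::geom_hline(
      yintercept = 1, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~evidence, scales = "free_x") +
    ggplot2::labs(
      x = "Evidence bin", y = "Likelihood ratio (log scale)",
      title = "Per-bin likelihood ratios"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)
    )
}

#' Plot the TP/FP reliability diagnostic
#'
#' @param labels,scores,cutoffs As in [tp_fp_ratio_curve()].
#' @return A ggplot of the TP/FP ratio against the LR cutoff (log-log).
#' @export
plot_tp_fp_ratio <- function(labels, scores, cutoffs) {
  tab <- tp_fp_ratio_curve(labels, scores, cutoffs) %>%
    filter(is.finite(ratio))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cutoff, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "LR cutoff", y = "TP/FP ratio",
      title = "True/false positive ratio versus likelihood cutoff"
    ) +
    ggplot2::theme_minimal()
}

#' Plot SAM observed versus expected order statistics
#'
#' The classic SAM quantile plot: observed ordered d statistics against
#' their permutation expectation, with the delta band and significant
#' genes highlighted.
#'
#' @param object A `ppi_sam`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppi_sam <- function(object, ...) {
  ord <- order(object$genes$d)
  tab <- tibble(
    expected = object$d_expected,
    observed = object$genes$d[ord],
    significant = object$genes$significant[ord]
  )
  delta <- if (is.finite(object$delta)) object$delta else NA_real_
  p <- ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$expected, y = .data$observed,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "Expected order statistic",
      y = "Observed d statistic",
      title = "SAM: observed versus expected",
      subtitle = sprintf(
        "delta = %s, estimated FDR = %.3f, %d significant",
        format(object$delta, digits = 3), object$fdr_estimate,
        sum(object$genes$significant)
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.na(delta)) {
    p <- p +
      ggplot2::geom_abline(
        slope = 1, intercept = delta, linetype = "dotted"
      ) +
      ggplot2::geom_abline(
        slope = 1, intercept = -delta, linetype = "dotted"
      )
  }
  p
}
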