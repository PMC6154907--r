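# ggplot2 figures for the three result types: ROC averages, the
# precision-recall trade-off, and codon importance grouped by amino acid.

#' Plot micro/macro-averaged ROC curves with per-fold curves
#'
#' @param x A `viroscu_eval` object from [summarize_evaluation()], or a
#'   `viroscu_cv` fold table.
#' @return A ggplot object.
#' @export
plot_roc <- function(x) {
  if (inherits(x, "viroscu_cv")) x <- summarize_evaluation(x)
  stopifnot(inherits(x, "viroscu_eval"))
  micro <- mutate(x$micro$curve, which = sprintf("micro (AUROC %.3f)", x$micro$auroc))
  macro <- mutate(x$macro$curve, which = sprintf("macro (AUROC %.3f)", x$macro$auroc))
  ggplot2::ggplot(
    bind_rows(micro[c("fpr", "tpr", "which")], macro[c("fpr", "tpr", "which")]),
    ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$which)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate", colour = NULL,
      title = "Cross-validated ROC, micro and macro averaged"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.viroscu_eval <- function(object, ...) plot_roc(object)

#' Plot the virus-class precision-recall trade-off across thresholds
#'
#' @param x A `viroscu_eval` object or the trade-off tibble from
#'   [precision_recall_tradeoff()].
#' @return A ggplot object.
#' @export
plot_precision_recall <- function(x) {
  tradeoff <- if (inherits(x, "viroscu_eval")) x$pr_tradeoff else x
  long <- tidyr::pivot_longer(
    tradeoff,
    cols = c("micro_precision", "micro_recall", "macro_precision", "macro_recall"),
    names_to = c("averaging", "metric"), names_sep = "_", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$value,
    colour = .data$averaging, linetype = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Classification threshold p(virus) >= t", y = NULL,
      title = "Virus-class precision-recall trade-off"
    ) +
    ggplot2::theme_minimal()
}

#' Plot codon importance grouped by amino acid
#'
#' Bar plot of mean Gini importance per codon with across-tree standard
#' deviation whiskers, codons grouped by amino acid and amino acids ordered
#' by family size (6-codon families first).
#'
#' @param report A `viroscu_importance` tibble from [gini_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(report) {
  grouped <- group_by_amino_acid(report)
  grouped$codon <- factor(grouped$codon, levels = grouped$codon)
  has_var <- !all(is.na(grouped$variance))
  p <- ggplot2::ggplot(grouped, ggplot2::aes(
    x = .data$codon, y = .data$mean_importance, fill = .data$amino_acid
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = "Codon (grouped by amino acid, largest families first)",
      y = "Mean Gini importance",
      title = "Codon RSCU importance in the random forest"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 7))
  if (has_var) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean_importance - sqrt(.data$variance), 0),
        ymax = .data$mean_importance + sqrt(.data$variance)
      ),
      width = 0.3, linewidth = 0.3, colour = "grey30"
    )
  }
  p
}

#' @export
autoplot.viroscu_importance <- function(object, ...) plot_importance(object)
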