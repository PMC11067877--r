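# ggplot2 views of the main result types.

#' Plot classifier evaluation
#'
#' ROC curves, precision-recall curves, or permutation feature importance
#' for a classifier evaluation.
#'
#' @param object An `eicir_eval` from [evaluate()].
#' @param type `"roc"`, `"pr"` or `"importance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eicir_eval <- function(object, type = c("roc", "pr", "importance"),
                                ...) {
  type <- match.arg(type)
  if (type == "roc") {
    labs <- object$pairwise |>
      mutate(label = sprintf("%s (AUROC %.2f)", .data$pair, .data$auroc))
    dat <- left_join(object$curves, select(labs, "pair", "label"),
                     by = "pair")
    ggplot2::ggplot(dat, ggplot2::aes(.data$fpr, .data$tpr,
                                      colour = .data$label)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "pr") {
    labs <- object$pairwise |>
      mutate(label = sprintf("%s (AUPRC %.2f)", .data$pair, .data$auprc))
    dat <- left_join(object$curves, select(labs, "pair", "label"),
                     by = "pair")
    ggplot2::ggplot(dat, ggplot2::aes(.data$recall, .data$precision,
                                      colour = .data$label)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Recall", y = "Precision", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$importance,
                    ggplot2::aes(.data$auroc_drop,
                                 stats::reorder(.data$feature,
                                                .data$auroc_drop),
                                 fill = factor(.data$sign))) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~pair) +
      ggplot2::labs(x = "Mean AUROC drop on permutation", y = NULL,
                    fill = "Association") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-intron retention metrics
#'
#' PIR against intron coverage, sized by middle-window support; the dashed
#' lines mark the validation cutoff `IC >= 0.9` and the CIR cutoff
#' `PIR >= 0.1`.
#'
#' @param metrics Tibble from [intron_metrics()].
#' @param ic_cutoff,pir_cutoff Reference lines (defaults 0.9 and 0.1).
#' @return A ggplot object.
#' @export
plot_retention_metrics <- function(metrics, ic_cutoff = 0.9,
                                   pir_cutoff = 0.1) {
  ggplot2::ggplot(metrics, ggplot2::aes(.data$IC, .data$PIR,
                                        size = .data$I)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = ic_cutoff, linetype = 2) +
    ggplot2::geom_hline(yintercept = pir_cutoff, linetype = 2) +
    ggplot2::labs(x = "Intron coverage (#IC)",
                  y = "Percent intron retention (PIR)",
                  size = "#I") +
    ggplot2::theme_minimal()
}

#' Plot the tau tissue-specificity distribution
#'
#' @param tau_tbl Tibble from [tau()].
#' @return A ggplot object.
#' @export
plot_tau <- function(tau_tbl) {
  ggplot2::ggplot(filter(tau_tbl, !.data$undefined),
                  ggplot2::aes(.data$tau)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::labs(x = "Tissue specificity index (tau)", y = "Features") +
    ggplot2::theme_minimal()
}
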