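#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `erc_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot erc_roc
#' @export
autoplot.erc_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = object$complex_id,
      subtitle = sprintf("AUC = %.3f (one-tailed MW p = %.3g)", object$auc, object$p_mw),
      x = "False positive rate", y = "True positive rate"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null with the observed statistic
#'
#' @param object An `erc_perm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot erc_perm
#' @export
autoplot.erc_perm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = object$statistic,
      subtitle = sprintf("observed = %.3f, p = %.3g (B = %d)", object$observed, object$p, object$B)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a gene-set permutation null
#'
#' @param object An `erc_set_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot erc_set_test
#' @export
autoplot.erc_set_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_erc, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "null mean ftERC",
      subtitle = sprintf(
        "%s: mean ftERC = %.3f, p = %.3g",
        object$set_id %||% "", object$mean_erc, object$p
      )
    ) +
    ggplot2::theme_minimal()
}

#' Mean set ERC versus set size, coloured by kind
#'
#' The study-level view of gene-set ERC: each point is one complex or
#' pathway, its mean ftERC against the number of members contributing.
#'
#' @param set_results Tibble from [set_permutation_tests()].
#' @return A ggplot.
#' @export
plot_set_erc <- function(set_results) {
  ggplot2::ggplot(
    set_results,
    ggplot2::aes(x = .data$n_members, y = .data$mean_erc, colour = .data$kind)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "members", y = "mean ftERC", colour = NULL) +
    ggplot2::theme_minimal()
}
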