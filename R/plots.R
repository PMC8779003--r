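#' Plot a score card as an ordered bar chart
#'
#' @param object A `score_card`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(scm_reference_card())
#' @method autoplot score_card
#' @export
autoplot.score_card <- function(object, ...) {
  d <- tidy(object)
  d$residue <- factor(d$residue, levels = d$residue)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "propensity score",
      title = sprintf("%s propensity score card", object$origin)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2)
  }
  p
}

#' Plot the GA fitness trajectory of a fitted SCM model
#'
#' @param object An `scm_fit`.
#' @param ... Unused.
#' @return A ggplot object showing best fitness per generation and the
#'   initial card's fitness as a dashed reference line.
#' @method autoplot scm_fit
#' @export
autoplot.scm_fit <- function(object, ...) {
  d <- tibble(
    generation = seq_along(object$fitness_history) - 1L,
    fitness = object$fitness_history
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$initial_fitness, linetype = 2) +
    ggplot2::labs(x = "generation", y = "best fitness",
                  title = "GA fitness trajectory") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve from scores and labels
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return A ggplot object; the subtitle reports the AUC.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      subtitle = sprintf("AUC = %.3f", roc_auc(scores, labels))
    ) +
    ggplot2::theme_minimal()
}
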