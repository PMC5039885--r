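# ggplot2 views of the two result objects.

#' Plot the precision-recall curve of an evaluation report
#'
#' @param object An evaluation report from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fpmpn_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("Precision-recall over top-K (%s, AUC = %.3f)",
                                  object$aspect, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the FP/TP curve of an evaluation report
#'
#' @param report An evaluation report.
#' @return A ggplot object.
#' @export
plot_fptp_curve <- function(report) {
  ggplot2::ggplot(report$fptp_curve,
                  ggplot2::aes(x = .data$tp_total, y = .data$fp_total)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Pooled true positives", y = "Pooled false positives",
                  title = sprintf("FP/TP curve (%s)", report$aspect)) +
    ggplot2::theme_minimal()
}

#' Plot the composite scores of a prediction result
#'
#' @param object A prediction result from [predict_functions()].
#' @param ... Unused.
#' @return A ggplot object with one bar per candidate term, selected terms
#'   highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.fpmpn_prediction <- function(object, ...) {
  tb <- tidy(object)
  tb$term <- stats::reorder(tb$term, tb$score)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$term, y = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Composite score",
                  title = sprintf("Predicted functions for %s",
                                  if (nrow(tb)) tb$query[1L] else "")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
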