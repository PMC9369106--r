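# ggplot2 displays for the result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.orbital_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0("ROC: ", object$positive,
                     sprintf(" (AUC = %.2f)", object$auc)),
      x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_model <- function(object, scores = 0:15, ...) {
  ggplot2::ggplot(risk_curve(object, scores),
                  ggplot2::aes(x = .data$score, y = .data$risk)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste("Risk model:", object$entity),
                  x = "Score", y = "Predicted risk") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_fit <- function(object, ...) {
  curve <- risk_curve(object$model,
                      seq(min(object$risk_table$score),
                          max(object$risk_table$score), length.out = 100))
  ggplot2::ggplot(object$risk_table,
                  ggplot2::aes(x = .data$score, y = .data$risk)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), alpha = 0.7) +
    ggplot2::geom_line(data = curve, linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(title = paste("Fitted risk model:", object$positive),
                  x = "Score", y = "Empirical / fitted risk", size = "n") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.orbital_validation <- function(object, ...) {
  curves <- dplyr::bind_rows(lapply(names(object$roc), function(e) {
    dplyr::mutate(object$roc[[e]]$curve,
                  entity = sprintf("%s (AUC %.2f)", e, object$roc[[e]]$auc))
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity,
                               colour = .data$entity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  title = "Score performance in the validation cohort") +
    ggplot2::theme_minimal()
}

#' Score synopsis plot: every sample by all three scores
#'
#' @param report An `orbital_validation`.
#' @return A ggplot object.
#' @export
plot_score_synopsis <- function(report) {
  long <- report$scores
  ggplot2::ggplot(long, ggplot2::aes(x = .data$entity, y = .data$score,
                                     colour = .data$entity)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.1, alpha = 0.8) +
    ggplot2::facet_wrap(~ .data$panel_entity, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "True entity", y = "Score", colour = NULL,
                  title = "Marker scores by panel and true entity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
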