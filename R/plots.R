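# ggplot2 views of the result objects.

#' @export
autoplot.syn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"run", names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(
      x = NULL, y = "value",
      title = sprintf("%d x %d-fold cross-validation",
                      object$config$n_repeats, object$config$n_folds),
      subtitle = paste(object$features, collapse = " + ")) +
    ggplot2::ylim(0, 1)
}

#' @export
autoplot.syn_search <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$size), y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "features in subset", y = "mean CV accuracy",
                  title = sprintf("%d candidate models", object$n_models))
}

#' @export
autoplot.syn_permtest <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(accuracy = object$null),
                  ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "validation accuracy under scrambled labels",
                  y = "permutations",
                  title = sprintf("Y-scrambling: p = %.4g", object$p_value))
}

#' Bar chart of feature importance of a fitted classifier
#'
#' @param fit A `syn_fit`.
#' @param measure `"gain"` or `"fscore"` (split frequency).
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(fit, measure = c("gain", "fscore")) {
  measure <- match.arg(measure)
  imp <- dplyr::arrange(fit$importance, .data[[measure]])
  imp$feature <- factor(imp$feature, levels = imp$feature)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data[[measure]], y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = measure, y = NULL, title = "Feature importance")
}
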