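#' Plot the training-loss history of a fitted classifier
#'
#' @param object A trained `cpi_dnn`.
#' @param ... Unused.
#' @return A ggplot of loss per epoch.
#' @export
autoplot.cpi_dnn <- function(object, ...) {
  ggplot(object$history, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "steelblue") +
    labs(x = "Epoch", y = "Training BCE loss", title = "Training history") +
    theme_minimal()
}

#' Plot canonical correlations of a fitted correlation space
#'
#' @param object A fitted `cpi_cca`.
#' @param ... Unused.
#' @return A ggplot of per-component canonical correlation.
#' @export
autoplot.cpi_cca <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$component, y = .data$correlation)) +
    geom_col(fill = "steelblue") +
    labs(x = "Canonical component", y = "Correlation",
         title = "Compound-target correlation space") +
    ylim(0, 1) +
    theme_minimal()
}

#' Plot grid-search results
#'
#' @param results The `results` tibble from [grid_search()].
#' @return A ggplot of cross-validated accuracy across candidate models.
#' @export
plot_grid_search <- function(results) {
  df <- dplyr::mutate(results, rank = rank(-.data$cv_accuracy, ties.method = "first"))
  ggplot(df, aes(x = .data$rank, y = .data$cv_accuracy)) +
    geom_point(alpha = 0.6) +
    labs(x = "Model rank", y = "CV accuracy",
         title = "Hyperparameter grid search") +
    theme_minimal()
}

#' Plot the similarity versus shared-active-compounds relationship
#'
#' @param report Output of [similarity_vs_shared_report()].
#' @return A ggplot: per-bin median and interquartile range of shared active
#'   compound counts.
#' @export
plot_similarity_vs_shared <- function(report) {
  df <- dplyr::filter(report, .data$n_pairs > 0)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot(df, aes(x = .data$bin)) +
    geom_errorbar(aes(ymin = .data$shared_q1, ymax = .data$shared_q3), width = 0.25) +
    geom_point(aes(y = .data$shared_median), color = "darkorange", size = 2) +
    labs(x = "Protein-protein embedding distance bin",
         y = "Shared active compounds",
         title = "Embedding distance vs shared active compounds") +
    theme_minimal()
}
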