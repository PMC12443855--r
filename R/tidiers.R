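# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.cv_report <- function(x, ...) {
  as_tibble(x$metrics)
}

#' @export
glance.cv_report <- function(x, ...) {
  tibble(mean_accuracy = mean(x$metrics$accuracy),
         sd_accuracy = sd(x$metrics$accuracy),
         mean_macro_f1 = mean(x$metrics$macro_f1),
         mean_macro_auc = mean(x$auc$macro_auc),
         n_features = x$n_features,
         n_splits = x$scheme$n_splits,
         n_repeats = x$scheme$n_repeats)
}

#' @export
tidy.feature_selection <- function(x, ...) {
  left_join(x$importance, x$ranks, by = "feature_id") |>
    mutate(selected = .data$feature_id %in% x$selected)
}

#' @export
glance.feature_selection <- function(x, ...) {
  tibble(n_input = x$n_input, n_selected = length(x$selected),
         reduction = 1 - length(x$selected) / max(x$n_input, 1))
}

#' @export
tidy.shapley_attribution <- function(x, ...) {
  d <- dim(x$phi)
  tibble(sample_id = rep(x$sample_ids %||% seq_len(d[1]), times = d[2] * d[3]),
         feature_id = rep(rep(x$feature_ids, each = d[1]), times = d[3]),
         class = rep(x$classes, each = d[1] * d[2]),
         phi = as.vector(x$phi))
}

#' @export
glance.shapley_attribution <- function(x, ...) {
  tibble(n_samples = dim(x$phi)[1], n_features = dim(x$phi)[2],
         n_classes = dim(x$phi)[3],
         local_accuracy_error = local_accuracy_error(x))
}

#' @export
tidy.scenario_report <- function(x, ...) {
  purrr::map_dfr(names(x$reports), function(ds)
    purrr::map_dfr(names(x$reports[[ds]]), function(m)
      purrr::map_dfr(c("full", "selected"), function(fs)
        mutate(tidy(x$reports[[ds]][[m]][[fs]]),
               dataset = ds, model = m, feature_set = fs, .before = 1))))
}

#' @export
glance.scenario_report <- function(x, ...) {
  as_tibble(x$benefit)
}

#' Plot fold accuracies of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = factor(.data$rep), y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "repeat", y = "fold accuracy",
                  title = sprintf("%s, %d features", object$model,
                                  object$n_features)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the four importance views of a selection
#'
#' Log-scale pairwise view of forest impurity vs boosting gain, coloured by
#' consensus membership.
#'
#' @param object A `feature_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_selection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$imp_rf, y = .data$imp_xgb,
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_sqrt() + ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "forest impurity importance",
                  y = "boosting gain importance",
                  colour = "consensus") +
    ggplot2::theme_minimal()
}

#' Plot top features of an attribution, by mean |phi|
#'
#' @param object A `shapley_attribution`.
#' @param top_n Number of features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shapley_attribution <- function(object, top_n = 20, ...) {
  g <- shap_global(object) |>
    arrange(dplyr::desc(.data$score)) |>
    head(top_n)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$score,
                                  y = stats::reorder(.data$feature_id,
                                                     .data$score))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL) +
    ggplot2::theme_minimal()
}

#' Feature-density track along the genome
#'
#' @param windows Output of [density_windows()].
#' @return A ggplot faceted by chromosome.
#' @export
plot_density_windows <- function(windows) {
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = (.data$win_start + .data$win_end) / 2e6,
                               y = .data$n, colour = .data$kind)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "features per window") +
    ggplot2::theme_minimal()
}
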