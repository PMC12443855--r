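# Consensus feature selection: train both ensembles on the labelled
# matrix, score every feature from four views (forest impurity decrease,
# boosting gain, mean |Shapley| over each model) and retain the strict
# intersection of the four non-zero sets.

#' Assemble the four-view importance table
#'
#' @param rf,xgb Fitted handles from [train_rf()] / [train_xgb()].
#' @param attr_rf,attr_xgb Their [attribution()]s (computed on the training
#'   matrix when omitted — only possible for the RF handle, which retains
#'   its training data; pass both explicitly otherwise).
#' @return Tibble of class `"importance_table"`: `feature_id`, `imp_rf`,
#'   `imp_xgb`, `shap_rf`, `shap_xgb`.
#' @export
importance_table <- function(rf, xgb, attr_rf, attr_xgb) {
  stopifnot(identical(rf$feature_ids, xgb$feature_ids))
  out <- tibble(feature_id = rf$feature_ids,
                imp_rf = model_importance(rf)$importance,
                imp_xgb = model_importance(xgb)$importance,
                shap_rf = shap_global(attr_rf)$score,
                shap_xgb = shap_global(attr_xgb)$score)
  if (any(out$imp_rf < 0 | out$imp_xgb < 0 | out$shap_rf < 0 |
            out$shap_xgb < 0))
    abort("importance scores must be non-negative")
  class(out) <- c("importance_table", class(out))
  out
}

#' Consensus selection from an importance table
#'
#' A feature is retained iff all four importance views are strictly
#' positive — no epsilon: tree importances and exact attributions are exact
#' sums, so zero means the models never used the feature.  The selection is
#' ordered by mean rank across the four views (rank 1 = largest score).
#'
#' @param table An [importance_table()].
#' @return Tibble with `feature_id` and `mean_rank` for the selected
#'   features, best-ranked first.  Empty selections are allowed (with a
#'   warning).
#' @export
consensus_select <- function(table) {
  keep <- table$imp_rf > 0 & table$imp_xgb > 0 &
    table$shap_rf > 0 & table$shap_xgb > 0
  if (!any(keep)) {
    warn("consensus selection is empty: no feature is non-zero in all four views")
    return(tibble(feature_id = character(), mean_rank = numeric()))
  }
  ranks <- cbind(rank(-table$imp_rf), rank(-table$imp_xgb),
                 rank(-table$shap_rf), rank(-table$shap_xgb))
  tibble(feature_id = table$feature_id, mean_rank = rowMeans(ranks))[keep, ] |>
    arrange(.data$mean_rank)
}

#' Train both ensembles and select the consensus feature set
#'
#' Trains the random forest and the boosted ensemble on the full labelled
#' matrix, attributes both with exact Shapley values, builds the four-view
#' [importance_table()] and applies [consensus_select()].  Selecting on the
#' full data set mirrors the original analysis design; for honest
#' generalisation estimates use `nested_selection = TRUE` in
#' [cross_validate()], which redoes this inside every training fold.
#'
#' @param mm A labelled `methylation_matrix`.
#' @param rf_config,xgb_config Model configurations.
#' @param labels Optional label override.
#' @return An object of class `"feature_selection"`: list with `selected`
#'   (ordered feature ids), `importance` (the table), `rf`, `xgb`,
#'   `attr_rf`, `attr_xgb`, `n_input`.
#' @export
select_features <- function(mm, rf_config = dormclass::rf_config(),
                            xgb_config = dormclass::xgb_config(),
                            labels = NULL) {
  rf <- train_rf(mm, rf_config, labels = labels)
  xgb <- train_xgb(mm, xgb_config, labels = labels)
  attr_rf <- attribution(rf, mm)
  attr_xgb <- attribution(xgb, mm)
  tab <- importance_table(rf, xgb, attr_rf, attr_xgb)
  sel <- consensus_select(tab)
  structure(list(selected = sel$feature_id, ranks = sel,
                 importance = tab, rf = rf, xgb = xgb,
                 attr_rf = attr_rf, attr_xgb = attr_xgb,
                 n_input = nrow(tab)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d of %d features retained (%.2f%%)\n",
              length(x$selected), x$n_input,
              100 * length(x$selected) / max(x$n_input, 1)))
  if (length(x$selected))
    cat("  top:", paste(head(x$selected, 5), collapse = ", "), "\n")
  invisible(x)
}
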