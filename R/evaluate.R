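# Repeated stratified k-fold evaluation: fold construction with exact
# stratification guarantees, the metric suite (accuracy, per-class and
# macro precision/recall/F1, one-vs-rest macro AUC, pooled confusion
# matrices) and the paired significance test of the selection benefit.

#' Cross-validation scheme
#'
#' 3 folds for the three-stage scenario (the 9-sample minority class still
#' puts three paradormancy samples in every fold), 10 folds for the
#' two-stage scenario.
#'
#' @param n_splits Number of folds (>= 2).
#' @param n_repeats Number of repeats of the whole fold construction.
#' @param seed Integer seed; folds are deterministic given it.
#' @return A list of class `"cv_scheme"`.
#' @export
cv_scheme <- function(n_splits = 3L, n_repeats = 10L, seed = 1L) {
  if (n_splits < 2) abort("`n_splits` must be >= 2")
  structure(list(n_splits = as.integer(n_splits),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)), class = "cv_scheme")
}

#' Stratified fold assignments
#'
#' Per repeat, samples of each class are shuffled and dealt into folds so
#' that per-fold class counts differ from proportionality by at most one;
#' with every class count >= the fold count, every fold contains every
#' class.
#'
#' @param labels Character or factor label vector.
#' @param scheme A [cv_scheme()].
#' @return List of length `n_repeats`; each element an integer vector of
#'   fold ids (1..n_splits) per sample.
#' @export
stratified_folds <- function(labels, scheme) {
  labels <- as.character(labels)
  cnt <- table(labels)
  small <- names(cnt)[cnt < scheme$n_splits]
  if (length(small))
    abort(sprintf("class '%s' has %d samples, fewer than %d folds",
                  small[1], cnt[[small[1]]], scheme$n_splits))
  seeded(scheme$seed, {
    lapply(seq_len(scheme$n_repeats), function(r) {
      fold <- integer(length(labels))
      for (cl in names(cnt)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- sample(rep_len(seq_len(scheme$n_splits), length(idx)))
      }
      fold
    })
  })
}

#' Metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted.  Per-class precision, recall
#' and F1 use the 0/0 -> 0 convention (with a warning); macro metrics are
#' unweighted class means.
#'
#' @param cm Square non-negative integer matrix with identical row/column
#'   names.
#' @return List with `overall` (one-row tibble: `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`) and `per_class`.
#' @export
metrics_from_confusion <- function(cm) {
  if (nrow(cm) != ncol(cm)) abort("confusion matrix must be square")
  if (any(cm < 0)) abort("confusion matrix must be non-negative")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  tp <- unname(diag(cm))
  pred_tot <- unname(colSums(cm))
  true_tot <- unname(rowSums(cm))
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warn(sprintf("%s undefined (0/0) for class %s; reported as 0",
                   what, paste(classes[bad], collapse = ", ")))
    ifelse(den == 0, 0, num / den)
  }
  precision <- safe_div(tp, pred_tot, "precision")
  recall <- safe_div(tp, true_tot, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  list(overall = tibble(accuracy = sum(tp) / sum(cm),
                        macro_precision = mean(precision),
                        macro_recall = mean(recall),
                        macro_f1 = mean(f1)),
       per_class = tibble(class = classes, precision = precision,
                          recall = recall, f1 = f1,
                          support = as.integer(true_tot)))
}

# one-vs-rest macro AUC from class probabilities
macro_auc <- function(truth, prob) {
  classes <- colnames(prob)
  aucs <- vapply(classes, function(cl) {
    y <- as.integer(truth == cl)
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, 0)
  mean(aucs, na.rm = TRUE)
}

train_model <- function(model, mm, rf_config, xgb_config, labels = NULL) {
  switch(model,
         rf = train_rf(mm, rf_config, labels = labels),
         xgb = train_xgb(mm, xgb_config, labels = labels),
         abort(sprintf("unknown model '%s'", model)))
}

#' Repeated stratified cross-validation of one model on one feature set
#'
#' Trains on each training split only and predicts the held-out fold.
#' With `nested_selection = TRUE` consensus feature selection is redone
#' inside every training fold (no information from the held-out fold
#' reaches the selection), and the fold model is refit on the fold-selected
#' features.
#'
#' @param mm A labelled `methylation_matrix`.
#' @param model `"rf"` or `"xgb"`.
#' @param scheme A [cv_scheme()].
#' @param rf_config,xgb_config Model configurations (`rf_config` is also
#'   used for the nested selector's forest).
#' @param folds Optional precomputed [stratified_folds()] output, so that
#'   several calls share identical fold assignments (required for the
#'   paired selection-benefit test).
#' @param nested_selection Redo consensus selection per training fold.
#' @return Object of class `"cv_report"`: list with `metrics` (per repeat
#'   and fold), `per_class`, `confusion` (pooled over everything), `auc`
#'   (per repeat), `folds`, `model`, `scheme`, `n_features`.
#' @export
cross_validate <- function(mm, model = c("rf", "xgb"),
                           scheme = cv_scheme(),
                           rf_config = dormclass::rf_config(),
                           xgb_config = dormclass::xgb_config(),
                           folds = NULL,
                           nested_selection = FALSE) {
  model <- match.arg(model)
  labels <- mm$meta$stage
  classes <- intersect(dormancy_stages, unique(labels))
  folds <- folds %||% stratified_folds(labels, scheme)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  metrics <- list(); per_class <- list(); aucs <- list()
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    prob_r <- matrix(NA_real_, length(labels), length(classes),
                     dimnames = list(NULL, classes))
    for (f in sort(unique(fold))) {
      test <- fold == f
      tr_mm <- new_methylation_matrix(mm$values[!test, , drop = FALSE],
                                      mm$features, mm$meta[!test, ])
      if (nested_selection) {
        sel <- suppressWarnings(select_features(tr_mm, rf_config, xgb_config))
        if (length(sel$selected) == 0)
          warn("nested selection empty in a fold; using all features there")
        else tr_mm <- subset_features(tr_mm, sel$selected)
      }
      fit <- train_model(model, tr_mm, rf_config, xgb_config)
      te_x <- mm$values[test, colnames(tr_mm$values), drop = FALSE]
      prob <- predict(fit, te_x, type = "prob")
      pred <- predict(fit, te_x, type = "class")
      prob_full <- matrix(0, nrow(prob), length(classes),
                          dimnames = list(NULL, classes))
      prob_full[, colnames(prob)] <- prob
      prob_r[test, ] <- prob_full
      cm <- table(factor(labels[test], levels = classes),
                  factor(pred, levels = classes))
      cm <- unclass(cm)
      pooled <- pooled + cm
      m <- suppressWarnings(metrics_from_confusion(cm))
      metrics[[length(metrics) + 1]] <-
        mutate(m$overall, rep = r, fold = f, .before = 1)
      per_class[[length(per_class) + 1]] <-
        mutate(m$per_class, rep = r, fold = f, .before = 1)
    }
    aucs[[r]] <- tibble(rep = r, macro_auc = macro_auc(labels, prob_r))
  }
  structure(list(metrics = bind_rows(metrics),
                 per_class = bind_rows(per_class),
                 confusion = pooled,
                 auc = bind_rows(aucs),
                 folds = folds, model = model, scheme = scheme,
                 classes = classes,
                 n_features = ncol(mm$values)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s on %d features, %d-fold x %d repeats\n",
              x$model, x$n_features, x$scheme$n_splits, x$scheme$n_repeats))
  cat(sprintf("  mean accuracy %.3f, mean macro AUC %.3f\n",
              mean(x$metrics$accuracy), mean(x$auc$macro_auc)))
  invisible(x)
}

#' Paired significance test of the selection benefit
#'
#' Two-sided paired t-test on per-(repeat, fold) accuracy differences
#' between the selected-feature and full-feature runs.  The two score
#' vectors must come from identical fold assignments.  Zero-variance
#' differences are flagged degenerate and reported with p = 1 rather than
#' propagating NaN.
#'
#' @param scores_full,scores_selected Equal-length numeric vectors of
#'   per-fold accuracies, or two `cv_report`s (their fold assignments are
#'   then checked for identity).
#' @return One-row tibble: `t`, `p`, `mean_diff`, `df`, `degenerate`.
#' @export
selection_benefit_test <- function(scores_full, scores_selected) {
  if (inherits(scores_full, "cv_report")) {
    if (!identical(scores_full$folds, scores_selected$folds))
      abort("fold assignments differ; the paired test requires identical folds")
    scores_full <- scores_full$metrics$accuracy
    scores_selected <- scores_selected$metrics$accuracy
  }
  if (length(scores_full) != length(scores_selected))
    abort("paired score vectors must have equal length")
  d <- scores_selected - scores_full
  if (sd(d) == 0 || length(d) < 2) {
    warn("degenerate paired test: zero-variance differences")
    return(tibble(t = NA_real_, p = 1, mean_diff = mean(d),
                  df = length(d) - 1, degenerate = TRUE))
  }
  tt <- t.test(scores_selected, scores_full, paired = TRUE)
  tibble(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
         df = unname(tt$parameter), degenerate = FALSE)
}

#' Evaluate full vs selected feature sets across datasets and models
#'
#' The driver for a whole classification scenario: for each dataset (e.g.
#' cytosine-level and region-level matrices) it runs consensus selection,
#' then cross-validates both models on the full and the selected feature
#' set under identical fold assignments, and runs the paired
#' selection-benefit test per (dataset, model).  The two-stage scenario
#' drops paradormancy samples before anything else.
#'
#' @param matrices Named list of labelled `methylation_matrix` objects
#'   (same samples in each).
#' @param scenario `"3stage"` or `"2stage"`.
#' @param models Character subset of `c("rf", "xgb")`.
#' @param scheme A [cv_scheme()]; defaults to 3 folds for `"3stage"` and 10
#'   folds for `"2stage"`.
#' @param rf_config,xgb_config Model configurations.
#' @return Object of class `"scenario_report"`: list with `reports` (nested
#'   list dataset -> model -> full/selected `cv_report`), `benefit`
#'   (tibble), `selections`, `scenario`.
#' @export
run_scenario <- function(matrices, scenario = c("3stage", "2stage"),
                         models = c("rf", "xgb"),
                         scheme = NULL,
                         rf_config = dormclass::rf_config(),
                         xgb_config = dormclass::xgb_config()) {
  scenario <- match.arg(scenario)
  models <- match.arg(models, several.ok = TRUE)
  scheme <- scheme %||%
    cv_scheme(n_splits = if (scenario == "3stage") 3L else 10L)
  if (scenario == "2stage")
    matrices <- lapply(matrices, subset_stages,
                       stages = c("endodormancy", "ecodormancy"))
  st <- lapply(matrices, function(m) sort(m$meta$sample_id))
  if (!all(vapply(st, identical, TRUE, st[[1]])))
    abort("matrices must share the same sample set")

  reports <- list(); selections <- list(); benefit <- list()
  for (ds in names(matrices)) {
    mm <- matrices[[ds]]
    sel <- select_features(mm, rf_config, xgb_config)
    selections[[ds]] <- sel
    if (length(sel$selected) == 0)
      abort(sprintf("empty consensus selection for dataset '%s'", ds))
    mm_sel <- subset_features(mm, sel$selected)
    folds <- stratified_folds(mm$meta$stage, scheme)
    for (model in models) {
      full <- cross_validate(mm, model, scheme, rf_config, xgb_config,
                             folds = folds)
      selr <- cross_validate(mm_sel, model, scheme, rf_config, xgb_config,
                             folds = folds)
      reports[[ds]][[model]] <- list(full = full, selected = selr)
      benefit[[length(benefit) + 1]] <-
        mutate(selection_benefit_test(full, selr),
               dataset = ds, model = model, .before = 1)
    }
  }
  structure(list(reports = reports, benefit = bind_rows(benefit),
                 selections = selections, scenario = scenario,
                 scheme = scheme),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s\n", x$scenario))
  for (ds in names(x$reports)) for (m in names(x$reports[[ds]])) {
    r <- x$reports[[ds]][[m]]
    cat(sprintf("  %s/%s: accuracy %.3f (full, %d features) -> %.3f (selected, %d)\n",
                ds, m, mean(r$full$metrics$accuracy), r$full$n_features,
                mean(r$selected$metrics$accuracy), r$selected$n_features))
  }
  print(x$benefit)
  invisible(x)
}
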