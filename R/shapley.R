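# Exact Shapley attribution for the fitted tree ensembles.  Both model
# handles are lowered to a common tree-table form (children indexed after
# parents, covers from the training data) and attributed by the exact
# per-leaf subset-enumeration algorithm in src/treeshap.cpp.  A pure-R
# exhaustive-enumeration oracle over whole-ensemble feature subsets is
# exported for small models.

empty_value_matrix <- function(n_nodes, k) matrix(0, n_nodes, k)

rf_tree_tables <- function(handle) {
  fit <- handle$fit
  k <- length(handle$classes)
  X <- handle$x_train
  inbag <- fit$inbag
  lapply(seq_len(fit$ntree), function(t) {
    tr <- randomForest::getTree(fit, t, labelVar = FALSE)
    is_leaf <- tr[, "status"] == -1
    feature <- ifelse(is_leaf, -1L, as.integer(tr[, "split var"]) - 1L)
    yes <- ifelse(is_leaf, -1L, as.integer(tr[, "left daughter"]) - 1L)
    no <- ifelse(is_leaf, -1L, as.integer(tr[, "right daughter"]) - 1L)
    value <- empty_value_matrix(nrow(tr), k)
    cls <- as.integer(tr[is_leaf, "prediction"])
    value[cbind(which(is_leaf), cls)] <- 1 / fit$ntree
    cover <- tree_cover_cpp(feature, as.numeric(tr[, "split point"]),
                            yes, no, TRUE, X, as.numeric(inbag[, t]))
    list(feature = as.integer(feature), split = as.numeric(tr[, "split point"]),
         yes = as.integer(yes), no = as.integer(no),
         cover = as.numeric(cover), value = value, le = TRUE)
  })
}

xgb_tree_tables <- function(handle) {
  k <- length(handle$classes)
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = handle$fit))
  split_trees <- split(dt, dt$Tree)
  lapply(split_trees, function(d) {
    d <- d[order(d$Node), ]
    is_leaf <- d$Feature == "Leaf"
    feature <- ifelse(is_leaf, -1L,
                      match(d$Feature, handle$feature_ids) - 1L)
    if (anyNA(feature)) abort("xgboost split feature not in feature ids")
    idx <- setNames(seq_len(nrow(d)) - 1L, d$ID)
    yes <- ifelse(is_leaf, -1L, idx[d$Yes])
    no <- ifelse(is_leaf, -1L, idx[d$No])
    value <- empty_value_matrix(nrow(d), k)
    klass <- (d$Tree[1] %% k) + 1L
    value[is_leaf, klass] <- d$Gain[is_leaf]
    # thresholds are single precision inside xgboost; make them
    # float32-exact so double comparisons reproduce its routing
    split <- as.numeric(round_float32_cpp(matrix(d$Split, nrow = 1)))
    list(feature = as.integer(feature), split = split,
         yes = as.integer(unname(yes)), no = as.integer(unname(no)),
         cover = as.numeric(d$Cover), value = value, le = FALSE)
  })
}

xgb_base_score <- function(fit) {
  cfg <- xgboost::xgb.config(fit)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

tree_tables <- function(handle) {
  if (inherits(handle, "dormclass_rf")) rf_tree_tables(handle)
  else if (inherits(handle, "dormclass_xgb")) xgb_tree_tables(handle)
  else abort("attribution supports tree-ensemble handles only")
}

attribution_output <- function(handle, x) {
  if (inherits(handle, "dormclass_rf")) {
    predict(handle, x, type = "prob")
  } else {
    p <- predict(handle$fit, xgboost::xgb.DMatrix(x, nthread = 1),
                 outputmargin = TRUE)
    if (is.null(dim(p)))
      p <- matrix(p, nrow(x), byrow = TRUE)
    colnames(p) <- handle$classes
    p
  }
}

#' Exact Shapley attribution of a fitted ensemble
#'
#' Computes, for every (sample, class, feature), the exact path-dependent
#' Shapley value of the model output: the per-class vote fraction for the
#' random forest, the per-class margin for gradient boosting.  No sampling
#' is involved; attributions satisfy local accuracy (they sum, with the
#' base value, to the model output) up to floating-point error.
#'
#' @param handle A `dormclass_rf` or `dormclass_xgb` handle.
#' @param mm A `methylation_matrix` or numeric matrix whose columns match
#'   the training features.
#' @return An object of class `"shapley_attribution"`: list with `phi`
#'   (samples x features x classes array), `base` (per-class base value),
#'   `output` (per-sample per-class model output), `classes`,
#'   `feature_ids`, `sample_ids`, `model`.
#' @export
attribution <- function(handle, mm) {
  x <- if (inherits(mm, "methylation_matrix")) mm$values else as.matrix(mm)
  x <- x[, handle$feature_ids, drop = FALSE]
  # xgboost routes samples with single-precision comparisons; mirror it
  if (inherits(handle, "dormclass_xgb")) x <- round_float32_cpp(x)
  k <- length(handle$classes)
  trees <- tree_tables(handle)
  phi <- treeshap_cpp(trees, x, k)
  base <- as.numeric(treeshap_base_cpp(trees, k))
  if (inherits(handle, "dormclass_xgb"))
    base <- base + xgb_base_score(handle$fit)
  dimnames(phi) <- list(rownames(x), handle$feature_ids, handle$classes)
  structure(list(phi = phi, base = setNames(base, handle$classes),
                 output = attribution_output(handle, x),
                 classes = handle$classes, feature_ids = handle$feature_ids,
                 sample_ids = rownames(x),
                 model = class(handle)[1]),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<shapley_attribution> %s: %d samples x %d features x %d classes\n",
              x$model, d[1], d[2], d[3]))
  cat(sprintf("  max |sum(phi) + base - output| = %.3g\n",
              local_accuracy_error(x)))
  invisible(x)
}

#' Largest local-accuracy violation of an attribution
#'
#' For every sample and class, `sum(phi) + base` must equal the model
#' output; this returns the largest absolute deviation.
#'
#' @param attr A `shapley_attribution`.
#' @return A single number.
#' @export
local_accuracy_error <- function(attr) {
  recon <- apply(attr$phi, c(1, 3), sum) +
    matrix(attr$base, nrow(attr$output), length(attr$base), byrow = TRUE)
  max(abs(recon - attr$output))
}

#' Global per-feature attribution score
#'
#' The mean of |phi| over samples and classes: the multiclass global view
#' used for consensus feature selection.
#'
#' @param attr A `shapley_attribution`.
#' @return Tibble with `feature_id` and `score`, in input feature order.
#' @export
shap_global <- function(attr) {
  tibble(feature_id = attr$feature_ids,
         score = apply(abs(attr$phi), 2, mean))
}

# recursive path-dependent conditional expectation of one tree, all classes
expvalue_tree <- function(tree, x, S, node = 1L) {
  f <- tree$feature[node]
  if (f < 0) return(tree$value[node, ])
  yes <- tree$yes[node] + 1L
  no <- tree$no[node] + 1L
  if ((f + 1L) %in% S) {
    goleft <- if (tree$le) x[f + 1L] <= tree$split[node]
              else x[f + 1L] < tree$split[node]
    expvalue_tree(tree, x, S, if (goleft) yes else no)
  } else {
    (tree$cover[yes] * expvalue_tree(tree, x, S, yes) +
       tree$cover[no] * expvalue_tree(tree, x, S, no)) / tree$cover[node]
  }
}

#' Exhaustive Shapley oracle for small models
#'
#' Computes Shapley values by direct enumeration of every feature subset of
#' the whole ensemble, with the same path-dependent conditional expectation
#' as [attribution()].  Exponential in the number of distinct features the
#' ensemble uses, so it refuses models with more than `max_features`; it
#' exists as an independent reference for validating the fast path.
#'
#' @param handle A fitted ensemble handle.
#' @param x A single sample: numeric vector in training-feature order.
#' @param max_features Refuse enumeration beyond this many distinct
#'   features (default 15).
#' @return List with `phi` (features x classes matrix) and `base`.
#' @export
shapley_exhaustive <- function(handle, x, max_features = 15) {
  if (inherits(handle, "dormclass_xgb"))
    x <- as.numeric(round_float32_cpp(matrix(x, nrow = 1)))
  trees <- tree_tables(handle)
  k <- length(handle$classes)
  p <- length(handle$feature_ids)
  used <- sort(unique(unlist(lapply(trees, function(t)
    t$feature[t$feature >= 0])))) + 1L
  d <- length(used)
  if (d > max_features)
    abort(sprintf("model uses %d features; exhaustive oracle capped at %d",
                  d, max_features))
  fS <- function(S) {
    Reduce(`+`, lapply(trees, expvalue_tree, x = x, S = S))
  }
  phi <- matrix(0, p, k, dimnames = list(handle$feature_ids, handle$classes))
  for (i in used) {
    others <- setdiff(used, i)
    for (s in 0:length(others)) {
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      combs <- if (s == 0) list(integer(0))
               else lapply(asplit(combn(seq_along(others), s), 2),
                           function(j) others[j])
      for (S in combs)
        phi[i, ] <- phi[i, ] + w * (fS(c(S, i)) - fS(S))
    }
  }
  base <- fS(integer(0))
  if (inherits(handle, "dormclass_xgb"))
    base <- base + xgb_base_score(handle$fit)
  list(phi = phi, base = setNames(base, handle$classes))
}
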