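# The two tree-ensemble classifiers.  Random forests aggregate per-tree
# class votes by majority (documented tie-break: lowest class index in the
# canonical stage order); gradient boosting fits a regularised softmax
# objective.  Both handles expose per-class probabilities, built-in
# importances and the tree structures needed for exact Shapley attribution.

#' Random-forest configuration
#'
#' @param n_trees Number of trees in the vote.
#' @param mtry Features tried per split; `NULL` for the library default
#'   (square root of the feature count).
#' @param seed Integer seed.
#' @return A list of class `"rf_config"`.
#' @export
rf_config <- function(n_trees = 500L, mtry = NULL, seed = 1L) {
  if (n_trees < 1) abort("`n_trees` must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)), class = "rf_config")
}

#' Gradient-boosting configuration
#'
#' Hyperparameters of the regularised boosting objective: `reg_gamma`
#' penalises each additional leaf, `reg_lambda` is the L2 penalty on leaf
#' weights.
#'
#' @param n_rounds Boosting rounds.
#' @param learning_rate Shrinkage per round (> 0).
#' @param reg_gamma Minimum loss reduction to split (>= 0).
#' @param reg_lambda L2 regularisation on leaf weights (>= 0).
#' @param max_depth Maximum tree depth.
#' @param subsample,colsample_bytree Row/column subsampling fractions.
#' @param seed Integer seed.
#' @return A list of class `"xgb_config"`.
#' @export
xgb_config <- function(n_rounds = 600L, learning_rate = 0.1, reg_gamma = 0.75,
                       reg_lambda = 1, max_depth = 2L, subsample = 1,
                       colsample_bytree = 0.1, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  if (reg_gamma < 0 || reg_lambda < 0)
    abort("regularisation parameters must be >= 0")
  structure(list(n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate, reg_gamma = reg_gamma,
                 reg_lambda = reg_lambda, max_depth = as.integer(max_depth),
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 seed = as.integer(seed)), class = "xgb_config")
}

mm_xy <- function(mm, labels = NULL) {
  x <- if (inherits(mm, "methylation_matrix")) mm$values else as.matrix(mm)
  y <- labels %||% (if (inherits(mm, "methylation_matrix")) mm$meta$stage
                    else abort("labels required for a bare matrix"))
  lev <- intersect(dormancy_stages, unique(y))
  if (!length(lev)) lev <- sort(unique(y))
  y <- factor(y, levels = lev)
  if (anyNA(x)) abort("matrix contains missing values")
  if (nlevels(droplevels(y)) < 2) abort("need at least two classes to train")
  list(x = x, y = y)
}

#' Train the random-forest classifier
#'
#' @param mm A `methylation_matrix` (stage labels taken from its metadata)
#'   or a bare numeric matrix with `labels` supplied.
#' @param config An [rf_config()].
#' @param labels Optional label vector overriding the matrix metadata.
#' @return A handle of class `"dormclass_rf"` supporting [predict()],
#'   [model_importance()] and [attribution()].
#' @export
train_rf <- function(mm, config = rf_config(), labels = NULL) {
  d <- mm_xy(mm, labels)
  fit <- seeded(config$seed,
    randomForest::randomForest(
      x = d$x, y = d$y, ntree = config$n_trees,
      mtry = config$mtry %||% max(1, floor(sqrt(ncol(d$x)))),
      keep.forest = TRUE, keep.inbag = TRUE))
  structure(list(fit = fit, classes = levels(d$y),
                 feature_ids = colnames(d$x), x_train = d$x,
                 config = config),
            class = "dormclass_rf")
}

#' Train the gradient-boosting classifier
#'
#' Always fits a multiclass softmax model (two-class problems are the
#' special case with two classes) so that per-class probabilities and
#' attributions have one shape everywhere.
#'
#' @inheritParams train_rf
#' @param config An [xgb_config()].
#' @return A handle of class `"dormclass_xgb"`.
#' @export
train_xgb <- function(mm, config = xgb_config(), labels = NULL) {
  d <- mm_xy(mm, labels)
  k <- nlevels(d$y)
  dtrain <- xgboost::xgb.DMatrix(d$x, label = as.integer(d$y) - 1L,
                                 nthread = 1)
  params <- list(objective = "multi:softprob", num_class = k,
                 max_depth = config$max_depth, eta = config$learning_rate,
                 gamma = config$reg_gamma, lambda = config$reg_lambda,
                 subsample = config$subsample,
                 colsample_bytree = config$colsample_bytree,
                 nthread = 1, seed = config$seed, base_score = 0.5)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = config$n_rounds, verbose = 0)
  structure(list(fit = fit, classes = levels(d$y),
                 feature_ids = colnames(d$x), config = config),
            class = "dormclass_xgb")
}

#' Majority vote over per-tree class predictions
#'
#' Returns the class with the most votes; ties are broken by the lowest
#' class index in `classes` (canonical stage order by default).
#'
#' @param votes Character vector of per-tree predicted labels.
#' @param classes Class order used for tie-breaking; defaults to the
#'   canonical dormancy-stage order restricted to the observed labels.
#' @return A single class label.
#' @export
#' @examples
#' majority_vote(c("endodormancy", "endodormancy", "ecodormancy"))
majority_vote <- function(votes, classes = NULL) {
  if (length(votes) == 0) abort("empty vote vector")
  classes <- classes %||% intersect(dormancy_stages, unique(votes))
  if (!length(classes)) classes <- sort(unique(votes))
  unknown <- setdiff(unique(votes), classes)
  if (length(unknown))
    abort(sprintf("vote for unknown class '%s'", unknown[1]))
  counts <- table(factor(votes, levels = classes))
  classes[which.max(counts)]   # which.max takes the first (lowest-index) max
}

#' @export
predict.dormclass_rf <- function(object, newdata = NULL,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x_train
       else if (inherits(newdata, "methylation_matrix")) newdata$values
       else as.matrix(newdata)
  votes <- predict(object$fit, x, type = "vote", norm.votes = FALSE)
  votes <- votes[, object$classes, drop = FALSE]
  if (type == "prob") {
    p <- votes / rowSums(votes)
    rownames(p) <- rownames(x)
    return(p)
  }
  # same tie-break as majority_vote(): first maximum in canonical order
  object$classes[apply(votes, 1, which.max)]
}

#' @export
predict.dormclass_xgb <- function(object, newdata = NULL,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "methylation_matrix")) newdata$values
       else as.matrix(newdata)
  p <- predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  if (is.null(dim(p))) p <- matrix(p, nrow(x), byrow = TRUE)
  colnames(p) <- object$classes
  rownames(p) <- rownames(x)
  if (type == "prob") p else object$classes[apply(p, 1, which.max)]
}

#' Built-in feature importance of a fitted ensemble
#'
#' Impurity-decrease (Gini) importance for the random forest, total split
#' gain for gradient boosting.  Every input feature appears in the output;
#' features never used by the model score exactly zero.
#'
#' @param object A `dormclass_rf` or `dormclass_xgb` handle.
#' @return Tibble with `feature_id` and `importance`.
#' @export
model_importance <- function(object) UseMethod("model_importance")

#' @export
model_importance.dormclass_rf <- function(object) {
  imp <- randomForest::importance(object$fit, type = 2)
  tibble(feature_id = object$feature_ids,
         importance = as.numeric(imp[object$feature_ids, 1]))
}

#' @export
model_importance.dormclass_xgb <- function(object) {
  # raw (unnormalised) total split gain per feature, from the tree dump
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = object$fit))
  dt <- dt[dt$Feature != "Leaf", , drop = FALSE]
  gain <- setNames(rep(0, length(object$feature_ids)), object$feature_ids)
  if (nrow(dt)) {
    agg <- tapply(dt$Gain, dt$Feature, sum)
    gain[names(agg)] <- pmax(agg, 0)
  }
  tibble(feature_id = object$feature_ids, importance = unname(gain))
}
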