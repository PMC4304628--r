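#' Stratified train/test split
#'
#' Disjoint, exhaustive, stratified by the label column: each class
#' contributes `ceiling(train_fraction * n_class)` rows to the training
#' set (so 502 rows at 70% with an 18/484 class balance give a test set
#' of 150). Seed-deterministic.
#'
#' @param data tibble with a logical/two-level `label_col`.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @param label_col name of the label column.
#' @return list with `train` and `test` tibbles.
#' @export
split_train_test <- function(data, train_fraction = 0.70, seed = 1L,
                             label_col = "beneficial") {
  stopifnot(nrow(data) >= 10, train_fraction > 0, train_fraction < 1)
  lab <- data[[label_col]]
  idx_train <- local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), lab), function(ix) {
      n_tr <- ceiling(train_fraction * length(ix))
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  train <- data[sort(idx_train), , drop = FALSE]
  test <- data[-sort(idx_train), , drop = FALSE]
  if (length(unique(train[[label_col]])) < 2 ||
      length(unique(test[[label_col]])) < 2)
    stop("a label class is absent from the train or test split",
         call. = FALSE)
  list(train = train, test = test)
}

#' Train a gradient-boosted tree classifier on a labeled ensemble
#'
#' Boosted ensemble of shallow regression trees with logistic loss
#' (depth <= 3, 300 trees, shrinkage 0.1 by default), predicting the
#' probability of a beneficial trial outcome from log10 rate constants.
#' Class imbalance (beneficial outcomes are a few percent) is handled by
#' weighting the positive class, configurable off.
#'
#' @param train training tibble.
#' @param features character vector of feature columns; defaults to all
#'   numeric columns except the label.
#' @param label_col logical label column.
#' @param max_depth,nrounds,eta boosting hyperparameters.
#' @param class_weight weight positives by the negative/positive ratio.
#' @param seed seed (the fit itself is deterministic single-threaded).
#' @return object of class `trial_classifier`.
#' @export
train_classifier <- function(train, features = NULL,
                             label_col = "beneficial", max_depth = 3L,
                             nrounds = 300L, eta = 0.1,
                             class_weight = TRUE, seed = 1L) {
  y <- as.integer(train[[label_col]])
  if (length(unique(y)) < 2)
    stop("training data contain a single class; model degenerate",
         call. = FALSE)
  if (is.null(features))
    features <- setdiff(names(train)[vapply(train, is.numeric, TRUE)],
                        label_col)
  X <- as.matrix(train[, features, drop = FALSE])
  if (anyNA(X)) stop("missing feature values", call. = FALSE)
  spw <- if (class_weight) sum(y == 0) / sum(y == 1) else 1
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- local_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, scale_pos_weight = spw, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0))
  structure(list(booster = booster, features = features,
                 label_col = label_col, threshold = 0.5,
                 config = list(max_depth = max_depth, nrounds = nrounds,
                               eta = eta, class_weight = class_weight)),
            class = "trial_classifier")
}

#' @export
print.trial_classifier <- function(x, ...) {
  cat(sprintf(
    "<trial_classifier: %d features, %d trees, depth %d, eta %.3g>\n",
    length(x$features), x$config$nrounds, x$config$max_depth,
    x$config$eta))
  invisible(x)
}

#' Predicted probability of a beneficial outcome
#'
#' @param object a `trial_classifier`.
#' @param newdata tibble containing the model's feature columns.
#' @param ... unused.
#' @return numeric vector of class probabilities.
#' @export
predict.trial_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  stats::predict(object$booster, X)
}

#' Relative influence of each feature
#'
#' Friedman split-improvement importance: the per-feature sum of loss
#' reductions over every split using that feature, across all trees,
#' normalized to total 100%.
#'
#' @param model a `trial_classifier`.
#' @return tibble: `parameter`, `relative_influence_pct`, `rank`,
#'   descending; zero for features never split on.
#' @export
relative_influence <- function(model) {
  ## gain summed over split nodes from the tree dump (identical to the
  ## booster's gain importance, but robust for single-feature models)
  trees <- xgboost::xgb.model.dt.tree(model = model$booster)
  splits <- trees[trees$Feature != "Leaf", ]
  if (nrow(splits) == 0)
    stop("model contains no splits; influence undefined", call. = FALSE)
  by_feat <- tapply(splits$Gain, splits$Feature, sum)
  gain <- stats::setNames(rep(0, length(model$features)), model$features)
  gain[names(by_feat)] <- by_feat
  pct <- 100 * gain / sum(gain)
  out <- tibble::tibble(parameter = names(pct),
                        relative_influence_pct = unname(pct))
  out <- dplyr::arrange(out, dplyr::desc(.data$relative_influence_pct))
  out$rank <- seq_len(nrow(out))
  out
}

#' Confusion counts and rates on a test set
#'
#' @param model a `trial_classifier`.
#' @param test test tibble with features and the label column.
#' @return one-row tibble: `tp`, `fn`, `fp`, `tn`, `tpr`, `fpr`,
#'   `accuracy`.
#' @export
test_metrics <- function(model, test) {
  stopifnot(nrow(test) > 0)
  truth <- as.logical(test[[model$label_col]])
  pred <- predict(model, test) >= model$threshold
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  tibble::tibble(tp = tp, fn = fn, fp = fp, tn = tn,
                 tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 accuracy = (tp + tn) / length(truth))
}

#' Outcome enrichment under a restriction
#'
#' Beneficial and harmful fractions inside a subset of ensemble records,
#' next to the unrestricted fractions. The subset can be a logical
#' vector, a predicate on the records, or a `trial_classifier` (rows
#' predicted beneficial at its threshold).
#'
#' @param records tibble with a `label` column in
#'   beneficial/harmful/insignificant.
#' @param subset logical vector, one-argument function, or
#'   `trial_classifier`.
#' @return one-row tibble with subset and overall counts/fractions and
#'   an `empty` flag.
#' @export
enrichment <- function(records, subset) {
  stopifnot("label" %in% names(records))
  keep <- if (is.logical(subset)) subset
  else if (inherits(subset, "trial_classifier"))
    predict(subset, records) >= subset$threshold
  else if (is.function(subset)) subset(records)
  else stop("subset must be logical, a function, or a trial_classifier",
            call. = FALSE)
  stopifnot(length(keep) == nrow(records))
  frac <- function(lab, x) if (length(x) == 0) NA_real_ else mean(x == lab)
  sub <- records$label[keep]
  tibble::tibble(
    subset_size = length(sub), total_size = nrow(records),
    beneficial_count = sum(sub == "beneficial"),
    beneficial_fraction = frac("beneficial", sub),
    harmful_count = sum(sub == "harmful"),
    harmful_fraction = frac("harmful", sub),
    overall_beneficial_fraction = frac("beneficial", records$label),
    overall_harmful_fraction = frac("harmful", records$label),
    empty = length(sub) == 0)
}

#' Enrichment when one parameter is restricted by a threshold
#'
#' The what-if reading of the influence ranking: if a parameter's true
#' value were known to lie on one side of a threshold, how would the
#' beneficial fraction change?
#'
#' @param records ensemble records with `label` and the parameter column
#'   (natural scale).
#' @param parameter column name.
#' @param threshold cutoff on the natural scale.
#' @param direction `"below"` keeps values < threshold, `"above"` keeps
#'   values > threshold.
#' @return as [enrichment()].
#' @export
conditional_threshold_analysis <- function(records, parameter, threshold,
                                           direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (!parameter %in% names(records))
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  keep <- if (direction == "below") records[[parameter]] < threshold
  else records[[parameter]] > threshold
  enrichment(records, keep)
}
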