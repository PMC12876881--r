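# Viability classification: gradient-boosted decision trees (xgboost) on the
# 32-feature texture vectors, validated by stratified k-fold cross-validation
# with ROC/AUC reporting, a learning-curve analysis over dataset fractions,
# gain-based feature importance, and longitudinal track scoring.

.as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    keep <- vapply(features, is.numeric, logical(1)) &
      !(names(features) %in% c("label", "day", "track_id"))
    features <- as.matrix(features[, keep, drop = FALSE])
  }
  if (any(is.na(features))) stop("missing feature values are not accepted")
  features
}

.as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("HIGH", "LOW"))) stop("labels must be HIGH/LOW")
    return(as.integer(labels == "HIGH"))
  }
  as.integer(labels)
}

# stratified fold assignment: per class, shuffle then deal round-robin
.stratifiedFolds <- function(y, k, seed) {
  .withSeed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop("need at least k samples per class (class ", cl, " has ",
             length(idx), ")")
      idx <- sample(idx)
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

.fit_gbt <- function(x, y, params, seed) {
  .withSeed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = params$eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds)
  })
}

#' Stratified k-fold cross-validation of the viability classifier
#'
#' Fits a gradient-boosted decision-tree ensemble on each training split and
#' scores the held-out fold; reports the per-fold ROC curve and AUC and
#' their mean. Folds are stratified by class so every fold sees both
#' statuses; each sample is validated exactly once.
#'
#' @param features numeric matrix or feature data.frame (32 texture
#'   columns; \code{label}/\code{day}/\code{track_id} columns are ignored).
#' @param labels HIGH/LOW factor or character vector, or a 0/1 vector
#'   (1 = HIGH viability).
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and fitting.
#' @param params list overriding the \code{classify} group of
#'   [defaultConfig()].
#' @param folds optional precomputed integer fold assignment (overrides the
#'   stratified draw; used e.g. to rescore identical splits).
#' @return A \code{CVResult}: list with \code{fold_auc}, \code{mean_auc},
#'   \code{roc} (per-fold list of FPR/TPR data.frames), \code{folds},
#'   \code{predictions} and \code{seed}.
#' @export
crossValidate <- function(features, labels, k = 10, seed = 1,
                          params = list(), folds = NULL) {
  p <- utils::modifyList(defaultConfig()$classify, params)
  x <- .as_feature_matrix(features)
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("single-class input")
  if (is.null(folds)) folds <- .stratifiedFolds(y, k, seed)
  stopifnot(length(folds) == length(y))
  pred <- numeric(length(y))
  fold_auc <- numeric(k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- .fit_gbt(x[!te, , drop = FALSE], y[!te], p, seed + f)
    pred[te] <- predict(fit, xgboost::xgb.DMatrix(x[te, , drop = FALSE],
                                                  nthread = 1))
    r <- pROC::roc(y[te], pred[te], quiet = TRUE, direction = "<",
                   levels = c(0, 1))
    fold_auc[f] <- as.numeric(pROC::auc(r))
    rocs[[f]] <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc), roc = rocs,
                 folds = folds, predictions = pred, seed = seed, k = k),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: %d-fold stratified CV, mean AUC %.3f (range %.3f-%.3f)\n",
              x$k, x$mean_auc, min(x$fold_auc), max(x$fold_auc)))
  invisible(x)
}

#' Learning curve over dataset fractions
#'
#' Repeats the cross-validation on stratified subsamples of the dataset,
#' from 10% to 100% of the samples in steps of 10% by default, and records
#' the mean AUC per fraction. At fraction 1 the result equals
#' [crossValidate()] on the full set with the same seed.
#'
#' @param features,labels,k,seed,params as in [crossValidate()].
#' @param fractions dataset fractions to evaluate.
#' @return data.frame with \code{fraction}, \code{n} and \code{mean_auc}.
#' @export
learningCurve <- function(features, labels, fractions = seq(0.1, 1, by = 0.1),
                          k = 10, seed = 1, params = list()) {
  x <- .as_feature_matrix(features)
  y <- .as_binary(labels)
  out <- data.frame(fraction = fractions, n = NA_integer_,
                    mean_auc = NA_real_)
  for (i in seq_along(fractions)) {
    fr <- fractions[i]
    idx <- .withSeed(seed + 1000 + i, {
      sel <- integer(0)
      for (cl in unique(y)) {
        ci <- which(y == cl)
        n_cl <- max(k, round(fr * length(ci)))
        if (n_cl > length(ci)) n_cl <- length(ci)
        sel <- c(sel, if (n_cl == length(ci)) ci else sample(ci, n_cl))
      }
      sort(sel)
    })
    if (length(unique(y[idx])) < 2 || min(table(y[idx])) < k)
      stop("fraction ", fr, " leaves too few samples per class")
    cv <- crossValidate(x[idx, , drop = FALSE], y[idx], k = k, seed = seed,
                        params = params)
    out$n[i] <- length(idx)
    out$mean_auc[i] <- cv$mean_auc
  }
  out
}

#' Fit the viability classifier on the full dataset
#'
#' @param features,labels as in [crossValidate()].
#' @param seed integer seed.
#' @param params list overriding the \code{classify} group of
#'   [defaultConfig()].
#' @return A fitted xgboost model with the feature names attached.
#' @export
fitViabilityModel <- function(features, labels, seed = 1, params = list()) {
  p <- utils::modifyList(defaultConfig()$classify, params)
  x <- .as_feature_matrix(features)
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("single-class input")
  fit <- .fit_gbt(x, y, p, seed)
  attr(fit, "feature_names") <- colnames(x)
  fit
}

#' Gain-based feature importance of a fitted classifier
#'
#' Importances are the normalized total gain contributed by each feature
#' across all tree splits (they sum to 1); features never used by the
#' ensemble get importance 0.
#'
#' @param model a model from [fitViabilityModel()].
#' @param top number of top features to flag (default 9).
#' @return data.frame with \code{feature}, \code{gain}, \code{rank} and
#'   logical \code{top}, in decreasing gain order.
#' @export
featureImportance <- function(model, top = 9) {
  imp <- xgboost::xgb.importance(model = model)
  fn <- attr(model, "feature_names")
  gain <- stats::setNames(rep(0, length(fn)), fn)
  gain[imp$Feature] <- imp$Gain
  gain <- gain / sum(gain)
  ord <- order(-gain)
  data.frame(feature = fn[ord], gain = as.numeric(gain[ord]),
             rank = seq_along(fn), top = seq_along(fn) <= top,
             row.names = NULL)
}

#' Score tracked organoids day by day
#'
#' Predicts the per-day viability status of each tracked organoid at the
#' model's probability threshold and summarizes each track by its overall
#' viability: the fraction of observed days predicted HIGH (0 means the
#' organoid was always classified low-viability).
#'
#' @param model a model from [fitViabilityModel()].
#' @param feature_table data.frame with \code{track_id}, \code{day} and the
#'   32 feature columns.
#' @param cutoff probability threshold for a HIGH call (default 0.5).
#' @return List with \code{per_day} (data.frame \code{track_id, day,
#'   probability, status}) and \code{overall} (data.frame \code{track_id,
#'   n_days, n_high, overall_viability}).
#' @export
scoreTracks <- function(model, feature_table, cutoff = 0.5) {
  stopifnot(all(c("track_id", "day") %in% names(feature_table)))
  x <- .as_feature_matrix(feature_table)
  fn <- attr(model, "feature_names")
  if (!is.null(fn) && !is.null(colnames(x))) x <- x[, fn, drop = FALSE]
  prob <- predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
  per_day <- data.frame(track_id = feature_table$track_id,
                        day = feature_table$day, probability = prob,
                        status = ifelse(prob > cutoff, "HIGH", "LOW"))
  ids <- unique(per_day$track_id)
  overall <- do.call(rbind, lapply(ids, function(id) {
    sub <- per_day[per_day$track_id == id, ]
    if (nrow(sub) == 0) stop("track with zero scorable days: ", id)
    data.frame(track_id = id, n_days = nrow(sub),
               n_high = sum(sub$status == "HIGH"),
               overall_viability = mean(sub$status == "HIGH"))
  }))
  list(per_day = per_day, overall = overall)
}

#' Overall viability from per-day status calls
#'
#' The worked summary statistic: with \code{n_high} of \code{n_days} days
#' called HIGH, the overall viability is \code{n_high / n_days} (e.g. 8 of
#' 10 days gives 0.80, 7 of 10 gives 0.70).
#'
#' @param n_high days predicted HIGH.
#' @param n_days observed days (> 0).
#' @return Fraction in [0, 1].
#' @export
overallViability <- function(n_high, n_days) {
  stopifnot(n_days > 0, n_high >= 0, n_high <= n_days)
  n_high / n_days
}
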