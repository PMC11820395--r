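#' Gradient-boosting hyperparameters
#'
#' The fixed, non-optimized tree-booster settings used throughout:
#' binary-logistic gbtree with eta 0.3, gamma 0, max_depth 6,
#' min_child_weight 1, subsample 1, colsample_bytree 1, 50 rounds.
#'
#' @param nrounds boosting rounds.
#' @param ... overrides for individual parameters.
#' @return A named list of parameters plus `nrounds`.
#' @export
booster_hyperparameters <- function(nrounds = 50, ...) {
  params <- list(booster = "gbtree", objective = "binary:logistic",
                 eta = 0.3, gamma = 0, max_depth = 6, min_child_weight = 1,
                 subsample = 1, colsample_bytree = 1)
  dots <- list(...)
  params[names(dots)] <- dots
  c(params, list(nrounds = nrounds))
}

#' Donor-exclusion leave-one-out splits
#'
#' One split per sample; the training set excludes every sample from the
#' test sample's donor, so donor identity can never leak into training.
#'
#' @param metadata data.frame with a `donor_id` column (one row per sample,
#'   in matrix column order).
#' @return A list of `list(train, test)` index pairs.
#' @export
leave_one_donor_out_splits <- function(metadata) {
  donor <- metadata$donor_id
  if (is.null(donor) || anyNA(donor)) stop("donor_id must be present for every sample")
  lapply(seq_along(donor), function(i) {
    list(train = which(donor != donor[i]), test = i)
  })
}

#' ROC curve and AUC
#'
#' ROC by descending-score thresholding with ties grouped; AUC by the
#' trapezoidal rule, which equals the pair-counting statistic
#' P(score_pos > score_neg) + 1/2 P(equal).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical/0-1 vector, TRUE/1 = positive class.
#' @return A list with `roc` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into single threshold steps
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  roc <- data.frame(threshold = s[last_of_tie],
                    fpr = fp / n_neg, tpr = tp / n_pos)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Donor-exclusion LOOCV with gradient-boosted trees
#'
#' Fits the booster once per donor (all donor-exclusion splits for one
#' donor share the same training set) and records each sample's
#' out-of-fold probability of the positive class. Accuracy thresholds the
#' probability at 0.5 (exact ties predicted positive); ROC/AUC are pooled
#' over all out-of-fold probabilities.
#'
#' Fitting is single-threaded with an explicit seed; with subsample and
#' colsample at 1 repeated runs on identical input are identical.
#'
#' @param m `sebum_matrix` at stage `top_selected` (features x samples;
#'   transposed internally to samples x features for fitting).
#' @param labels per-sample class labels (2 classes).
#' @param metadata data.frame with `donor_id` per sample, in matrix column
#'   order (rows matched by `sample_id` when present).
#' @param positive label treated as the positive class; default: the
#'   second level of `factor(labels)`.
#' @param hyperparams from [booster_hyperparameters()].
#' @param seed integer seed for the fits.
#' @return A `cv_result`: `samples` data.frame (sample_id, truth, prob,
#'   predicted), `accuracy` (percent), `roc`, `auc`, `positive`, `seed`.
#' @export
run_cv <- function(m, labels, metadata, positive = NULL,
                   hyperparams = booster_hyperparameters(), seed = 1) {
  assert_stage(m, "top_selected")
  if (!is.null(metadata$sample_id)) {
    metadata <- metadata[match(m$sample_ids, metadata$sample_id), ]
    if (anyNA(metadata$sample_id)) stop("metadata is missing matrix samples")
  }
  lab <- factor(labels)
  if (nlevels(lab) != 2) stop("labels must have exactly 2 classes")
  if (is.null(positive)) positive <- levels(lab)[2]
  if (!positive %in% levels(lab)) stop("positive class not among labels")
  y <- as.integer(lab == positive)

  x <- t(as.matrix(m$values))
  colnames(x) <- sprintf("mz_%.2f", m$bin_edges)
  splits <- leave_one_donor_out_splits(metadata)
  donors <- metadata$donor_id
  prob <- rep(NA_real_, nrow(x))

  nrounds <- hyperparams$nrounds
  params <- hyperparams[setdiff(names(hyperparams), "nrounds")]
  params$nthread <- 1
  params$seed <- seed
  set.seed(seed)
  for (d in unique(donors)) {
    test <- which(donors == d)
    train <- which(donors != d)
    if (length(unique(y[train])) < 2) {
      stop("training fold for donor ", d, " contains a single class")
    }
    dtrain <- xgboost::xgb.DMatrix(x[train, , drop = FALSE],
                                   label = y[train], nthread = 1)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = nrounds, verbose = 0)
    prob[test] <- predict(booster,
                          xgboost::xgb.DMatrix(x[test, , drop = FALSE],
                                               nthread = 1))
  }
  stopifnot(!anyNA(prob))

  predicted <- prob >= 0.5  # ties predicted positive
  accuracy <- 100 * mean(predicted == (y == 1))
  rc <- roc_auc(prob, y == 1)
  structure(list(
    samples = data.frame(sample_id = m$sample_ids,
                         truth = as.character(lab),
                         prob = prob,
                         predicted = ifelse(predicted, positive,
                                            setdiff(levels(lab), positive))),
    accuracy = accuracy, roc = rc$roc, auc = rc$auc,
    positive = positive, seed = seed, hyperparams = hyperparams,
    splits = splits), class = "cv_result")
}

#' Percent of correctly classified samples
#'
#' @param cv a `cv_result` from [run_cv()].
#' @return Accuracy in percent (0.5-probability threshold, ties positive).
#' @export
classification_accuracy <- function(cv) {
  if (!inherits(cv, "cv_result")) stop("expected a cv_result")
  cv$accuracy
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d samples, positive class '%s': accuracy %.1f%%, AUC %.3f\n",
              nrow(x$samples), x$positive, x$accuracy, x$auc))
  invisible(x)
}
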