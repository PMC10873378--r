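# Molecule descriptors pooled from encoder memory, baseline descriptors,
# and the fold-based downstream property-prediction harness.

#' Pool encoder memory into a fixed-width descriptor
#'
#' Four pooling methods over the `L x d` encoder memory of one molecule:
#' `mean` (column averages, width d), `first_token` (first row, width d),
#' `concat4` (mean, max, first, last; width 4d), `concat6` (mean, max, min,
#' standard deviation, first, last; width 6d). The standard deviation is the
#' population form, so a single-position memory pools to zeros.
#'
#' @param memory `L x d` numeric matrix (`L >= 1`).
#' @param method pooling method.
#' @return numeric vector with attribute `method`.
#' @export
pool_memory <- function(memory,
                        method = c("mean", "first_token", "concat4",
                                   "concat6")) {
  method <- match.arg(method)
  stopifnot(is.matrix(memory), nrow(memory) >= 1)
  L <- nrow(memory)
  colmean <- colMeans(memory)
  first <- memory[1, ]
  last <- memory[L, ]
  v <- switch(method,
    mean = colmean,
    first_token = first,
    concat4 = c(colmean, apply(memory, 2, max), first, last),
    concat6 = {
      sd_pop <- sqrt(colMeans(memory^2) - colmean^2)
      sd_pop[!is.finite(sd_pop)] <- 0
      c(colmean, apply(memory, 2, max), apply(memory, 2, min),
        sd_pop, first, last)
    })
  attr(v, "method") <- method
  v
}

#' Baseline descriptors
#'
#' `random_uniform`: values drawn uniformly from \[0, 1\] (width `n_bits`),
#' reproducible from the RNG state. `ecfp`: the folded binary
#' extended-connectivity fingerprint of the molecule (radius 2, width
#' `n_bits` by default).
#'
#' @param kind `"random_uniform"` or `"ecfp"`.
#' @param smiles molecule SMILES (required for `"ecfp"`).
#' @param n_bits descriptor width.
#' @param radius ECFP radius.
#' @return numeric vector of length `n_bits`.
#' @export
baseline_descriptor <- function(kind = c("random_uniform", "ecfp"),
                                smiles = NULL, n_bits = 2048L, radius = 2L) {
  kind <- match.arg(kind)
  if (kind == "random_uniform") return(stats::runif(n_bits))
  stopifnot(!is.null(smiles))
  fp <- fingerprint_smiles(smiles, "ecfp", radius, n_bits)[1, ]
  if (anyNA(fp)) stop("invalid SMILES for ECFP baseline: ", smiles)
  as.numeric(fp)
}

#' Pool descriptors for a whole corpus
#'
#' Tokenizes each molecule's source string, runs the encoder, and pools the
#' memory.
#'
#' @param model trained (or untrained) model.
#' @param corpus corpus data.frame.
#' @param vocab source vocabulary.
#' @param method pooling method, see [pool_memory()].
#' @param source_mode which string feeds the encoder (see
#'   [make_translation_pairs()]).
#' @return numeric matrix, one row per molecule.
#' @export
corpus_descriptors <- function(model, corpus, vocab,
                               method = "mean",
                               source_mode = "randomized") {
  pairs <- make_translation_pairs(corpus, vocab, vocab, source_mode)
  rows <- lapply(pairs, function(p)
    pool_memory(encoder_memory(model, p$source), method))
  do.call(rbind, rows)
}

make_folds <- function(n, n_folds) {
  fold <- rep_len(seq_len(n_folds), n)
  sample(fold)
}

xgb_fit_predict <- function(x_tr, y_tr, x_te, task, params, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(x_tr, label = y_tr)
  booster <- xgboost::xgb.train(
    params = c(params, list(
      objective = if (task == "regression") "reg:squarederror"
                  else "binary:logistic",
      nthread = 1)),
    data = dtrain, nrounds = nrounds, verbose = 0)
  stats::predict(booster, xgboost::xgb.DMatrix(x_te))
}

score_predictions <- function(y, yhat, task) {
  if (task == "regression") return(sqrt(mean((y - yhat)^2)))
  # AUROC via the rank statistic (Mann-Whitney)
  pos <- yhat[y == 1]; neg <- yhat[y == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("degenerate labels: a fold contains a single class")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Fold-based downstream property prediction
#'
#' Trains a gradient-boosted-tree predictor per train/validation/test fold
#' with a bounded random hyperparameter search on the validation split, and
#' scores the held-out test fold: RMSE for regression, AUROC for
#' classification.
#'
#' @param descriptors numeric matrix (rows = molecules).
#' @param labels numeric (regression) or 0/1 (classification) vector.
#' @param task `"regression"` or `"classification"`.
#' @param n_folds number of folds (default 5).
#' @param n_trials hyperparameter draws per fold (default 8).
#' @return list: `fold_scores`, `mean`, `sd` (unbiased), `task`, `metric`.
#' @export
downstream_eval <- function(descriptors, labels,
                            task = c("regression", "classification"),
                            n_folds = 5L, n_trials = 8L) {
  task <- match.arg(task)
  stopifnot(nrow(descriptors) == length(labels), n_folds >= 2)
  if (task == "classification" && length(unique(labels)) < 2)
    stop("degenerate labels: single class")
  n <- nrow(descriptors)
  fold <- make_folds(n, n_folds)
  scores <- numeric(n_folds)
  better <- if (task == "regression") `<` else `>`
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    rest <- which(fold != f)
    val_take <- max(1L, round(length(rest) / n_folds))
    val_idx <- sample(rest, val_take)
    tr_idx <- setdiff(rest, val_idx)
    best <- NULL
    for (trial in seq_len(n_trials)) {
      params <- list(eta = stats::runif(1, 0.05, 0.4),
                     max_depth = sample(2:8, 1),
                     subsample = stats::runif(1, 0.6, 1),
                     colsample_bytree = stats::runif(1, 0.5, 1))
      nrounds <- sample(c(25L, 50L, 100L), 1)
      yhat_val <- xgb_fit_predict(descriptors[tr_idx, , drop = FALSE],
                                  labels[tr_idx],
                                  descriptors[val_idx, , drop = FALSE],
                                  task, params, nrounds)
      sc <- score_predictions(labels[val_idx], yhat_val, task)
      if (is.null(best) || better(sc, best$score))
        best <- list(params = params, nrounds = nrounds, score = sc)
    }
    fit_idx <- c(tr_idx, val_idx)
    yhat <- xgb_fit_predict(descriptors[fit_idx, , drop = FALSE],
                            labels[fit_idx],
                            descriptors[test_idx, , drop = FALSE],
                            task, best$params, best$nrounds)
    scores[f] <- score_predictions(labels[test_idx], yhat, task)
  }
  list(fold_scores = scores, mean = mean(scores), sd = stats::sd(scores),
       task = task,
       metric = if (task == "regression") "RMSE" else "AUROC")
}
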