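# Random-forest classification of case status from taxon abundances:
# leave-one-out cross-validated probabilities, rank-formulation ROC/AUC with
# a DeLong confidence interval, rank-level model comparison, and
# mean-decrease-in-impurity feature importance.

#' Leave-one-out cross-validated random-forest scores
#'
#' For each sample, a forest is trained on the remaining n-1 samples and the
#' held-out sample's predicted probability of the positive class (fraction of
#' trees voting for it) is recorded. Deterministic under a fixed seed.
#'
#' Each tree draws a class-balanced stratified bootstrap (both classes
#' sampled at the minority-class size). With unequal groups the vanilla
#' bootstrap lets the training prior drift as each sample is held out, which
#' biases out-of-fold scores and pulls the null AUC below 0.5; balanced
#' sampling keeps the prior fixed across folds.
#'
#' @param x an [AbundanceExperiment-class] or samples-by-taxa matrix.
#' @param groups factor of class labels.
#' @param n_trees trees per forest (default 500).
#' @param seed RNG seed.
#' @param positive label of the positive class (default "ALL").
#' @return named numeric vector of out-of-fold scores, one per sample.
#' @export
loocvScores <- function(x, groups, n_trees = 500, seed = 42,
                        positive = "ALL") {
  m <- .abMatrix(x)
  groups <- factor(groups)
  if (nrow(m) < 4) stop("input error: need n >= 4 samples")
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("input error: need both classes with n >= 2")
  if (!positive %in% levels(groups))
    stop("input error: positive class '", positive, "' absent")
  set.seed(seed)
  scores <- vapply(seq_len(nrow(m)), function(i) {
    g_train <- droplevels(groups[-i])
    n_min <- min(table(g_train))
    fit <- randomForest::randomForest(m[-i, , drop = FALSE], g_train,
                                      ntree = n_trees, strata = g_train,
                                      sampsize = c(n_min, n_min))
    unname(stats::predict(fit, m[i, , drop = FALSE],
                          type = "prob")[, positive])
  }, numeric(1))
  stats::setNames(scores, rownames(m))
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted 1/2; the
#' curve is the (FPR, TPR) step function over score thresholds; the 95% CI is
#' computed by the DeLong method (via \pkg{pROC}).
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels class labels, parallel to scores.
#' @param positive label of the positive class (default "ALL").
#' @param conf_level CI level (default 0.95).
#' @return list of class \code{"chipbiome_roc"}: auc, auc_ci_low,
#'   auc_ci_high, curve (data.frame threshold, fpr, tpr), scores, labels.
#' @export
rocAuc <- function(scores, labels, positive = "ALL", conf_level = 0.95) {
  labels <- factor(labels)
  if (!positive %in% levels(labels) || nlevels(labels) != 2)
    stop("input error: need both classes present")
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop("input error: one class absent")
  r <- rank(scores)                          # average ranks handle ties (1/2)
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- t(vapply(thr, function(t) {
    c(fpr = sum(scores[!is_pos] >= t) / n_neg,
      tpr = sum(scores[is_pos] >= t) / n_pos)
  }, numeric(2)))
  ci <- tryCatch({
    roc_obj <- pROC::roc(response = is_pos, predictor = as.numeric(scores),
                         levels = c(FALSE, TRUE), direction = "<",
                         quiet = TRUE)
    as.numeric(suppressWarnings(pROC::ci.auc(roc_obj,
                                             conf.level = conf_level,
                                             method = "delong")))
  }, error = function(e) c(NA_real_, auc, NA_real_))
  structure(list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[3],
                 curve = data.frame(threshold = thr, fpr = curve[, "fpr"],
                                    tpr = curve[, "tpr"]),
                 scores = scores, labels = labels),
            class = "chipbiome_roc")
}

#' @export
print.chipbiome_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, length(x$scores)))
  invisible(x)
}

#' LOOCV classification report for one taxonomic rank
#'
#' Convenience wrapper: [loocvScores()] then [rocAuc()].
#'
#' @inheritParams loocvScores
#' @return a \code{"chipbiome_roc"} list (see [rocAuc()]).
#' @export
classifyCohort <- function(x, groups, n_trees = 500, seed = 42,
                           positive = "ALL") {
  s <- loocvScores(x, groups, n_trees = n_trees, seed = seed,
                   positive = positive)
  rocAuc(s, groups, positive = positive)
}

#' Compare classification performance across taxonomic ranks
#'
#' Runs the full LOOCV/AUC chain independently on the species-level matrix
#' aggregated to each requested rank.
#'
#' @param x a species-level [AbundanceExperiment-class].
#' @param groups factor of class labels.
#' @param ranks ranks to compare.
#' @param n_trees,seed,positive as in [loocvScores()].
#' @return list with \code{table} (data.frame rank, auc, ci_low, ci_high,
#'   n_features) and \code{reports} (per-rank \code{"chipbiome_roc"}).
#' @export
compareRanks <- function(x, groups,
                         ranks = c("species", "genus", "family", "order"),
                         n_trees = 500, seed = 42, positive = "ALL") {
  stopifnot(is(x, "AbundanceExperiment"))
  reports <- lapply(stats::setNames(ranks, ranks), function(r) {
    xr <- aggregateToRank(x, r)
    rep <- classifyCohort(xr, groups, n_trees = n_trees, seed = seed,
                          positive = positive)
    rep$n_features <- nrow(xr)
    rep
  })
  tab <- do.call(rbind, lapply(ranks, function(r) {
    data.frame(rank = r, auc = reports[[r]]$auc,
               ci_low = reports[[r]]$auc_ci_low,
               ci_high = reports[[r]]$auc_ci_high,
               n_features = reports[[r]]$n_features)
  }))
  list(table = tab, reports = reports)
}

#' Random-forest feature importance
#'
#' Mean decrease in impurity (Gini) from a forest trained on all samples,
#' ranked descending.
#'
#' @inheritParams loocvScores
#' @param top_k rows to keep in the \code{top} table (default 10).
#' @return list: \code{all} (full ranked data.frame taxon, importance) and
#'   \code{top} (first \code{top_k} rows).
#' @export
featureImportance <- function(x, groups, n_trees = 500, seed = 42,
                              top_k = 10) {
  m <- .abMatrix(x)
  groups <- factor(groups)
  set.seed(seed)
  n_min <- min(table(groups))
  fit <- randomForest::randomForest(m, groups, ntree = n_trees,
                                    strata = groups,
                                    sampsize = rep(n_min, nlevels(groups)),
                                    importance = FALSE)
  imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
  df <- data.frame(taxon = names(imp), importance = as.numeric(imp),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$importance), ]
  rownames(df) <- NULL
  list(all = df, top = utils::head(df, top_k))
}
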