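#' Cross-validated discrimination of the risk model
#'
#' Repeated stratified k-fold cross-validation with ROC/Youden reporting:
#' within every repeat the subjects of each class are shuffled into k folds
#' (fold sizes differing by at most one within class), the model is fitted
#' on the training folds with scaling parameters learned on the training
#' data only, and the held-out subjects receive out-of-sample predicted
#' probabilities. Predictions are pooled over folds and repeats for the
#' headline metrics; per-repeat metrics give percentile confidence
#' intervals.
#'
#' @name crossvalidation
NULL

#' Rank-based ROC area under the curve
#'
#' AUC computed from the rank statistic (equivalent to the normalized
#' count of concordant pairs, ties counted half), so it is invariant to any
#' strictly monotone transform of the scores.
#'
#' @param labels binary labels (1/TRUE = event)
#' @param scores predicted scores or probabilities
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(labels, scores) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity/specificity at every distinct threshold (score >= threshold
#' classifies as event).
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `sensitivity`, `specificity`
#' @export
roc_curve <- function(labels, scores) {
  y <- as.logical(labels)
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) mean(scores[y] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!y] < t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Youden-optimal operating point
#'
#' The ROC point maximizing sensitivity + specificity - 1. Ties resolve to
#' the lowest threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden_j`
#' @export
youden_point <- function(labels, scores) {
  rc <- roc_curve(labels, scores)
  j <- rc$sensitivity + rc$specificity - 1
  i <- which.max(j)
  list(threshold = rc$threshold[i], sensitivity = rc$sensitivity[i],
       specificity = rc$specificity[i], youden_j = j[i])
}

# Stratified fold assignment: within each class, shuffled round-robin.
#' @keywords internal
#' @noRd
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("stratification error: class ", cls, " has fewer members (",
           length(idx), ") than folds (", k, ")")
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation of the risk model
#'
#' @param table feature table with a `group` column
#' @param measures covariate column names
#' @param positive event group label
#' @param k folds
#' @param repeats repeated random fold splits
#' @param seed integer seed (one sub-seed per repeat)
#' @param threshold fixed classification threshold for the accuracy metrics
#' @return a `cv_report`: list with pooled `auc`, `balanced_accuracy`,
#'   `acc_pos`, `acc_neg`, `youden` (pooled Youden point), per-repeat
#'   metric data.frame `per_repeat`, percentile CIs `ci` (over repeats),
#'   pooled `predictions` (subject, repeat, fold, y, p), `k`, `repeats`,
#'   `seed`
#' @export
crossvalidate <- function(table, measures, positive = "HCM_VF", k = 5,
                          repeats = 20, seed = 1, threshold = 0.5) {
  y <- as.numeric(table$group == positive)
  n <- length(y)
  X <- as.matrix(table[, measures, drop = FALSE])
  rep_seeds <- spawn_seeds(seed, repeats)
  preds <- vector("list", repeats)
  per_rep <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    folds <- stratified_folds(y, k)
    p_out <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L)
        stop("stratification error: single-class training fold")
      mu <- colMeans(X[tr, , drop = FALSE])
      sds <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sds[sds == 0] <- 1
      Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
      fit <- fit_logistic_newton(Z[tr, , drop = FALSE], y[tr],
                                 strict = FALSE, max_iter = 25)
      p_out[!tr] <- predict(fit, Z[!tr, , drop = FALSE])
    }
    preds[[r]] <- data.frame(repeat_id = r, subject = seq_len(n),
                             fold = folds, y = y, p = p_out)
    yp <- youden_point(y, p_out)
    per_rep[[r]] <- data.frame(
      repeat_id = r,
      auc = roc_auc(y, p_out),
      acc_pos = mean(p_out[y == 1] > threshold),
      acc_neg = mean(p_out[y == 0] <= threshold),
      youden_sens = yp$sensitivity,
      youden_spec = yp$specificity
    )
  }
  pooled <- do.call(rbind, preds)
  per_rep <- do.call(rbind, per_rep)
  per_rep$balanced_accuracy <- (per_rep$acc_pos + per_rep$acc_neg) / 2
  acc_pos <- mean(pooled$p[pooled$y == 1] > threshold)
  acc_neg <- mean(pooled$p[pooled$y == 0] <= threshold)
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  structure(list(
    auc = roc_auc(pooled$y, pooled$p),
    balanced_accuracy = (acc_pos + acc_neg) / 2,
    acc_pos = acc_pos, acc_neg = acc_neg,
    youden = youden_point(pooled$y, pooled$p),
    per_repeat = per_rep,
    ci = list(auc = ci(per_rep$auc),
              balanced_accuracy = ci(per_rep$balanced_accuracy),
              acc_pos = ci(per_rep$acc_pos),
              acc_neg = ci(per_rep$acc_neg)),
    predictions = pooled,
    k = k, repeats = repeats, seed = seed, threshold = threshold,
    measures = measures
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation: %d-fold x %d repeats (%s)\n",
              x$k, x$repeats, paste(x$measures, collapse = " + ")))
  cat(sprintf("  pooled AUC %.3f (repeat CI %.3f-%.3f)\n",
              x$auc, x$ci$auc[1], x$ci$auc[2]))
  cat(sprintf("  balanced accuracy %.3f at threshold %.2f (CI %.3f-%.3f)\n",
              x$balanced_accuracy, x$threshold,
              x$ci$balanced_accuracy[1], x$ci$balanced_accuracy[2]))
  cat(sprintf("  Youden point: sens %.1f%%, spec %.1f%%\n",
              100 * x$youden$sensitivity, 100 * x$youden$specificity))
  invisible(x)
}
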