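#' ROC curve and AUC from decision values
#'
#' Sweeps a threshold over the unique decision values (ties collapsed, which
#' yields diagonal segments, so a constant score gives AUC 0.5) and integrates
#' the curve by the trapezoid rule. The trapezoidal AUC equals the normalised
#' Mann-Whitney pairwise-win count (ties counting one half).
#'
#' @param scores numeric decision values, higher meaning more likely positive.
#' @param truth class labels, two classes present.
#' @param positive the label treated as positive; default: the second factor
#'   level of `truth`.
#' @return list with `points` (matrix of FPR, TPR rows from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, truth, positive = NULL) {
  truth <- factor(truth)
  if (is.null(positive)) positive <- levels(truth)[nlevels(truth)]
  pos <- truth == positive
  if (!any(pos) || all(pos)) stop("both classes must be present in truth")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  ends <- cumsum(rle(s)$lengths)  # last index of each tie group
  tpr <- c(0, cumsum(p)[ends] / sum(pos))
  fpr <- c(0, cumsum(!p)[ends] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = cbind(FPR = fpr, TPR = tpr), auc = auc)
}

binary_metrics <- function(pred_pos, true_pos) {
  tp <- sum(pred_pos & true_pos); tn <- sum(!pred_pos & !true_pos)
  fp <- sum(pred_pos & !true_pos); fn <- sum(!pred_pos & true_pos)
  list(confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Bundle per-subject curvature samples for cross-validation
#'
#' A `cohort_features` object holds, per subject, the raw per-vertex value and
#' area-weight samples for each descriptor channel, so that descriptor ranges
#' can be re-derived from the training subjects of every fold (no test-fold
#' information enters the encoding).
#'
#' @param samples list (one element per subject) of named channel lists, each
#'   channel a list with `values` and `weights`.
#' @param labels diagnostic labels per subject.
#' @param subject_ids subject identifiers.
#' @param feature_type,encoding,bins descriptor settings; `encoding = "raw"`
#'   passes channel values through unchanged (used by the volumetry baseline).
#' @return an object of class `cohort_features`.
#' @export
cohort_features <- function(samples, labels, subject_ids = NULL,
                            feature_type = "shape_operator",
                            encoding = "histogram", bins = 64) {
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_along(samples))
  stopifnot(length(samples) == length(labels))
  structure(list(samples = samples, labels = as.character(labels),
                 subject_ids = subject_ids, feature_type = feature_type,
                 encoding = encoding, bins = bins),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("cohort_features: %d subjects (%s), %s/%s descriptors\n",
              length(x$samples),
              paste(names(table(x$labels)), table(x$labels), collapse = ", "),
              x$feature_type, x$encoding))
  invisible(x)
}

# pooled 1-99 percentile ranges per channel over a subject subset
pooled_ranges <- function(cf, idx) {
  nms <- names(cf$samples[[1L]])
  out <- lapply(nms, function(nm) {
    pooled <- unlist(lapply(cf$samples[idx], function(s) s[[nm]]$values),
                     use.names = FALSE)
    stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
  })
  names(out) <- nms
  out
}

# descriptor matrix for all subjects under fixed channel ranges
descriptor_matrix <- function(cf, ranges = NULL) {
  rows <- lapply(cf$samples, function(s) {
    unlist(lapply(names(s), function(nm) {
      v <- s[[nm]]$values; w <- s[[nm]]$weights
      switch(cf$encoding,
             raw = v,
             quantile = stats::quantile(v, probs = seq(0, 1, length.out = cf$bins),
                                        names = FALSE),
             histogram = {
               v <- winsorize(v)
               rg <- if (!is.null(ranges)) ranges[[nm]] else range(v)
               weighted_histogram(v, w, rg, cf$bins) / length(s)
             })
    }), use.names = FALSE)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- cf$subject_ids
  X
}

#' Cross-validated evaluation of the hierarchical classifier
#'
#' Repeated stratified k-fold cross-validation. Within every training fold
#' the entire preprocessing chain is refitted: descriptor value ranges,
#' Fisher-score ranking, feature z-scoring and the (k, C, gamma) grid search.
#' Stage-1 metrics (NC vs abnormal, positive = abnormal) are computed over
#' all subjects; stage-2 metrics (MCI vs AD, positive = AD) over the truly
#' abnormal subjects only, mirroring per-stage ROC reporting. The overall
#' accuracy is the fraction of subjects whose final hierarchical label equals
#' the true three-class label.
#'
#' @param cf a [cohort_features()] object, or a plain feature matrix (then
#'   `labels` must be given and descriptor ranges are not refitted since the
#'   matrix is already fixed).
#' @param labels required when `cf` is a matrix.
#' @param folds,repeats stratified folds and repetitions.
#' @param seed seed controlling fold assignment and inner tuning; the same
#'   seed reproduces the report bit for bit.
#' @param config tuning settings, see [hier_svm_config()].
#' @return an object of class `eval_report`.
#' @export
cross_validate <- function(cf, labels = NULL, folds = 5, repeats = 5, seed = 1,
                           config = hier_svm_config()) {
  if (is.matrix(cf) || is.data.frame(cf)) {
    if (is.null(labels)) stop("labels required with a plain feature matrix")
    X0 <- as.matrix(cf)
    cf <- cohort_features(lapply(seq_len(nrow(X0)), function(i)
      list(x = list(values = X0[i, ], weights = rep(1, ncol(X0))))),
      labels, encoding = "raw", feature_type = "matrix")
  }
  y <- cf$labels
  n <- length(y)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pred <- list()
  per_fold <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      ranges <- if (cf$encoding == "histogram") pooled_ranges(cf, tr) else NULL
      X <- descriptor_matrix(cf, ranges)
      fit <- hier_svm(X[tr, , drop = FALSE], y[tr], config = config,
                      seed = sample.int(2^30, 1L))
      p <- predict(fit, X[te, , drop = FALSE])
      pred[[length(pred) + 1L]] <- cbind(p, truth = y[te], repeat_ = r, fold = f,
                                         subject = cf$subject_ids[te])
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(repeat_ = r, fold = f, n = length(te),
                   accuracy = mean(p$label == y[te]))
    }
  }
  pred <- do.call(rbind, pred)
  eval_report(pred, do.call(rbind, per_fold),
              meta = list(folds = folds, repeats = repeats, seed = seed,
                          feature_type = cf$feature_type, encoding = cf$encoding))
}

# assemble an eval_report from pooled cross-validated predictions
eval_report <- function(pred, per_fold, meta) {
  truth1 <- pred$truth != "NC"
  s1 <- binary_metrics(pred$score_stage1 >= 0, truth1)
  r1 <- roc_curve(pred$score_stage1, factor(truth1, c(FALSE, TRUE),
                                            c("NC", "abnormal")), "abnormal")
  abn <- pred$truth %in% c("MCI", "AD")
  truth2 <- pred$truth[abn] == "AD"
  s2 <- binary_metrics(pred$score_stage2[abn] >= 0, truth2)
  r2 <- roc_curve(pred$score_stage2[abn], factor(truth2, c(FALSE, TRUE),
                                                 c("MCI", "AD")), "AD")
  stage <- function(m, r, label, positive, n) {
    c(m, list(roc_points = r$points, auc = r$auc, label = label,
              positive = positive, n = n))
  }
  structure(list(
    stage1 = stage(s1, r1, "NC vs abnormal", "abnormal", nrow(pred)),
    stage2 = stage(s2, r2, "AD vs MCI", "AD", sum(abn)),
    overall_accuracy = mean(pred$label == pred$truth),
    per_fold = per_fold, predictions = pred, meta = meta),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cross-validated evaluation\n")
  if (!is.null(x$meta$folds))
    cat(sprintf("  %d-fold, %d repeats (seed %s); features: %s/%s\n",
                x$meta$folds, x$meta$repeats, x$meta$seed,
                x$meta$feature_type, x$meta$encoding))
  for (nm in c("stage1", "stage2")) {
    st <- x[[nm]]
    cat(sprintf("  %-16s accuracy %.1f%%  sens %.1f%%  spec %.1f%%  AUC %.3f  (n=%d)\n",
                st$label, 100 * st$accuracy, 100 * st$sensitivity,
                100 * st$specificity, st$auc, st$n))
  }
  cat(sprintf("  overall three-class accuracy %.1f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "true positive rate", main = "cross-validated ROC", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::lines(x$stage1$roc_points, col = "firebrick", lwd = 2)
  graphics::lines(x$stage2$roc_points, col = "navy", lwd = 2)
  graphics::legend("bottomright", bty = "n", lwd = 2,
                   col = c("firebrick", "navy"),
                   legend = c(sprintf("%s (AUC %.3f)", x$stage1$label, x$stage1$auc),
                              sprintf("%s (AUC %.3f)", x$stage2$label, x$stage2$auc)))
  invisible(x)
}

#' Label-permutation null check
#'
#' Re-runs the cross-validated pipeline after randomly permuting the
#' diagnostic labels. With the class structure destroyed, any apparent
#' discrimination must come from information leakage, so the per-stage
#' balanced accuracy (mean of sensitivity and specificity) should fall at its
#' chance level of 1/2. Balanced accuracy is used because its null
#' expectation is exactly 1/2 for any classifier that is independent of the
#' labels, regardless of class imbalance (stage 1 is 1:2 imbalanced, where
#' raw accuracy would centre at the majority-class rate instead).
#'
#' @param cf a [cohort_features()] object.
#' @param folds,repeats,config forwarded to [cross_validate()].
#' @param n_perm number of independent label permutations.
#' @param seed seed controlling the permutations and the inner runs.
#' @return matrix with one row per permutation and columns `stage1`, `stage2`
#'   holding balanced accuracies.
#' @export
permutation_null <- function(cf, folds = 5, repeats = 1, n_perm = 3, seed = 1,
                             config = hier_svm_config()) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- vapply(seq_len(n_perm), function(i) {
    cfp <- cf
    cfp$labels <- sample(cf$labels)
    r <- cross_validate(cfp, folds = folds, repeats = repeats,
                        seed = sample.int(2^30, 1L), config = config)
    c(stage1 = (r$stage1$sensitivity + r$stage1$specificity) / 2,
      stage2 = (r$stage2$sensitivity + r$stage2$specificity) / 2)
  }, c(stage1 = 0, stage2 = 0))
  t(out)
}
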