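#' Hierarchical two-stage RBF-SVM classifier
#'
#' Fits the two-stage diagnostic cascade: stage 1 separates normal controls
#' (NC) from abnormal subjects (the union of AD and MCI); stage 2, trained
#' exclusively on the abnormal subjects, separates AD from MCI. Each stage is
#' a radial-basis-function support vector machine (libsvm via \pkg{e1071})
#' preceded by training-data z-scoring and Fisher-score feature selection;
#' the number of retained dimensions `k`, the cost `C` and the kernel width
#' `gamma` are chosen jointly by stratified inner cross-validation on the
#' training data only.
#'
#' @param x numeric feature matrix, one row per subject.
#' @param y diagnostic labels, values in `{"NC", "MCI", "AD"}`; all three must
#'   be present.
#' @param config list of tuning settings, see [hier_svm_config()].
#' @param seed integer seed for the inner cross-validation folds.
#' @return An object of class `hier_svm` with components `stage1`, `stage2`
#'   (each carrying the fitted SVM, selected dimensions and tuning choices)
#'   and the training `config`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 10), 60)
#' y <- rep(c("NC", "MCI", "AD"), each = 20)
#' x[y != "NC", 1] <- x[y != "NC", 1] + 4   # stage-1 signal
#' x[y == "AD", 2] <- x[y == "AD", 2] + 4   # stage-2 signal
#' fit <- hier_svm(x, y)
#' table(predict(fit, x)$label, y)
#' @export
hier_svm <- function(x, y, config = hier_svm_config(), seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (!all(y %in% c("NC", "MCI", "AD")))
    stop("labels must be NC, MCI or AD")
  if (!all(c("NC", "MCI", "AD") %in% y))
    stop("insufficient classes: need all of NC, MCI, AD in training data")
  if (any(table(y) < 5))
    warning("fewer than 5 subjects in some class; tuning will be unstable")
  y1 <- factor(ifelse(y == "NC", "NC", "abnormal"), levels = c("NC", "abnormal"))
  stage1 <- fit_stage(x, y1, config, seed)
  abn <- y != "NC"
  y2 <- factor(y[abn], levels = c("MCI", "AD"))
  stage2 <- fit_stage(x[abn, , drop = FALSE], y2, config, seed + 1L)
  structure(list(stage1 = stage1, stage2 = stage2, config = config,
                 classes = c("NC", "MCI", "AD"), call = match.call()),
            class = "hier_svm")
}

#' Tuning configuration for [hier_svm()]
#'
#' @param cost_grid SVM cost values searched.
#' @param gamma_factors RBF width factors; the kernel gamma is
#'   `factor / k` for `k` selected dimensions (so the grid adapts to the
#'   feature count).
#' @param k_grid Fisher-selection sizes searched; `Inf` means all dimensions.
#' @param inner_folds folds of the inner model-selection cross-validation.
#' @return a config list.
#' @export
hier_svm_config <- function(cost_grid = c(0.1, 1, 10, 100),
                            gamma_factors = c(0.1, 1, 10),
                            k_grid = c(16, 32, 64, 128, Inf),
                            inner_folds = 3) {
  list(cost_grid = cost_grid, gamma_factors = gamma_factors,
       k_grid = k_grid, inner_folds = inner_folds)
}

# fit one binary SVM stage with inner-CV choice of (k, C, gamma)
fit_stage <- function(X, y2, config, seed) {
  stopifnot(is.factor(y2), nlevels(y2) == 2L)
  keep <- which(colMeans(X^2) - colMeans(X)^2 > 0)
  if (length(keep) == 0L) stop("all features constant in training data")
  Xk <- X[, keep, drop = FALSE]
  ks <- unique(pmin(config$k_grid, ncol(Xk)))
  combos <- expand.grid(k = ks, cost = config$cost_grid,
                        gfac = config$gamma_factors)
  # with very small classes the inner search degrades gracefully: every
  # inner-training fold still needs >= 2 subjects per class for Fisher scores
  inner_folds <- min(config$inner_folds, floor(min(table(y2)) / 2))
  if (inner_folds < 2) {
    k <- min(64, ncol(Xk))
    ranking <- fisher_score(Xk, y2)
    combos <- data.frame(k = k, cost = 1, gfac = 1)
    acc <- 0
    config$inner_folds <- 0L
  } else config$inner_folds <- inner_folds
  folds <- if (config$inner_folds >= 2) stratified_folds(y2, config$inner_folds, seed)
  acc <- numeric(nrow(combos))
  for (f in seq_len(config$inner_folds)) {
    tr <- folds != f; te <- !tr
    mu_f <- colMeans(Xk[tr, , drop = FALSE])
    sd_f <- apply(Xk[tr, , drop = FALSE], 2L, stats::sd)
    sd_f[sd_f == 0] <- 1
    Ztr <- scale(Xk[tr, , drop = FALSE], mu_f, sd_f)
    Zte <- scale(Xk[te, , drop = FALSE], mu_f, sd_f)
    ranking <- fisher_score(Ztr, y2[tr])
    for (ci in seq_len(nrow(combos))) {
      k <- combos$k[ci]
      dims <- ranking$order[seq_len(k)]
      fit <- e1071::svm(Ztr[, dims, drop = FALSE], y2[tr], kernel = "radial",
                        cost = combos$cost[ci], gamma = combos$gfac[ci] / k,
                        scale = FALSE)
      pred <- predict(fit, Zte[, dims, drop = FALSE])
      acc[ci] <- acc[ci] + sum(pred == y2[te])
    }
  }
  best <- combos[which.max(acc), ]
  ranking <- fisher_score(Xk, y2)
  dims <- ranking$order[seq_len(best$k)]
  # explicit z-scoring (stored, training-derived) rather than svm's internal
  mu <- colMeans(Xk[, dims, drop = FALSE])
  sdv <- apply(Xk[, dims, drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- scale(Xk[, dims, drop = FALSE], mu, sdv)
  fit <- e1071::svm(Z, y2, kernel = "radial", cost = best$cost,
                    gamma = best$gfac / best$k, scale = FALSE)
  dv <- attr(predict(fit, Z, decision.values = TRUE), "decision.values")[, 1L]
  # orient decision values so higher = second (positive) level
  flip <- if (mean(dv[y2 == levels(y2)[2L]]) >= mean(dv[y2 == levels(y2)[1L]])) 1 else -1
  list(svm = fit, columns = keep[dims], center = mu, scale = sdv,
       flip = flip, k = best$k, cost = best$cost, gamma = best$gfac / best$k,
       levels = levels(y2), inner_accuracy = max(acc) / length(y2),
       fisher_scores = ranking$scores)
}

# oriented decision scores: positive means the stage's positive class
stage_scores <- function(stage, X) {
  Z <- scale(X[, stage$columns, drop = FALSE], stage$center, stage$scale)
  dv <- attr(predict(stage$svm, Z, decision.values = TRUE),
             "decision.values")[, 1L]
  stage$flip * dv
}

#' Predict diagnostic labels from a fitted hierarchical SVM
#'
#' Stage 1 is applied first; subjects on its NC side are labelled NC and
#' stage 2 is not consulted. The remainder receive stage 2's AD/MCI label.
#' A subject exactly on a stage boundary (decision value 0) is sent to the
#' abnormal (stage 1) / AD (stage 2) side, favouring sensitivity to disease.
#' Both stages' oriented decision values are returned for ROC analysis
#' (positive direction: abnormal for stage 1, AD for stage 2).
#'
#' @param object a fitted [hier_svm()].
#' @param newdata feature matrix with the same columns as the training data.
#' @param ... unused.
#' @return data.frame with `label`, `score_stage1`, `score_stage2`.
#' @export
predict.hier_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  s1 <- stage_scores(object$stage1, newdata)
  s2 <- stage_scores(object$stage2, newdata)
  label <- ifelse(s1 >= 0, ifelse(s2 >= 0, "AD", "MCI"), "NC")
  data.frame(label = label, score_stage1 = s1, score_stage2 = s2,
             stringsAsFactors = FALSE)
}

#' @export
print.hier_svm <- function(x, ...) {
  cat("Hierarchical two-stage RBF-SVM\n")
  for (nm in c("stage1", "stage2")) {
    st <- x[[nm]]
    cat(sprintf("  %s (%s vs %s): k = %d, C = %g, gamma = %.4g, %d SVs, inner-CV accuracy %.3f\n",
                nm, st$levels[1L], st$levels[2L], st$k, st$cost, st$gamma,
                nrow(st$svm$SV), st$inner_accuracy))
  }
  invisible(x)
}

#' @export
summary.hier_svm <- function(object, ...) {
  print(object)
  for (nm in c("stage1", "stage2")) {
    st <- object[[nm]]
    top <- order(st$fisher_scores, decreasing = TRUE)[1:5]
    cat(sprintf("  %s top Fisher dimensions: %s\n", nm,
                paste(sprintf("%d (%.3g)", top, st$fisher_scores[top]), collapse = ", ")))
  }
  invisible(object)
}

# stratified fold assignment; every class present in every fold
stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  y <- factor(y)
  if (any(table(y) < k))
    stop(sprintf("fold construction failed: a class has fewer than %d subjects; use fewer folds", k))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}
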