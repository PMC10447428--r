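make_synth <- function(n_per_class = 10, sep = 4, p = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c("NC", "MCI", "AD"), each = n_per_class)
  X <- matrix(rnorm(3 * n_per_class * p), ncol = p)
  X[y != "NC", 1] <- X[y != "NC", 1] + sep
  X[y == "AD", 2] <- X[y == "AD", 2] + sep
  list(X = X, y = y)
}

test_that("separable classes are learned perfectly and hierarchy short-circuits", {
  d <- make_synth(10, sep = 8)
  fit <- hier_svm(d$X, d$y, seed = 3)
  pr <- predict(fit, d$X)
  expect_equal(pr$label, d$y)
  # stage-1 NC-side subjects are NC regardless of their stage-2 score
  nc_rows <- which(pr$score_stage1 < 0)
  expect_true(all(pr$label[nc_rows] == "NC"))
  # abnormal side goes to stage 2: positive score means AD
  ab_rows <- which(pr$score_stage1 >= 0)
  expect_equal(pr$label[ab_rows], ifelse(pr$score_stage2[ab_rows] >= 0, "AD", "MCI"))
})

test_that("stage 2 is trained on abnormal subjects only", {
  d <- make_synth(8, sep = 6)
  fit <- hier_svm(d$X, d$y, seed = 2)
  n_abn <- sum(d$y != "NC")
  expect_lte(nrow(fit$stage2$svm$SV), n_abn)
  expect_identical(fit$stage2$levels, c("MCI", "AD"))
  expect_error(hier_svm(d$X[d$y != "AD", ], d$y[d$y != "AD"]),
               "insufficient classes")
})

test_that("duplicating every training subject leaves predictions unchanged", {
  d <- make_synth(8, sep = 6)
  fit1 <- hier_svm(d$X, d$y, seed = 4)
  fit2 <- hier_svm(rbind(d$X, d$X), c(d$y, d$y), seed = 4)
  p1 <- predict(fit1, d$X)$label
  p2 <- predict(fit2, d$X)$label
  # approximate invariance: duplication rescales effective C, so compare labels
  expect_gt(mean(p1 == p2), 0.95)
})

test_that("ROC follows the threshold sweep and trapezoid AUC", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("pos", "pos", "neg", "neg"), "pos")
  expect_equal(r$auc, 1.0)
  expect_equal(r$points[1, ], c(FPR = 0, TPR = 0))
  expect_equal(r$points[nrow(r$points), ], c(FPR = 1, TPR = 1))

  # constant scores: a single diagonal segment
  r2 <- roc_curve(rep(0.5, 10), rep(c("pos", "neg"), 5), "pos")
  expect_equal(r2$auc, 0.5)
  expect_equal(nrow(r2$points), 2)

  # hand-computable crossing case: (3 wins + 0 ties) / 4
  r3 <- roc_curve(c(0.8, 0.4, 0.6, 0.2), c("pos", "pos", "neg", "neg"), "pos")
  expect_equal(r3$auc, 0.75)

  expect_error(roc_curve(1:3, rep("pos", 3), "pos"), "both classes")
})

test_that("trapezoidal AUC equals the pairwise-win count on random scores", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    truth <- sample(c("a", "b"), n, replace = TRUE)
    while (length(unique(truth)) < 2) truth <- sample(c("a", "b"), n, replace = TRUE)
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    r <- roc_curve(scores, truth, "b")
    expect_equal(r$auc, pairwise_auc(scores, truth, "b"), tolerance = 1e-9)
    # monotone points
    expect_true(all(diff(r$points[, 1]) >= 0))
    expect_true(all(diff(r$points[, 2]) >= 0))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(40)
  truth <- sample(c("ctl", "case"), 40, replace = TRUE)
  r <- roc_curve(scores, truth, "case")
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores, levels = c("ctl", "case"),
                                              direction = "<")))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("separable data trains to 100% and cross-validation is deterministic", {
  d <- make_synth(10, sep = 8)
  fit <- hier_svm(d$X, d$y, seed = 5)
  expect_equal(mean(predict(fit, d$X)$label == d$y), 1.0)  # training accuracy

  r1 <- cross_validate(d$X, d$y, folds = 5, repeats = 2, seed = 77)
  r2 <- cross_validate(d$X, d$y, folds = 5, repeats = 2, seed = 77)
  expect_identical(r1, r2)
  expect_gte(r1$overall_accuracy, 0.9)
  expect_equal(r1$stage1$accuracy, 1.0)
  expect_equal(r1$stage1$auc, 1.0)
})

test_that("report invariants hold: confusion identities and trapezoid AUC", {
  d <- make_synth(8, sep = 1.5, seed = 6)  # imperfect separation
  r <- cross_validate(d$X, d$y, folds = 4, repeats = 2, seed = 5)
  for (st in list(r$stage1, r$stage2)) {
    cm <- st$confusion
    expect_equal(st$accuracy, (cm["TP"] + cm["TN"]) / sum(cm), ignore_attr = TRUE)
    expect_equal(st$sensitivity, cm["TP"] / (cm["TP"] + cm["FN"]), ignore_attr = TRUE)
    expect_equal(st$specificity, cm["TN"] / (cm["TN"] + cm["FP"]), ignore_attr = TRUE)
    pts <- st$roc_points
    expect_equal(st$auc, sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2),
                 tolerance = 1e-9)
  }
  # hierarchy error composition: overall errors >= stage-1 errors
  expect_lte(r$overall_accuracy, r$stage1$accuracy)
})

test_that("fold construction fails clearly when a class is too small", {
  d <- make_synth(3, sep = 5)
  expect_error(cross_validate(d$X, d$y, folds = 5, repeats = 1, seed = 1),
               "fewer than 5 subjects; use fewer folds")
})

test_that("no test-fold information reaches a fitted component (leakage canary)", {
  set.seed(31)
  n <- 60
  y <- rep(c("NC", "MCI", "AD"), each = n / 3)
  X <- matrix(rnorm(n * 10), n)
  # canary A: a feature equal to the label is learned almost perfectly
  Xa <- cbind(X, as.numeric(factor(y)))
  ra <- cross_validate(Xa, y, folds = 5, repeats = 1, seed = 8)
  expect_gt(ra$overall_accuracy, 0.9)
  # canary B: pure noise features cannot beat chance by much; if any fitted
  # component saw the test fold this would be near 100%
  rb <- cross_validate(X, y, folds = 5, repeats = 1, seed = 8)
  expect_lt(rb$overall_accuracy, 0.66)
})
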