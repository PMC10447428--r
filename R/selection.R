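#' Fisher-score feature ranking
#'
#' Ranks descriptor dimensions by the ratio of between-class to within-class
#' scatter,
#' \deqn{F_j = \frac{\sum_c n_c (\mu_{c,j} - \mu_j)^2}{\sum_c n_c \sigma^2_{c,j}},}
#' with population (n_c-denominator) class variances. In the two-class case
#' this reduces to the familiar \eqn{(\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2)}
#' up to class-size weighting. Dimensions with zero within-class variance and
#' zero between-class spread score 0; zero within-class variance with nonzero
#' spread scores `Inf` and ranks first. Ties are broken by ascending dimension
#' index. Scores are invariant to per-dimension affine rescaling.
#'
#' @param X numeric matrix, subjects in rows, feature dimensions in columns.
#' @param y class labels (any vector coercible to factor), >= 2 classes with
#'   >= 2 subjects each.
#' @return An object of class `fisher_ranking`: list with `scores` (one per
#'   dimension), `order` (dimensions by descending score) and `k` (`NA` until
#'   a cut is chosen).
#' @export
fisher_score <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("degenerate labels: need >= 2 classes")
  if (any(table(y) < 2)) stop("each class needs >= 2 subjects")
  mu <- colMeans(X)
  between <- numeric(ncol(X))
  within <- numeric(ncol(X))
  for (cl in levels(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    nc <- nrow(Xc)
    muc <- colMeans(Xc)
    between <- between + nc * (muc - mu)^2
    within <- within + nc * (colMeans(Xc^2) - muc^2)
  }
  scores <- ifelse(within > 0, between / within,
                   ifelse(between > 0, Inf, 0))
  structure(list(scores = scores,
                 order = order(scores, decreasing = TRUE),
                 k = NA_integer_),
            class = "fisher_ranking")
}

#' @export
print.fisher_ranking <- function(x, ...) {
  cat(sprintf("fisher_ranking: %d dimensions", length(x$scores)))
  if (!is.na(x$k)) cat(sprintf(", top %d retained", x$k))
  cat("\n  top scores:", paste(signif(x$scores[x$order[seq_len(min(5, length(x$scores)))]], 4),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Retain the top-k ranked dimensions
#'
#' Columns are reordered by descending Fisher score and truncated to `k`.
#' Fit the ranking on training subjects only and apply the same column choice
#' to test subjects (no leakage).
#'
#' @param ranking a [fisher_score()] result.
#' @param k number of dimensions to keep (1..n_features).
#' @param X matrix whose columns are reduced.
#' @return the reduced matrix with attribute `"dims"` recording the columns.
#' @export
select_top <- function(ranking, k, X) {
  X <- as.matrix(X)
  if (k < 1 || k > length(ranking$scores)) stop("k out of range")
  dims <- ranking$order[seq_len(k)]
  out <- X[, dims, drop = FALSE]
  attr(out, "dims") <- dims
  out
}

#' Dump a ranking to CSV for inspection
#' @param ranking a [fisher_score()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(data.frame(dimension = ranking$order,
                              score = ranking$scores[ranking$order],
                              rank = seq_along(ranking$order)),
                   path, row.names = FALSE)
  invisible(path)
}
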