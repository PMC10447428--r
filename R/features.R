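#' Fixed-length shape descriptors from a curvature field
#'
#' Meshes have different vertex counts from subject to subject, so per-vertex
#' curvatures cannot be compared directly. The descriptor summarises the
#' distribution of a curvature quantity over the surface into a fixed-length
#' vector:
#'
#' * `"histogram"` (default): area-weighted normalised histogram over a fixed
#'   value range, invariant to sampling density;
#' * `"quantile"`: empirical quantiles at `length` evenly spaced probabilities
#'   (keeps curvature magnitudes, in mm^-1 / mm^-2, that histograms discard).
#'
#' Feature types: `"gaussian_curvature"` (K), `"mean_curvature"` (H), and
#' `"shape_operator"` which encodes the per-vertex eigenvalue pair as two
#' concatenated halves (kappa1 then kappa2, total length `2 * length`).
#' Values are winsorised at their 1st/99th percentiles before encoding —
#' isosurface staircase residue creates heavy tails — and clipped into the
#' histogram range, so histogram entries always sum to one.
#'
#' @param field a [curvature_field()].
#' @param feature_type `"shape_operator"`, `"gaussian_curvature"` or
#'   `"mean_curvature"`.
#' @param encoding `"histogram"` or `"quantile"`.
#' @param length bins (histogram) or number of quantiles per value channel.
#' @param ranges optional list of `c(lo, hi)` per channel (named `kappa1`,
#'   `kappa2`, or the feature type). In a training/test split, compute ranges
#'   on the training cohort with [descriptor_ranges()] and reuse them; by
#'   default the field's own winsorised range is used.
#' @param subject_id,region_tag metadata carried on the result.
#' @return An object of class `feature_vector`.
#' @export
build_descriptor <- function(field,
                             feature_type = c("shape_operator", "gaussian_curvature", "mean_curvature"),
                             encoding = c("histogram", "quantile"),
                             length = 64, ranges = NULL,
                             subject_id = "unknown", region_tag = "hippocampus") {
  feature_type <- match.arg(feature_type)
  encoding <- match.arg(encoding)
  if (encoding == "histogram" && length < 8)
    stop("histogram descriptor length must be >= 8")
  if (encoding == "quantile" && length < 2)
    stop("quantile descriptor length must be >= 2")
  ch <- field_channels(field, feature_type)
  if (any(vapply(ch, function(x) length(x$values) == 0L, TRUE)))
    stop("empty curvature field: no successfully fitted vertices")
  vals <- lapply(names(ch), function(nm) {
    w <- ch[[nm]]$weights
    if (encoding == "histogram") {
      v <- winsorize(ch[[nm]]$values)
      rg <- if (!is.null(ranges)) ranges[[nm]] else range(v)
      weighted_histogram(v, w, rg, length) / length(ch)
    } else {
      # quantiles are rank-based, hence already tail-robust; no winsorisation
      stats::quantile(ch[[nm]]$values, probs = seq(0, 1, length.out = length),
                      names = FALSE)
    }
  })
  structure(list(subject_id = subject_id, region_tag = region_tag,
                 feature_type = feature_type, encoding = encoding,
                 length = length, values = unlist(vals, use.names = FALSE)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector [%s / %s]: %s encoding of %s, %d dimensions\n",
              x$subject_id, x$region_tag, x$encoding, x$feature_type,
              length(x$values)))
  invisible(x)
}

# per-channel value/weight samples of a curvature field
field_channels <- function(field, feature_type) {
  okv <- field$ok
  w <- field$vertex_area[okv]
  switch(feature_type,
         shape_operator = list(kappa1 = list(values = field$kappa1[okv], weights = w),
                               kappa2 = list(values = field$kappa2[okv], weights = w)),
         gaussian_curvature = list(gaussian_curvature = list(values = field$K[okv], weights = w)),
         mean_curvature = list(mean_curvature = list(values = field$H[okv], weights = w)))
}

winsorize <- function(v, probs = c(0.01, 0.99)) {
  q <- stats::quantile(v, probs, names = FALSE)
  pmin(pmax(v, q[1L]), q[2L])
}

weighted_histogram <- function(v, w, rg, bins) {
  if (rg[2L] <= rg[1L]) rg <- rg + c(-0.5, 0.5)  # degenerate constant field
  v <- pmin(pmax(v, rg[1L]), rg[2L])
  b <- pmin(bins, pmax(1L, ceiling((v - rg[1L]) / (rg[2L] - rg[1L]) * bins)))
  b[v == rg[1L]] <- 1L
  h <- numeric(bins)
  acc <- rowsum(w, b)
  h[as.integer(rownames(acc))] <- acc[, 1L]
  h / sum(h)
}

#' Pooled descriptor ranges from a training cohort
#'
#' Computes, per value channel, the pooled 1st-99th percentile range over a
#' list of curvature fields. Freeze the result into the model and reuse it
#' for test subjects so no test information leaks into the encoding.
#'
#' @param fields list of [curvature_field()] objects (training subjects).
#' @param feature_type as in [build_descriptor()].
#' @return named list of `c(lo, hi)` per channel.
#' @export
descriptor_ranges <- function(fields, feature_type) {
  chs <- lapply(fields, field_channels, feature_type = feature_type)
  nms <- names(chs[[1L]])
  out <- lapply(nms, function(nm) {
    pooled <- unlist(lapply(chs, function(x) x[[nm]]$values), use.names = FALSE)
    stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
  })
  names(out) <- nms
  out
}

#' Feature-level fusion of two descriptors
#'
#' Concatenates per-region descriptors of the same subject and feature type
#' (hippocampus before amygdala by convention) — the feature-level fusion
#' alternative to fusing the region masks before extraction.
#'
#' @param a,b [feature_vector] objects for the same subject, feature type and
#'   encoding.
#' @return a [feature_vector] with `region_tag = "feature_fusion"`.
#' @export
fuse_features <- function(a, b) {
  if (!identical(a$subject_id, b$subject_id))
    stop(sprintf("pairing error: subjects '%s' and '%s' differ", a$subject_id, b$subject_id))
  if (!identical(a$feature_type, b$feature_type) || !identical(a$encoding, b$encoding))
    stop("feature vectors must share feature type and encoding")
  structure(list(subject_id = a$subject_id, region_tag = "feature_fusion",
                 feature_type = a$feature_type, encoding = a$encoding,
                 length = a$length, values = c(a$values, b$values)),
            class = "feature_vector")
}
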