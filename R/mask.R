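#' Binary ROI masks
#'
#' A `voxel_mask` holds a segmented region of interest as a binary 3D occupancy
#' grid plus the 4x4 voxel-to-world affine (mm) carried by its NIfTI header.
#' Per-axis voxel spacing is derived from the affine column norms, so
#' anisotropic acquisitions are handled and all downstream geometry is in mm.
#'
#' @param grid 3D array of 0/1 occupancy.
#' @param affine 4x4 voxel-to-world transform (mm); voxel indices are 0-based
#'   in the NIfTI convention.
#' @param subject_id opaque subject identifier.
#' @param region_tag one of `"hippocampus"`, `"amygdala"`, `"fused"`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, affine = diag(4), subject_id = "unknown",
                       region_tag = "hippocampus") {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (!all(grid %in% c(0, 1))) stop("grid must be binary (0/1)")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing derived from affine must be positive and finite")
  structure(list(grid = grid, affine = affine, spacing = spacing,
                 subject_id = subject_id, region_tag = region_tag),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask [%s / %s]: %s grid, %d foreground voxels\n",
              x$subject_id, x$region_tag, paste(dim(x$grid), collapse = "x"),
              sum(x$grid)))
  cat(sprintf("  spacing: %s mm, volume: %.1f mm^3\n",
              paste(signif(x$spacing, 4), collapse = " x "), mask_volume(x)))
  invisible(x)
}

#' Read a binary ROI mask from a NIfTI volume
#'
#' Values are binarised as `value >= threshold`; probabilistic maps therefore
#' work with the default mid-level cut of 0.5, and integer label maps can be
#' reduced to one structure first with `label`.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param threshold binarisation cut in (0, 1]; applied after label selection.
#' @param label optional integer: keep only voxels equal to this label before
#'   binarisation (for multi-structure label maps).
#' @param keep_largest if `TRUE`, restrict to the largest 6-connected
#'   foreground component (drops segmentation specks that corrupt curvature
#'   statistics). By default all components are kept and a warning reports
#'   their count when there is more than one.
#' @param subject_id,region_tag metadata attached to the mask.
#' @return a [voxel_mask()].
#' @export
read_mask <- function(path, threshold = 0.5, label = NULL, keep_largest = FALSE,
                      subject_id = "unknown", region_tag = "hippocampus") {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot parse '%s' as NIfTI: %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (!is.null(label)) arr <- (arr == label) * 1
  grid <- (arr >= threshold) * 1
  if (sum(grid) == 0)
    stop(sprintf("empty mask: no foreground voxels for subject '%s', region '%s' (%s)",
                 subject_id, region_tag, path))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  m <- voxel_mask(grid, affine, subject_id, region_tag)
  comp <- label_components(m$grid)
  if (comp$n > 1L) {
    if (keep_largest) {
      m$grid <- (comp$labels == which.max(comp$sizes)) * 1
    } else {
      warning(sprintf("mask %s/%s has %d connected components (kept all)",
                      subject_id, region_tag, comp$n))
    }
  }
  m
}

#' Write a mask back to NIfTI
#' @param mask a [voxel_mask()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$grid)
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 6-connected component labelling of a binary grid (frontier BFS)
label_components <- function(grid) {
  d <- dim(grid)
  fg <- which(grid == 1)
  labels <- array(0L, d)
  if (length(fg) == 0L) return(list(labels = labels, n = 0L, sizes = integer()))
  offs <- c(-1L, 1L, -d[1L], d[1L], -d[1L] * d[2L], d[1L] * d[2L])
  # guard against wrap-around across x/y faces by padding instead
  pd <- d + 2L
  pg <- array(0, pd)
  pg[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- grid
  plab <- array(0L, pd)
  poffs <- c(-1L, 1L, -pd[1L], pd[1L], -pd[1L] * pd[2L], pd[1L] * pd[2L])
  pfg <- which(pg == 1)
  n <- 0L
  sizes <- integer()
  remaining <- pfg
  inqueue <- array(FALSE, pd)
  for (seed in pfg) {
    if (plab[seed] != 0L) next
    n <- n + 1L
    frontier <- seed
    plab[seed] <- n
    sz <- 1L
    while (length(frontier) > 0L) {
      nb <- unique(as.vector(outer(frontier, poffs, "+")))
      nb <- nb[pg[nb] == 1 & plab[nb] == 0L]
      plab[nb] <- n
      sz <- sz + length(nb)
      frontier <- nb
    }
    sizes <- c(sizes, sz)
  }
  labels <- plab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  list(labels = labels, n = n, sizes = sizes)
}

#' Fuse two ROI masks into one region
#'
#' Voxelwise addition followed by re-binarisation, i.e. the set union — the
#' region-level fusion that merges hippocampus and amygdala into a single
#' "hippo-amygdala" ROI before surface extraction. Both masks must live in the
#' same voxel grid and space.
#'
#' @param a,b [voxel_mask()] objects sharing grid shape and affine
#'   (affine entries compared at tolerance 1e-4).
#' @return a [voxel_mask()] with `region_tag = "fused"`.
#' @export
fuse_regions <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("grid mismatch: masks must share grid shape (same registered space)")
  if (max(abs(a$affine - b$affine)) > 1e-4)
    stop("grid mismatch: masks must share the voxel-to-world affine")
  g <- ((a$grid + b$grid) >= 1) * 1
  voxel_mask(g, a$affine, a$subject_id, "fused")
}

#' Foreground volume of a mask in mm^3
#'
#' Foreground voxel count times the voxel volume (product of spacings) — the
#' volumetry baseline feature.
#' @param m a [voxel_mask()].
#' @return scalar volume in mm^3.
#' @export
mask_volume <- function(m) {
  sum(m$grid) * prod(m$spacing)
}
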