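#' Synthetic phantom specification
#'
#' Describes one voxelised genus-0 shape with class-dependent local curvature
#' structure: an ellipsoid carrying a smooth spherical-cap indentation whose
#' depth grows with disease class (the localised "atrophy" of the diseased
#' classes), a mild global atrophy scale, log-normal per-subject scale jitter,
#' and smooth low-amplitude radial noise lobes. The indentation is a C-infinity
#' bump (Gaussian in angular distance), so curvature stays well defined at the
#' rim; a hard boolean cut would create curvature singularities.
#'
#' Class defaults for NC / MCI / AD: indentation depth 0 / 2.8 / 5.6 mm,
#' angular width 0.5 / 0.5 / 0.8 rad (progressive atrophy is both deeper and
#' more extended), and global atrophy scale 1 / 0.985 / 0.97. The indentation
#' sits at a consistent body-frame site (with small angular jitter), the way
#' subfield atrophy affects a consistent anatomical location, while the whole
#' shape is randomly rotated per subject. The scale jitter (sd 0.04 on the
#' log scale) makes volume alone a moderate but clearly imperfect classifier,
#' so shape descriptors can demonstrably beat volumetry.
#'
#' @param class_label one of `"NC"`, `"MCI"`, `"AD"`.
#' @param semi_axes ellipsoid semi-axes (mm) before jitter.
#' @param indent_depth indentation depth (mm); `NULL` picks the class default.
#' @param indent_width angular half-width of the indentation (rad); `NULL`
#'   picks the class default.
#' @param atrophy_scale global scale factor; `NULL` picks the class default.
#' @param scale_jitter_sd sd of the per-subject log-normal scale jitter.
#' @param noise_sd amplitude sd (mm) of the smooth radial noise lobes.
#' @param n_noise_lobes number of random noise lobes.
#' @param spacing voxel edge lengths (mm), length 3.
#' @param seed integer seed; phantoms are deterministic per seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("NC", "MCI", "AD"),
                         semi_axes = c(14, 9, 7),
                         indent_depth = NULL,
                         indent_width = NULL,
                         atrophy_scale = NULL,
                         scale_jitter_sd = 0.04,
                         noise_sd = 0.12,
                         n_noise_lobes = 4,
                         spacing = c(1, 1, 1),
                         seed = 1) {
  class_label <- match.arg(class_label)
  if (is.null(indent_depth))
    indent_depth <- c(NC = 0, MCI = 2.8, AD = 5.6)[[class_label]]
  if (is.null(indent_width))
    indent_width <- c(NC = 0.5, MCI = 0.5, AD = 0.8)[[class_label]]
  if (is.null(atrophy_scale))
    atrophy_scale <- c(NC = 1, MCI = 0.985, AD = 0.97)[[class_label]]
  if (any(semi_axes <= 2 * max(spacing)))
    stop("semi-axes must exceed twice the voxel spacing (unresolvable shape)")
  if (indent_depth >= min(semi_axes))
    stop("indentation depth must be smaller than the smallest semi-axis")
  structure(list(class_label = class_label, semi_axes = semi_axes,
                 indent_depth = indent_depth, indent_width = indent_width,
                 atrophy_scale = atrophy_scale,
                 scale_jitter_sd = scale_jitter_sd, noise_sd = noise_sd,
                 n_noise_lobes = n_noise_lobes, spacing = spacing, seed = seed),
            class = "phantom_spec")
}

# draw the random shape parameters of one phantom (uses the current RNG)
draw_shape <- function(spec) {
  rot <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
  # indentation sits at a consistent anatomical site (mid-axis pole) with
  # small angular jitter; world orientation is still fully randomised by rot
  u0 <- c(0, 1, 0) + stats::rnorm(3, 0, 0.15)
  u0 <- u0 / sqrt(sum(u0^2))
  nl <- spec$n_noise_lobes
  lob_u <- matrix(stats::rnorm(3 * nl), nl, 3)
  lob_u <- lob_u / sqrt(rowSums(lob_u^2))
  list(axes = spec$semi_axes * spec$atrophy_scale *
         exp(stats::rnorm(1, 0, spec$scale_jitter_sd)),
       rot = rot, u0 = u0,
       lob_u = lob_u,
       lob_a = stats::rnorm(nl, 0, spec$noise_sd),
       lob_w = stats::runif(nl, 0.5, 0.9))
}

# occupancy of a drawn shape at world points P (n x 3, mm, relative to centre)
shape_inside <- function(P, shape, spec) {
  Q <- P %*% shape$rot  # body frame
  r <- sqrt(rowSums(Q * Q))
  rho <- sqrt(rowSums(sweep(Q, 2L, shape$axes, "/")^2))
  inside <- rho <= 1  # provisional; refined below for r > 0
  nz <- r > 1e-9
  U <- Q[nz, , drop = FALSE] / r[nz]
  R0 <- r[nz] / pmax(rho[nz], 1e-12)  # ellipsoid radius along each direction
  ang <- acos(pmin(1, pmax(-1, U %*% shape$u0)))
  deform <- -spec$indent_depth * exp(-(ang / spec$indent_width)^2)
  for (k in seq_len(spec$n_noise_lobes)) {
    ak <- acos(pmin(1, pmax(-1, U %*% shape$lob_u[k, ])))
    deform <- deform + shape$lob_a[k] * exp(-(ak / shape$lob_w[k])^2)
  }
  inside[nz] <- r[nz] <= R0 + deform
  inside
}

#' Rasterise one phantom to a binary mask
#'
#' Deterministic per seed: the same spec yields a bit-identical grid.
#'
#' @param spec a [phantom_spec()].
#' @param center world-space centre of the shape (mm).
#' @param subject_id,region_tag metadata for the resulting mask.
#' @return a [voxel_mask()] on a grid that encloses the shape with margin.
#' @export
make_phantom <- function(spec, center = c(0, 0, 0), subject_id = "phantom",
                         region_tag = "hippocampus") {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  shape <- draw_shape(spec)
  margin <- 3 * max(spec$spacing) + max(abs(shape$lob_a)) + 1
  half <- max(shape$axes) + margin
  ax <- lapply(1:3, function(j) {
    n <- ceiling(half / spec$spacing[j])
    (-n:n) * spec$spacing[j]
  })
  d <- vapply(ax, length, 1L)
  P <- cbind(rep(ax[[1L]], times = d[2L] * d[3L]),
             rep(rep(ax[[2L]], each = d[1L]), times = d[3L]),
             rep(ax[[3L]], each = d[1L] * d[2L]))
  g <- array(shape_inside(P, shape, spec) * 1, d)
  if (sum(g) == 0) stop("unresolvable phantom spec: empty rasterisation")
  aff <- diag(c(spec$spacing, 1))
  aff[1:3, 4L] <- center + c(ax[[1L]][1L], ax[[2L]][1L], ax[[3L]][1L])
  voxel_mask(g, aff, subject_id, region_tag)
}

#' Generate a synthetic two-region cohort
#'
#' Writes one hippocampus-like and one smaller amygdala-like phantom per
#' subject into a shared voxel grid (so the two region masks are in the same
#' space and can be fused), plus a cohort manifest CSV with columns
#' `subject_id`, `label`, `path_hippocampus`, `path_amygdala`. The amygdala
#' phantom carries 60 percent of the class indentation depth, mirroring the
#' weaker disease signal reported for that structure.
#'
#' @param n_per_class subjects per diagnostic class (NC, MCI, AD).
#' @param dir output directory for NIfTI files and `manifest.csv`.
#' @param seed cohort seed; everything downstream is reproducible from it.
#' @param hippo_axes,amyg_axes semi-axes (mm) of the two phantom regions.
#' @param amyg_offset world offset (mm) of the amygdala centre.
#' @param ... further arguments passed to [phantom_spec()] (e.g. `noise_sd`).
#' @return the manifest as a data.frame, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
make_cohort <- function(n_per_class = 20, dir = tempfile("cohort"), seed = 1,
                        hippo_axes = c(14, 9, 7), amyg_axes = c(9, 7, 6),
                        amyg_offset = c(0, 28, 10), ...) {
  if (n_per_class < 2) stop("n_per_class must be >= 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  classes <- c("NC", "MCI", "AD")
  rows <- list()
  idx <- 0L
  for (cl in classes) for (i in seq_len(n_per_class)) {
    idx <- idx + 1L
    sid <- sprintf("sub-%03d", idx)
    sub_seed <- (seed * 7919L + idx * 131L) %% 2147483647L
    spec_h <- phantom_spec(cl, semi_axes = hippo_axes, seed = sub_seed, ...)
    spec_a <- phantom_spec(cl, semi_axes = amyg_axes, seed = sub_seed + 1L,
                           indent_depth = 0.6 * spec_h$indent_depth, ...)
    mh <- make_phantom(spec_h, subject_id = sid, region_tag = "hippocampus")
    ma <- make_phantom(spec_a, center = amyg_offset, subject_id = sid,
                       region_tag = "amygdala")
    joint <- joint_grid(mh, ma)
    ph <- file.path(dir, sprintf("%s_hippocampus.nii.gz", sid))
    pa <- file.path(dir, sprintf("%s_amygdala.nii.gz", sid))
    write_mask(joint$a, ph)
    write_mask(joint$b, pa)
    rows[[idx]] <- data.frame(subject_id = sid, label = cl,
                              path_hippocampus = ph, path_amygdala = pa,
                              stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# re-embed two masks (diagonal affines, same spacing) into one shared grid
joint_grid <- function(a, b) {
  sp <- a$spacing
  if (max(abs(sp - b$spacing)) > 1e-9) stop("regions must share voxel spacing")
  lo <- pmin(a$affine[1:3, 4L], b$affine[1:3, 4L])
  hi <- pmax(a$affine[1:3, 4L] + (dim(a$grid) - 1L) * sp,
             b$affine[1:3, 4L] + (dim(b$grid) - 1L) * sp)
  d <- as.integer(round((hi - lo) / sp)) + 1L
  aff <- diag(c(sp, 1)); aff[1:3, 4L] <- lo
  embed <- function(m) {
    g <- array(0, d)
    o <- as.integer(round((m$affine[1:3, 4L] - lo) / sp))
    dm <- dim(m$grid)
    g[o[1L] + seq_len(dm[1L]), o[2L] + seq_len(dm[2L]), o[3L] + seq_len(dm[3L])] <- m$grid
    voxel_mask(g, aff, m$subject_id, m$region_tag)
  }
  list(a = embed(a), b = embed(b))
}
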