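# shared fixtures and independent oracles for the test suite ------------------

# voxelised solids on unit-spacing grids
vox_sphere_mask <- function(r, spacing = 1, id = "sph") {
  n <- ceiling(r / spacing) + 2
  ax <- (-n:n) * spacing
  g <- (outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r^2) * 1
  aff <- diag(c(spacing, spacing, spacing, 1)); aff[1:3, 4] <- -n * spacing
  voxel_mask(g, aff, id, "hippocampus")
}

vox_ellipsoid_mask <- function(abc, spacing = 1, id = "ell") {
  n <- ceiling(max(abc) / spacing) + 2
  ax <- (-n:n) * spacing
  g <- (outer(outer((ax / abc[1])^2, (ax / abc[2])^2, "+"), (ax / abc[3])^2, "+") <= 1) * 1
  aff <- diag(c(spacing, spacing, spacing, 1)); aff[1:3, 4] <- -n * spacing
  voxel_mask(g, aff, id, "hippocampus")
}

vox_torus_mask <- function(R = 12, r = 5, id = "tor") {
  n <- R + r + 3
  ax <- -n:n
  g <- array(0, c(length(ax), length(ax), length(ax)))
  for (k in seq_along(ax)) {
    rad <- sqrt(outer(ax^2, ax^2, "+"))
    g[, , k] <- ((rad - R)^2 + ax[k]^2 <= r^2) * 1
  }
  aff <- diag(4); aff[1:3, 4] <- -n
  voxel_mask(g, aff, id, "hippocampus")
}

vox_capped_cylinder_mask <- function(r = 10, half_h = 15, id = "cyl") {
  n <- r + 4; nz <- half_h + 4
  ax <- -n:n; az <- -nz:nz
  g <- array(0, c(length(ax), length(ax), length(az)))
  disc <- (outer(ax^2, ax^2, "+") <= r^2) * 1
  for (k in seq_along(az)) g[, , k] <- disc * (abs(az[k]) <= half_h)
  aff <- diag(4); aff[1:3, 4] <- c(-n, -n, -nz)
  voxel_mask(g, aff, id, "hippocampus")
}

# memoised heavy fixtures (computed once per test run)
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

smoothed_sphere_field <- function(r = 20) {
  fixture(paste0("sph", r), {
    mesh <- smooth_mesh(extract_surface(vox_sphere_mask(r)), 20)
    list(mesh = mesh, field = curvature_field(mesh))
  })
}

# independent oracle: angle-deficit (discrete Gauss-Bonnet) Gaussian curvature
angle_deficit_K <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  deficit <- rep(2 * pi, nv)
  area <- numeric(nv)
  for (j in 1:3) {
    a <- v[f[, j], , drop = FALSE]
    b <- v[f[, j %% 3 + 1], , drop = FALSE]
    c_ <- v[f[, (j + 1) %% 3 + 1], , drop = FALSE]
    u <- b - a; w <- c_ - a
    du <- sqrt(rowSums(u^2)); dw <- sqrt(rowSums(w^2))
    ang <- acos(pmin(1, pmax(-1, rowSums(u * w) / (du * dw))))
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    ar <- 0.5 * sqrt(rowSums(cr^2))
    acc <- rowsum(cbind(ang, ar / 3), f[, j])
    idx <- as.integer(rownames(acc))
    deficit[idx] <- deficit[idx] - acc[, 1]
    area[idx] <- area[idx] + acc[, 2]
  }
  deficit / area
}

# independent oracle: Fisher score by direct arithmetic
brute_fisher <- function(X, y) {
  y <- factor(y)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    mu <- mean(x)
    num <- 0; den <- 0
    for (cl in levels(y)) {
      xc <- x[y == cl]
      num <- num + length(xc) * (mean(xc) - mu)^2
      den <- den + length(xc) * mean((xc - mean(xc))^2)
    }
    if (den > 0) num / den else if (num > 0) Inf else 0
  }, 1)
}

# independent oracle: AUC as normalised pairwise-win count
pairwise_auc <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# shared small phantom cohort for pipeline-level tests
small_cohort <- function() {
  fixture("small_cohort", {
    dir <- file.path(tempdir(), "gausscurv-small-cohort")
    make_cohort(n_per_class = 3, dir = dir, seed = 202)
  })
}

# default phantom cohort and pipeline runs shared by the acceptance checks
acc_manifest <- function() {
  fixture("acc_manifest", {
    dir <- file.path(tempdir(), "gausscurv-acc-cohort")
    make_cohort(n_per_class = 20, dir = dir, seed = 1)
  })
}

acc_shape_run <- function() {
  fixture("acc_shape_run", run_pipeline(
    acc_manifest(), out_dir = NULL, mode = "region_fusion",
    feature_type = "shape_operator", folds = 5, repeats = 5, seed = 1,
    verbose = FALSE))
}

acc_volume_run <- function() {
  fixture("acc_volume_run", run_pipeline(
    acc_manifest(), out_dir = NULL, mode = "volume_baseline",
    folds = 5, repeats = 5, seed = 1, verbose = FALSE))
}
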