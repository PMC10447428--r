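test_that("a constant field concentrates the histogram in one bin", {
  s <- mesh_icosphere(1, 3)
  cf <- curvature_field(s, ring = 2)
  cf$K[] <- 0.25  # degenerate distribution
  fv <- build_descriptor(cf, "gaussian_curvature", "histogram", 16,
                         ranges = list(gaussian_curvature = c(0, 1)))
  expect_equal(sum(fv$values > 0), 1)
  expect_equal(max(fv$values), 1)
  expect_equal(sum(fv$values), 1, tolerance = 1e-9)
})

test_that("quantile encoding matches linear-interpolation quantiles", {
  s <- mesh_icosphere(1, 3)
  cf <- curvature_field(s, ring = 2)
  cf$K <- c(1:100, rep(50, cf$n - 100))
  cf$ok <- c(rep(TRUE, 100), rep(FALSE, cf$n - 100))
  fv <- build_descriptor(cf, "gaussian_curvature", "quantile", 5)
  expect_equal(fv$values, c(1, 25.75, 50.5, 75.25, 100))
})

test_that("histogram descriptors are invariant to mesh sampling density", {
  # same ellipsoid triangulated at two very different vertex counts
  ell <- function(subdiv) {
    s <- mesh_icosphere(1, subdiv)
    triangle_mesh(sweep(s$vertices, 2, c(1.6, 1.1, 0.8), "*"), s$faces)
  }
  # the fitting ring is chosen so both meshes use the same metric (geodesic)
  # support, as in the voxel pipeline where edge length is set by the grid
  f3 <- curvature_field(ell(4), ring = 2)
  f4 <- curvature_field(ell(5), ring = 4)
  # shared frozen range, as in the real pipeline
  rg <- descriptor_ranges(list(f3, f4), "shape_operator")
  d3 <- build_descriptor(f3, "shape_operator", "histogram", 16, rg)
  d4 <- build_descriptor(f4, "shape_operator", "histogram", 16, rg)
  expect_equal(length(d3$values), 32)  # two concatenated halves
  expect_lt(sum(abs(d3$values - d4$values)), 0.05)
})

test_that("descriptors are invariant to rigid motion of the mesh", {
  base <- smooth_mesh(extract_surface(vox_ellipsoid_mask(c(12, 9, 7))), 20)
  moved <- transform_mesh(base, rotation_matrix(c(0, 1, 1), 2.0), c(-15, 8, 30))
  f1 <- curvature_field(base)
  f2 <- curvature_field(moved)
  rg <- descriptor_ranges(list(f1), "mean_curvature")
  d1 <- build_descriptor(f1, "mean_curvature", "histogram", 64, rg)
  d2 <- build_descriptor(f2, "mean_curvature", "histogram", 64, rg)
  expect_lt(sum(abs(d1$values - d2$values)), 1e-3)
})

test_that("histograms sum to one for every feature type", {
  cf <- curvature_field(mesh_icosphere(1, 3), ring = 2)
  for (ft in c("shape_operator", "gaussian_curvature", "mean_curvature")) {
    fv <- build_descriptor(cf, ft, "histogram", 32)
    expect_equal(sum(fv$values), 1, tolerance = 1e-9)
  }
})

test_that("feature-level fusion concatenates hippocampus before amygdala", {
  cf <- curvature_field(mesh_icosphere(1, 3), ring = 2)
  cf2 <- curvature_field(mesh_icosphere(2, 3), ring = 2)
  rg <- descriptor_ranges(list(cf, cf2), "mean_curvature")  # shared range
  a <- build_descriptor(cf, "mean_curvature", "histogram", 64, rg,
                        subject_id = "s1", region_tag = "hippocampus")
  b <- build_descriptor(cf2, "mean_curvature", "histogram", 64, rg,
                        subject_id = "s1", region_tag = "amygdala")
  fu <- fuse_features(a, b)
  expect_equal(length(fu$values), 128)
  expect_identical(fu$region_tag, "feature_fusion")
  # prefix property: first half is exactly the hippocampus vector
  expect_identical(fu$values[1:64], a$values)
  # order matters as a sequence but not as a multiset
  fu2 <- fuse_features(b, a)
  expect_false(identical(fu$values, fu2$values))
  expect_equal(sort(fu$values), sort(fu2$values))

  b2 <- b; b2$subject_id <- "s2"
  expect_error(fuse_features(a, b2), "pairing error")
  b3 <- b; b3$feature_type <- "gaussian_curvature"
  expect_error(fuse_features(a, b3), "feature type")
})

test_that("descriptor length contract is enforced", {
  cf <- curvature_field(mesh_icosphere(1, 2), ring = 2)
  expect_error(build_descriptor(cf, "mean_curvature", length = 4), ">= 8")
  expect_error(build_descriptor(cf, "mean_curvature", "quantile", length = 1), ">= 2")
  cf$ok[] <- FALSE
  expect_error(build_descriptor(cf, "mean_curvature"), "empty")
})
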