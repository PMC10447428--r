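test_that("quadric shape-operator fit recovers analytic curvatures", {
  # unit sphere: kappa1 = kappa2 = 1
  s <- mesh_icosphere(1, 4)
  cf <- curvature_field(s, ring = 2)
  expect_gt(mean(abs(cf$kappa1 - 1) < 0.05 & abs(cf$kappa2 - 1) < 0.05), 0.95)

  # flat plane: both curvatures vanish at interior vertices
  pl <- mesh_plane(15, 15, 1)
  cfp <- curvature_field(pl, ring = 2)
  interior <- which(abs(pl$vertices[, 1]) < 0.7 & abs(pl$vertices[, 2]) < 0.7)
  expect_lt(max(abs(cfp$kappa1[interior])), 1e-6)
  expect_lt(max(abs(cfp$kappa2[interior])), 1e-6)

  # cylinder of radius 2: lateral curvatures {1/2, 0}
  cy <- mesh_cylinder(2, 12, 96, 48)
  cfc <- curvature_field(cy, ring = 2)
  lat <- which(abs(cy$vertices[, 3]) < 4 &
                 abs(sqrt(rowSums(cy$vertices[, 1:2]^2)) - 2) < 1e-9)
  expect_lt(abs(stats::median(cfc$kappa1[lat]) - 0.5), 0.025)
  expect_lt(abs(stats::median(cfc$kappa2[lat])), 0.025)
})

test_that("principal curvature extraction from a 2x2 operator is exact", {
  expect_equal(principal_curvatures(rbind(c(2, 0), c(0, 3))), c(3, 2))
  expect_equal(principal_curvatures(rbind(c(0, 1), c(1, 0))), c(1, -1))
  expect_equal(principal_curvatures(rbind(c(0.7, 0), c(0, 0.7))), c(0.7, 0.7))
  expect_error(principal_curvatures(rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("K and H compose from principal curvatures as product and mean", {
  expect_identical(gaussian_curvature(2, 3), 6)
  expect_identical(gaussian_curvature(1, -1), -1)
  expect_identical(gaussian_curvature(0.5, 0), 0)
  expect_identical(mean_curvature(2, 4), 3)
  expect_identical(mean_curvature(1, -1), 0)
  expect_identical(mean_curvature(1, 1), 1)
})

test_that("surface points classify as elliptic, parabolic or hyperbolic", {
  expect_identical(classify_surface_point(0.04), "elliptic")     # sphere-like
  expect_identical(classify_surface_point(0), "parabolic")       # cylinder-like
  expect_identical(classify_surface_point(-1), "hyperbolic")     # saddle
  expect_identical(classify_surface_point(c(1e-9, 2e-6, -2e-6), tol = 1e-6),
                   c("parabolic", "elliptic", "hyperbolic"))
  expect_error(classify_surface_point(1, tol = -1), "tol")
})

test_that("derived fields are algebraically consistent with the operator", {
  for (mesh in list(mesh_icosphere(2, 3), mesh_torus(2, 0.7, 48, 24))) {
    cf <- curvature_field(mesh, ring = 2)
    expect_true(all(cf$kappa1 >= cf$kappa2))
    detS <- cf$shape_operator[, 1] * cf$shape_operator[, 3] - cf$shape_operator[, 2]^2
    trS <- cf$shape_operator[, 1] + cf$shape_operator[, 3]
    expect_equal(cf$K, detS, tolerance = 1e-12)
    expect_equal(cf$H, trS / 2, tolerance = 1e-12)
    expect_equal(cf$K, cf$kappa1 * cf$kappa2, tolerance = 1e-12)
    expect_equal(cf$H, (cf$kappa1 + cf$kappa2) / 2, tolerance = 1e-12)
    # vertex areas partition the total surface area
    expect_equal(sum(cf$vertex_area), sum(face_areas(mesh)), tolerance = 1e-6)
    expect_true(all(cf$vertex_area > 0))
  }
})

test_that("curvatures are covariant under uniform scaling", {
  s <- mesh_icosphere(1, 3)
  cf1 <- curvature_field(s, ring = 2)
  s2 <- triangle_mesh(s$vertices * 2.5, s$faces)
  cf2 <- curvature_field(s2, ring = 2)
  expect_equal(stats::median(cf2$H), stats::median(cf1$H) / 2.5, tolerance = 0.02)
  expect_equal(stats::median(cf2$K), stats::median(cf1$K) / 2.5^2, tolerance = 0.02)
})

test_that("curvatures are invariant under rigid motion", {
  base <- smooth_mesh(extract_surface(vox_ellipsoid_mask(c(12, 9, 7))), 20)
  cf1 <- curvature_field(base)
  moved <- transform_mesh(base, rotation_matrix(c(1, -1, 2), 1.1), c(20, -7, 13))
  cf2 <- curvature_field(moved)
  rel <- function(a, b) max(abs(a - b)) / max(abs(a))
  expect_lt(rel(cf1$H, cf2$H), 1e-3)
  expect_lt(rel(cf1$K, cf2$K), 1e-3)
})

test_that("Gauss-Bonnet integral matches the Euler characteristic", {
  sph <- smoothed_sphere_field(12)
  expect_lt(gauss_bonnet_residual(sph$field, sph$mesh), 0.02)

  ell <- smooth_mesh(extract_surface(vox_ellipsoid_mask(c(20, 15, 10))), 20)
  cfe <- curvature_field(ell)
  expect_lt(gauss_bonnet_residual(cfe, ell), 0.02)

  to <- mesh_torus(2, 0.7, 96, 48)
  cft <- curvature_field(to, ring = 2)
  expect_lt(gauss_bonnet_residual(cft, to), 0.1)  # chi = 0 guard arm
  expect_error(gauss_bonnet_residual(cft, mesh_plane(8, 8, 1)), "open mesh")
})

test_that("quadric estimator agrees with the angle-deficit oracle", {
  # near-equilateral triangulation, where the angle-deficit estimator is
  # itself unbiased; radius 2 so K = 0.25
  s <- mesh_icosphere(2, 4)
  cf <- curvature_field(s, ring = 2)
  K_oracle <- angle_deficit_K(s)
  expect_lt(abs(stats::median(cf$K) / stats::median(K_oracle) - 1), 0.03)
  expect_lt(abs(stats::median(K_oracle) / 0.25 - 1), 0.03)
  # and the area-weighted integrals both recover 4*pi
  expect_lt(abs(sum(cf$K * cf$vertex_area) / (4 * pi) - 1), 0.02)
})
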