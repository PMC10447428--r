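test_that("mask loading binarises by threshold and preserves the affine", {
  arr <- array(0, c(6, 7, 8))
  arr[2:4, 2:4, 2:4] <- 0.7
  arr[5, 5, 5] <- 0.2
  aff <- diag(c(1.5, 1, 1.25, 1)); aff[1:3, 4] <- c(-10, 5.5, 2)
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(aff, code = 2L)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)

  m <- read_mask(f, threshold = 0.5, subject_id = "s1")
  expect_equal(sum(m$grid), 27)              # only the 0.7 voxels survive
  expect_equal(m$affine, aff, tolerance = 1e-6)
  expect_equal(m$spacing, c(1.5, 1, 1.25), tolerance = 1e-6)

  # already-binary volume is unchanged at the default cut
  g2 <- (arr >= 0.5) * 1
  img2 <- RNifti::asNifti(g2)
  f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img2, f2)
  m2 <- read_mask(f2)
  expect_equal(as.vector(m2$grid), as.vector(g2))
})

test_that("empty and unreadable masks fail loudly with subject context", {
  img <- RNifti::asNifti(array(0, c(4, 4, 4)))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_mask(f, subject_id = "sub-9", region_tag = "amygdala"),
               "empty mask.*sub-9.*amygdala")
  expect_error(read_mask(tempfile(fileext = ".nii")), "not found")
})

test_that("label maps can be reduced to one structure before binarisation", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:3, 2:3, 2:3] <- 17L   # hippocampus label
  arr[5, 5, 5] <- 53L         # another structure
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  m <- read_mask(f, label = 17)
  expect_equal(sum(m$grid), 8)
})

test_that("multi-component masks warn, and keep_largest drops specks", {
  arr <- array(0, c(10, 10, 10))
  arr[2:6, 2:6, 2:6] <- 1   # main blob, 125 voxels
  arr[9, 9, 9] <- 1         # speck
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  expect_warning(m <- read_mask(f), "2 connected components")
  expect_equal(sum(m$grid), 126)
  m2 <- read_mask(f, keep_largest = TRUE)
  expect_equal(sum(m2$grid), 125)
})

test_that("region fusion is the set union and demands a shared space", {
  g <- array(0, c(12, 12, 12))
  a <- g; a[2:5, 2:5, 2:5] <- 1            # 64 voxels
  b <- g; b[8:10, 8:10, 8:10] <- 1         # 27 voxels, disjoint
  ma <- voxel_mask(a, subject_id = "s", region_tag = "hippocampus")
  mb <- voxel_mask(b, subject_id = "s", region_tag = "amygdala")
  fu <- fuse_regions(ma, mb)
  expect_equal(sum(fu$grid), 64 + 27)
  expect_identical(fu$region_tag, "fused")

  # fusing a mask with itself is idempotent
  expect_equal(fuse_regions(ma, ma)$grid, ma$grid)

  # overlap follows inclusion-exclusion
  c_ <- g; c_[4:6, 2:5, 2:5] <- 1          # 48 voxels, 32 overlapping with a
  mc <- voxel_mask(c_, subject_id = "s", region_tag = "amygdala")
  expect_equal(sum(fuse_regions(ma, mc)$grid), 64 + 48 - 32)

  # commutative and associative
  expect_equal(fuse_regions(ma, mb)$grid, fuse_regions(mb, ma)$grid)
  expect_equal(fuse_regions(fuse_regions(ma, mb), mc)$grid,
               fuse_regions(ma, fuse_regions(mb, mc))$grid)

  # mismatched spaces are refused
  small <- voxel_mask(array(1, c(4, 4, 4)))
  expect_error(fuse_regions(ma, small), "grid mismatch")
  aff2 <- diag(4); aff2[1, 4] <- 5
  mb2 <- voxel_mask(b, aff2, "s", "amygdala")
  expect_error(fuse_regions(ma, mb2), "grid mismatch")
})

test_that("mask volume is count times voxel volume and matches the analytic sphere", {
  g <- array(0, c(20, 20, 20)); g[sample(8000, 1000)] <- 1
  aff <- diag(c(1.2, 1, 1, 1))
  expect_equal(mask_volume(voxel_mask(g, aff)), 1200)
  expect_equal(mask_volume(voxel_mask(array(c(1, rep(0, 26)), c(3, 3, 3)))), 1)

  m <- vox_sphere_mask(15)
  expect_lt(abs(mask_volume(m) / (4 / 3 * pi * 15^3) - 1), 0.02)
})

test_that("volume of a fused mask is subadditive with equality iff disjoint", {
  g <- array(0, c(12, 12, 12))
  a <- g; a[2:5, 2:5, 2:5] <- 1
  b <- g; b[8:10, 8:10, 8:10] <- 1
  c_ <- g; c_[4:6, 2:5, 2:5] <- 1
  ma <- voxel_mask(a); mb <- voxel_mask(b); mc <- voxel_mask(c_)
  expect_equal(mask_volume(fuse_regions(ma, mb)), mask_volume(ma) + mask_volume(mb))
  expect_lt(mask_volume(fuse_regions(ma, mc)), mask_volume(ma) + mask_volume(mc))
})

test_that("write/read round-trip preserves grid and affine exactly", {
  m <- vox_sphere_mask(6, spacing = 1.5)
  f <- tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  m2 <- read_mask(f, subject_id = m$subject_id)
  expect_identical(m2$grid, m$grid)
  expect_identical(m2$affine, m$affine)
})
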