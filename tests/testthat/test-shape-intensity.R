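test_that("shape features recover analytic geometry of digital solids", {
  # ball of radius 10 mm on a 1 mm grid
  n <- 25
  ball <- radiogbm:::ellipsoid_mask_array(c(n, n, n), c(1, 1, 1),
                                          c(12, 12, 12), c(10, 10, 10))
  s <- compute_shape(voi_mask(ball + 0, c(1, 1, 1), c(0, 0, 0), "tumoral"))
  expect_gte(s[["sphericity"]], 0.95)
  expect_lte(s[["sphericity"]], 1.0)
  expect_lt(abs(s[["surface_area_mm2"]] - 4 * pi * 100) / (4 * pi * 100),
            0.06)
  expect_equal(s[["maximum_3d_diameter"]], 20, tolerance = 0.05)
  expect_lt(abs(s[["equivalent_sphere_diameter"]] - 20) / 20, 0.05)

  # 10x10x10 voxel cube: voxel-counted volume exactly 1000 mm^3
  cube <- array(0, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1
  sc <- compute_shape(voi_mask(cube, c(1, 1, 1), c(0, 0, 0), "tumoral"))
  expect_equal(sc[["volume_mm3"]], 1000)
  expect_equal(sc[["voxel_count"]], 1000)
  expect_equal(sc[["filled_fraction"]], 1)

  # ellipsoid semi-axes (15, 10, 5): PCA axis lengths within 5% of
  # 4 * sqrt(a^2 / 5) (analytic covariance of a uniform ellipsoid)
  ell <- radiogbm:::ellipsoid_mask_array(c(36, 26, 16), c(1, 1, 1),
                                         c(17, 12, 7), c(15, 10, 5))
  se <- compute_shape(voi_mask(ell + 0, c(1, 1, 1), c(0, 0, 0), "tumoral"))
  expect_lt(abs(se[["major_axis_length"]] - 4 * 15 / sqrt(5)) /
              (4 * 15 / sqrt(5)), 0.05)
  expect_lt(abs(se[["minor_axis_length"]] - 4 * 10 / sqrt(5)) /
              (4 * 10 / sqrt(5)), 0.05)
  expect_lt(abs(se[["least_axis_length"]] - 4 * 5 / sqrt(5)) /
              (4 * 5 / sqrt(5)), 0.05)
  expect_lt(abs(se[["elongation"]] - 10 / 15), 0.05)
  expect_lt(abs(se[["flatness"]] - 5 / 15), 0.05)
})

test_that("shape features count 24 and flag degenerate single voxels", {
  m <- array(0, c(3, 3, 3)); m[2, 2, 2] <- 1
  s <- compute_shape(voi_mask(m, c(1, 1, 1), c(0, 0, 0), "tumoral"))
  expect_length(s, 24)
  expect_true(all(c("elongation", "flatness") %in% attr(s, "degenerate")))
  expect_equal(s[["maximum_3d_diameter"]], 0)
  expect_true(all(is.finite(s)))
  expect_error(compute_shape(voi_mask(m, c(1, 1, 3), c(0, 0, 0), "tumoral")),
               "cubic")
})

test_that("shape translation invariance within the grid", {
  blob <- radiogbm:::ellipsoid_mask_array(c(20, 20, 20), c(1, 1, 1),
                                          c(7, 7, 7), c(5, 4, 3))
  a <- array(0, c(30, 30, 30)); a[1:20, 1:20, 1:20] <- blob
  b <- array(0, c(30, 30, 30)); b[9:28, 9:28, 9:28] <- blob
  sa <- compute_shape(voi_mask(a, c(1, 1, 1), c(0, 0, 0), "tumoral"))
  sb <- compute_shape(voi_mask(b, c(1, 1, 1), c(0, 0, 0), "tumoral"))
  expect_equal(sa, sb, tolerance = 1e-9)
})

test_that("intensity features reproduce hand-computed values", {
  arr <- array(c(1, 1, 3, 3), c(2, 2, 1))
  g <- voxel_grid(arr, c(1, 1, 1))
  m <- voi_mask(array(1, c(2, 2, 1)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  f <- compute_intensity(g, m)
  expect_length(f, 19)
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["variance"]], 1)          # population convention
  expect_equal(f[["coefficient_of_variation"]], 0.5)
  expect_equal(f[["range"]], 2)
  expect_equal(f[["skewness"]], 0)
})

test_that("constant VOIs are flagged degenerate, not NaN", {
  g <- voxel_grid(array(5, c(3, 3, 3)), c(1, 1, 1))
  m <- voi_mask(array(1, c(3, 3, 3)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  f <- compute_intensity(g, m)
  expect_equal(f[["coefficient_of_variation"]], 0)
  expect_equal(f[["variance"]], 0)
  expect_true(all(is.finite(f)))
  expect_true(all(paste0("enhancing_tumor_volume_", c(30, 40, 70)) %in%
                    attr(f, "degenerate")))
})

test_that("a linear ramp puts the expected volume above each cut", {
  v <- array(seq(0, 1, length.out = 1000), c(10, 10, 10))
  g <- voxel_grid(v, c(1, 1, 1))
  m <- voi_mask(array(1, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  f <- compute_intensity(g, m)
  expect_equal(f[["enhancing_tumor_volume_30"]], 0.7, tolerance = 0.01)
  expect_equal(f[["enhancing_tumor_volume_40"]], 0.6, tolerance = 0.01)
  expect_equal(f[["enhancing_tumor_volume_70"]], 0.3, tolerance = 0.01)
  # histogram entropy of a uniform 32-level histogram is log2(32)
  expect_equal(f[["histogram_entropy"]], 5, tolerance = 0.01)
  expect_equal(f[["histogram_energy"]], 1 / 32, tolerance = 0.001)
})

test_that("intensity features are invariant under FBN to affine transforms", {
  set.seed(8)
  v <- array(stats::rnorm(4 * 4 * 4, 50, 12), c(4, 4, 4))
  m <- voi_mask(array(1, c(4, 4, 4)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  g1 <- voxel_grid(v, c(1, 1, 1))
  g2 <- voxel_grid(2.5 * v + 40, c(1, 1, 1))
  dv1 <- discretize_fixed_bin_number(g1, m, 16)
  dv2 <- discretize_fixed_bin_number(g2, m, 16)
  lev1 <- dv1$levels; lev1[is.na(lev1)] <- 0
  lev2 <- dv2$levels; lev2[is.na(lev2)] <- 0
  f1 <- compute_intensity(voxel_grid(lev1 + 0, c(1, 1, 1)), m, dv1)
  f2 <- compute_intensity(voxel_grid(lev2 + 0, c(1, 1, 1)), m, dv2)
  expect_equal(f1, f2, tolerance = 1e-12)
})
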