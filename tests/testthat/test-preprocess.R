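test_that("trilinear resampling preserves constants and identities", {
  g <- voxel_grid(array(7, c(10, 10, 10)), c(2, 2, 2))
  r <- resample_trilinear(g, 3)
  expect_true(all(abs(r$data - 7) < 1e-12))
  expect_equal(r$spacing, c(3, 3, 3))

  # already cubic at the target: identity
  g2 <- voxel_grid(array(stats::rnorm(8 * 8 * 8), c(8, 8, 8)), c(3, 3, 3))
  r2 <- resample_trilinear(g2, 3)
  expect_equal(r2$data, g2$data, tolerance = 1e-12)

  expect_error(resample_trilinear(g2, 100), "extent")
})

test_that("trilinear resampling reproduces affine intensity fields exactly", {
  n <- c(31, 31, 13)
  sp <- c(1, 1, 3)
  ramp <- array(0, n)
  for (i in seq_len(n[1])) ramp[i, , ] <- (i - 1) * sp[1]  # I(x) = x mm^-1
  g <- voxel_grid(ramp, sp)
  r <- resample_trilinear(g, 3)
  centers <- (seq_len(dim(r$data)[1]) - 1) * 3
  for (k in seq_len(dim(r$data)[3]))
    expect_equal(r$data[, 3, k], centers, tolerance = 1e-6)
})

test_that("mask resampling thresholds at 0.5 and keeps the role", {
  m <- array(0, c(12, 12, 12)); m[4:9, 4:9, 4:9] <- 1
  mk <- voi_mask(m, c(1, 1, 1), c(0, 0, 0), "peritumoral")
  r <- resample_mask_trilinear(mk, 2)
  expect_identical(r$role, "peritumoral")
  expect_true(all(r$data %in% c(0, 1)))
  expect_gt(sum(r$data) * 8, 100)   # roughly preserves volume
})

test_that("fixed-bin-number discretization maps the range onto 1..G", {
  v <- array(stats::runif(5 * 5 * 4, 10, 40), c(5, 5, 4))
  g <- voxel_grid(v, c(1, 1, 1))
  m <- voi_mask(array(1, c(5, 5, 4)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  dv <- discretize_fixed_bin_number(g, m, 32)
  lv <- dv$levels[!is.na(dv$levels)]
  expect_equal(lv[which.min(v)], 1L)
  expect_equal(lv[which.max(v)], 32L)
  expect_true(all(lv >= 1 & lv <= 32))
  expect_equal(dv$G, 32L)

  # constant region: level 1 everywhere plus a degeneracy warning
  gc <- voxel_grid(array(5, c(3, 3, 3)), c(1, 1, 1))
  mc <- voi_mask(array(1, c(3, 3, 3)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  expect_warning(dvc <- discretize_fixed_bin_number(gc, mc), "constant")
  expect_true(all(dvc$levels == 1L))
})

test_that("an exact arithmetic sequence fills all 32 bins evenly", {
  # 3200 values, 100 equally spaced inside each of 32 unit-wide blocks:
  # every level must hold exactly 100 values
  vals <- as.vector(outer(seq(0, 0.99, length.out = 100), 0:31, `+`))
  arr <- array(vals, c(20, 20, 8))
  g <- voxel_grid(arr, c(1, 1, 1))
  m <- voi_mask(array(1, c(20, 20, 8)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  dv <- discretize_fixed_bin_number(g, m, 32)
  counts <- tabulate(dv$levels[!is.na(dv$levels)], 32)
  expect_equal(counts, rep(100L, 32))
})

test_that("two-point linear normalization solves the stated 2x2 system", {
  dm <- c(8, 8, 4)
  base <- array(100, dm)
  wm <- array(0, dm); wm[1:2, 1:2, 1] <- 1
  vit <- array(0, dm); vit[6:7, 6:7, 1] <- 1
  base[wm == 1] <- 200
  base[vit == 1] <- 50
  base[4, 4, 2] <- 125                       # probe voxel
  g <- voxel_grid(base, c(1, 1, 1))
  wm_m <- voi_mask(wm, c(1, 1, 1), c(0, 0, 0), "wm_reference")
  vit_m <- voi_mask(vit, c(1, 1, 1), c(0, 0, 0), "vitreous_reference")
  spec <- normalization_spec("linear_two_point", anchor_wm = 300,
                             anchor_vitreous = 0)
  out <- normalize_linear_two_point(g, wm_m, vit_m, spec)
  tr <- attr(out, "transform")
  expect_equal(unname(tr["a"]), 2)
  expect_equal(unname(tr["b"]), -100)
  expect_equal(out$data[4, 4, 2], 150)

  # reference means already on the anchors: identity
  out2 <- normalize_linear_two_point(out, wm_m, vit_m, spec)
  expect_equal(out2$data, out$data, tolerance = 1e-12)

  # scanner affine distortion is fully absorbed
  g_dist <- voxel_grid(2 * base + 7, c(1, 1, 1))
  out3 <- normalize_linear_two_point(g_dist, wm_m, vit_m, spec)
  expect_equal(out3$data, out$data, tolerance = 1e-9)

  # equal reference means: degenerate
  flat <- voxel_grid(array(1, dm), c(1, 1, 1))
  expect_error(normalize_linear_two_point(flat, wm_m, vit_m, spec),
               "degenerate")
})

test_that("fixed-bin-size discretization uses the in-mask minimum anchor", {
  arr <- array(0, c(2, 2, 1))
  arr[1, 1, 1] <- 0; arr[2, 1, 1] <- 49.9; arr[1, 2, 1] <- 50
  arr[2, 2, 1] <- 149
  g <- voxel_grid(arr, c(1, 1, 1))
  m <- voi_mask(array(1, c(2, 2, 1)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  dv <- discretize_fixed_bin_size(g, m, 50)
  expect_equal(as.vector(dv$levels), c(1L, 1L, 2L, 3L))
  expect_equal(dv$G, 3L)

  # constant region: single level
  gc <- voxel_grid(array(5, c(2, 2, 1)), c(1, 1, 1))
  dvc <- discretize_fixed_bin_size(gc, m, 50)
  expect_equal(dvc$G, 1L)

  # intensity range 1600 at bin width 50: 33 levels, comparable to 32 bins
  v <- array(seq(0, 1600, length.out = 64), c(4, 4, 4))
  gi <- voxel_grid(v, c(1, 1, 1))
  mi <- voi_mask(array(1, c(4, 4, 4)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  expect_equal(discretize_fixed_bin_size(gi, mi, 50)$G, 33L)
})

test_that("both discretizations are monotone and FBN is affine-invariant", {
  set.seed(21)
  v <- stats::rnorm(60, 100, 25)
  arr <- array(v, c(5, 4, 3))
  g <- voxel_grid(arr, c(1, 1, 1))
  m <- voi_mask(array(1, c(5, 4, 3)), c(1, 1, 1), c(0, 0, 0), "tumoral")
  for (dv in list(discretize_fixed_bin_number(g, m, 8),
                  discretize_fixed_bin_size(g, m, 20))) {
    lv <- dv$levels[order(v)]
    expect_true(all(diff(lv) >= 0))
  }
  dv1 <- discretize_fixed_bin_number(g, m, 8)
  g2 <- voxel_grid(3.7 * arr + 11, c(1, 1, 1))
  dv2 <- discretize_fixed_bin_number(g2, m, 8)
  expect_identical(dv1$levels, dv2$levels)
})
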