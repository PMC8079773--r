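#' Intensity normalization specification
#'
#' Bundles the parameters of the two supported normalization/discretization
#' schemes. `fixed_bin_number` divides the in-VOI intensity range into
#' `n_bins` equal bins (the discretization itself is the normalization).
#' `linear_two_point` first rescales the whole volume by the affine map that
#' sends the mean intensity of the white-matter reference region to
#' `anchor_wm` and the mean of the vitreous-body reference to
#' `anchor_vitreous`, then discretizes with a fixed bin width `bin_size`.
#' The default anchors (vitreous 0, white matter 300) give roughly 30-35
#' grey levels at bin width 50 for typical contrast, keeping both schemes'
#' level counts comparable.
#'
#' @param method `"fixed_bin_number"` or `"linear_two_point"`.
#' @param n_bins number of bins for fixed-bin-number discretization (>= 2).
#' @param bin_size bin width for fixed-bin-size discretization (> 0).
#' @param anchor_wm,anchor_vitreous target intensities of the two reference
#'   tissues after linear rescaling (must differ).
#' @return a `normalization_spec`.
#' @export
normalization_spec <- function(method = c("fixed_bin_number",
                                          "linear_two_point"),
                               n_bins = 32, bin_size = 50,
                               anchor_wm = 300, anchor_vitreous = 0) {
  method <- match.arg(method)
  if (n_bins < 2) stop("normalization_spec: n_bins must be >= 2")
  if (bin_size <= 0) stop("normalization_spec: bin_size must be > 0")
  if (anchor_wm == anchor_vitreous)
    stop("normalization_spec: reference anchors must be distinct")
  structure(list(method = method, n_bins = as.integer(n_bins),
                 bin_size = bin_size, anchor_wm = anchor_wm,
                 anchor_vitreous = anchor_vitreous),
            class = "normalization_spec")
}

#' Trilinear resampling to cubic voxels
#'
#' Resamples a volume to cubic voxel size `target_mm` by trilinear
#' interpolation of voxel-centre samples (1 mm for shape analysis, 3 mm for
#' intensity and texture analysis). The target lattice shares the source
#' origin and covers the source extent without extrapolation; when the source
#' is already cubic at `target_mm` the transform is the identity. Masks are
#' resampled by the same transform and thresholded at 0.5 (values >= 0.5 are
#' inside).
#'
#' @param grid a [voxel_grid()].
#' @param target_mm cubic voxel edge length, mm.
#' @return resampled `voxel_grid` / `voi_mask`.
#' @export
resample_trilinear <- function(grid, target_mm) {
  stopifnot(inherits(grid, "voxel_grid"), target_mm > 0)
  src <- grid$data
  n <- dim(src); s <- grid$spacing
  if (any(target_mm > n * s))
    stop("resample_trilinear: target voxel (", target_mm,
         " mm) exceeds the volume extent (",
         paste(signif(n * s, 4), collapse = "x"), " mm)")
  nt <- pmax(1L, as.integer(floor((n - 1) * s / target_mm + 1e-9)) + 1L)
  idx <- lapply(1:3, function(ax) {
    u <- ((seq_len(nt[ax]) - 1) * target_mm) / s[ax] + 1  # fractional source index
    i0 <- pmin(pmax(floor(u), 1), max(n[ax] - 1L, 1L))
    f <- pmin(pmax(u - i0, 0), 1)
    i1 <- pmin(i0 + 1L, n[ax])
    list(i0 = as.integer(i0), i1 = as.integer(i1), f = f)
  })
  out <- array(0, nt)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) idx[[1]]$i0 else idx[[1]]$i1
    iy <- if (cy == 0) idx[[2]]$i0 else idx[[2]]$i1
    iz <- if (cz == 0) idx[[3]]$i0 else idx[[3]]$i1
    wx <- if (cx == 0) 1 - idx[[1]]$f else idx[[1]]$f
    wy <- if (cy == 0) 1 - idx[[2]]$f else idx[[2]]$f
    wz <- if (cz == 0) 1 - idx[[3]]$f else idx[[3]]$f
    w <- outer(outer(wx, wy), wz)
    if (all(w == 0)) next
    out <- out + src[ix, iy, iz, drop = FALSE] * w
  }
  voxel_grid(out, spacing = rep(target_mm, 3), origin = grid$origin)
}

#' @rdname resample_trilinear
#' @param mask a [voi_mask()] to resample with the same transform.
#' @export
resample_mask_trilinear <- function(mask, target_mm) {
  g <- resample_trilinear(
    voxel_grid(mask$data + 0, mask$spacing, mask$origin), target_mm)
  voi_mask((g$data >= 0.5) + 0, g$spacing, g$origin, mask$role)
}

new_discretized_volume <- function(levels, G, method, params, spacing) {
  structure(list(levels = levels, G = as.integer(G), method = method,
                 params = params, spacing = spacing),
            class = "discretized_volume")
}

#' @export
print.discretized_volume <- function(x, ...) {
  cat("<discretized_volume> ", x$method, ", G=", x$G, ", ",
      sum(!is.na(x$levels)), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Fixed-bin-number discretization
#'
#' Maps in-mask intensities to levels `1..n_bins` by dividing the observed
#' in-mask intensity range into `n_bins` equal bins:
#' `level = 1 + floor(n_bins * (I - I_min) / (I_max - I_min))`, with the
#' maximum mapped to `n_bins`. Voxels outside the mask carry `NA` and are
#' excluded from all downstream statistics. The output is invariant to any
#' orientation-preserving affine transform of the input intensities.
#'
#' @param grid a [voxel_grid()].
#' @param mask aligned nonempty [voi_mask()].
#' @param n_bins number of grey levels (default 32).
#' @return a `discretized_volume` with `G = n_bins`.
#' @export
discretize_fixed_bin_number <- function(grid, mask, n_bins = 32) {
  check_aligned(grid, mask)
  inmask <- mask$data != 0L
  if (!any(inmask)) stop("discretize_fixed_bin_number: empty mask")
  v <- grid$data[inmask]
  lo <- min(v); hi <- max(v)
  lev <- array(NA_integer_, dim(grid$data))
  if (hi == lo) {
    warning("discretize_fixed_bin_number: constant intensity in mask; ",
            "all voxels assigned level 1")
    lev[inmask] <- 1L
  } else {
    lev[inmask] <- pmin(1L + as.integer(floor(n_bins * (v - lo) / (hi - lo))),
                        as.integer(n_bins))
  }
  new_discretized_volume(lev, n_bins, "fixed_bin_number",
                         list(n_bins = n_bins, i_min = lo, i_max = hi),
                         grid$spacing)
}

#' Two-point linear intensity normalization
#'
#' Applies the affine intensity map `I' = a I + b` with `a`, `b` solved so
#' that the mean intensity over the white-matter reference mask equals
#' `spec$anchor_wm` and the mean over the vitreous-body reference mask equals
#' `spec$anchor_vitreous`. The map is applied to the whole volume; applying
#' the normalization twice is idempotent, and any affine distortion of the
#' input (scanner gain/offset) yields an identical normalized volume.
#'
#' @param grid a [voxel_grid()].
#' @param wm_mask,vitreous_mask aligned nonempty reference [voi_mask()]s.
#' @param spec a [normalization_spec()].
#' @return normalized `voxel_grid`, with the fitted `a`, `b` attached as
#'   attribute `transform`.
#' @export
normalize_linear_two_point <- function(grid, wm_mask, vitreous_mask,
                                       spec = normalization_spec("linear_two_point")) {
  check_aligned(grid, wm_mask); check_aligned(grid, vitreous_mask)
  if (!any(wm_mask$data != 0) || !any(vitreous_mask$data != 0))
    stop("normalize_linear_two_point: empty reference mask")
  m_wm <- mean(grid$data[wm_mask$data != 0])
  m_vit <- mean(grid$data[vitreous_mask$data != 0])
  if (isTRUE(all.equal(m_wm, m_vit)))
    stop("normalize_linear_two_point: reference means are equal (",
         signif(m_wm, 6), "); two-point rescaling is degenerate")
  a <- (spec$anchor_wm - spec$anchor_vitreous) / (m_wm - m_vit)
  b <- spec$anchor_wm - a * m_wm
  out <- voxel_grid(a * grid$data + b, grid$spacing, grid$origin)
  attr(out, "transform") <- c(a = a, b = b)
  out
}

#' Fixed-bin-size discretization
#'
#' Maps in-mask intensities to levels with constant bin width:
#' `level = 1 + floor((I - I_min) / bin_size)` where `I_min` is the in-mask
#' minimum; the number of levels `G` is the maximum assigned level. Intended
#' to follow [normalize_linear_two_point()], with a bin width (default 50)
#' chosen so the level count is comparable to the 32-bin fixed-bin-number
#' scheme.
#'
#' @param grid a (normalized) [voxel_grid()].
#' @param mask aligned nonempty [voi_mask()].
#' @param bin_size bin width in intensity units (default 50).
#' @return a `discretized_volume`.
#' @export
discretize_fixed_bin_size <- function(grid, mask, bin_size = 50) {
  check_aligned(grid, mask)
  inmask <- mask$data != 0L
  if (!any(inmask)) stop("discretize_fixed_bin_size: empty mask")
  v <- grid$data[inmask]
  if (any(!is.finite(v)))
    stop("discretize_fixed_bin_size: non-finite intensities in mask")
  lo <- min(v)
  lev <- array(NA_integer_, dim(grid$data))
  lev[inmask] <- 1L + as.integer(floor((v - lo) / bin_size))
  new_discretized_volume(lev, max(lev[inmask]), "fixed_bin_size",
                         list(bin_size = bin_size, i_min = lo),
                         grid$spacing)
}
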