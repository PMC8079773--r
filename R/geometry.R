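#' Pre-contrast subtraction of blood residuals
#'
#' Removes voxels that are already hyperintense on the pre-contrast T1 volume
#' (blood residuals along a resection cavity) from the post-contrast tumor
#' mask, so only genuinely contrast-enhancing tissue remains.
#'
#' @param post_mask tumor [voi_mask()] drawn on the post-contrast volume.
#' @param pre_hyperintense_mask [voi_mask()] of pre-contrast hyperintensity.
#' @return the cleaned tumor `voi_mask`.
#' @export
subtract_precontrast <- function(post_mask, pre_hyperintense_mask) {
  check_aligned(post_mask, pre_hyperintense_mask)
  res <- post_mask$data * (1L - pre_hyperintense_mask$data)
  if (sum(res) == 0L)
    stop("subtract_precontrast: tumor mask fully explained by pre-contrast ",
         "hyperintensity; nothing left to analyse")
  voi_mask(res, post_mask$spacing, post_mask$origin, post_mask$role)
}

# "no source on this line yet" sentinel; large but finite so the
# lower-envelope arithmetic never produces Inf - Inf
.DT_BIG <- 1e20

# Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform
# on arbitrary sample positions x (mm). f is the current squared-distance
# field along the line; returns min_j f[j] + (x - x[j])^2.
dt1d <- function(f, x) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  fx <- f + x * x
  for (q in 2:n) {
    s <- (fx[q] - fx[v[k]]) / (2 * (x[q] - x[v[k]]))
    while (s <= z[k]) {
      k <- k - 1L
      s <- (fx[q] - fx[v[k]]) / (2 * (x[q] - x[v[k]]))
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    p <- v[k]
    d[q] <- f[p] + (x[q] - x[p])^2
  }
  d
}

#' Anisotropy-aware Euclidean distance transform
#'
#' For every voxel centre, the Euclidean distance in world millimetres to the
#' nearest set voxel centre of `mask`, computed by the separable
#' lower-envelope algorithm along each axis with the grid's per-axis spacing.
#'
#' @param mask a [voi_mask()] (or 0/1 array with `spacing`).
#' @param spacing mm per axis, taken from `mask` when it is a `voi_mask`.
#' @return numeric 3D array of distances (mm); 0 inside the mask.
#' @export
distance_transform_mm <- function(mask, spacing = NULL) {
  if (inherits(mask, "voi_mask")) { spacing <- mask$spacing; m <- mask$data }
  else m <- mask
  stopifnot(length(spacing) == 3L)
  dm <- dim(m)
  d2 <- array(ifelse(m != 0, 0, .DT_BIG), dm)
  x1 <- (seq_len(dm[1]) - 1) * spacing[1]
  x2 <- (seq_len(dm[2]) - 1) * spacing[2]
  x3 <- (seq_len(dm[3]) - 1) * spacing[3]
  if (dm[1] > 1L) for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) {
    f <- d2[, j, k]
    if (f[1L] >= .DT_BIG && all(f >= .DT_BIG)) next
    d2[, j, k] <- dt1d(f, x1)
  }
  if (dm[2] > 1L) for (k in seq_len(dm[3])) for (i in seq_len(dm[1])) {
    f <- d2[i, , k]
    if (f[1L] >= .DT_BIG && all(f >= .DT_BIG)) next
    d2[i, , k] <- dt1d(f, x2)
  }
  if (dm[3] > 1L) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    f <- d2[i, j, ]
    if (f[1L] >= .DT_BIG && all(f >= .DT_BIG)) next
    d2[i, j, ] <- dt1d(f, x3)
  }
  sqrt(d2)
}

#' Peritumoral rim construction
#'
#' Builds the peritumoral volume of interest: all voxels whose centre lies
#' within `distance_mm` (world mm, anisotropy-aware, measured centre to
#' centre) of some tumor voxel centre, minus the tumor itself and minus all
#' exclusion regions (resection cavity, ventricle, non-brain tissue). The
#' rim is computed on the native grid, before any resampling.
#'
#' @param tumor tumor [voi_mask()].
#' @param exclusions list of [voi_mask()]s to carve out (may be empty).
#' @param distance_mm rim width in mm (default 15).
#' @return peritumoral [voi_mask()].
#' @export
make_peritumoral_rim <- function(tumor, exclusions = list(), distance_mm = 15) {
  stopifnot(inherits(tumor, "voi_mask"), distance_mm > 0)
  if (sum(tumor$data) == 0L) stop("make_peritumoral_rim: empty tumor mask")
  for (ex in exclusions) check_aligned(tumor, ex)
  d <- distance_transform_mm(tumor)
  rim <- d > 0 & d <= distance_mm
  for (ex in exclusions) rim <- rim & (ex$data == 0L)
  if (!any(rim))
    stop("make_peritumoral_rim: rim empty after exclusions")
  voi_mask(rim + 0, tumor$spacing, tumor$origin, "peritumoral")
}

#' VOI volume and minimum-volume filter
#'
#' Volume in millilitres (1 ml = 1000 mm^3) as voxel count times voxel
#' volume. `below_volume_threshold()` flags masks smaller than `threshold_ml`
#' for exclusion from analysis; the comparison is strict, so a VOI of exactly
#' the threshold volume is kept.
#'
#' @param mask a [voi_mask()].
#' @param threshold_ml exclusion threshold (default 0.2 ml).
#' @return volume in ml / logical flag.
#' @export
voi_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$data) * voxel_volume_mm3(mask) / 1000
}

#' @rdname voi_volume_ml
#' @export
below_volume_threshold <- function(mask, threshold_ml = 0.2) {
  voi_volume_ml(mask) < threshold_ml
}
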