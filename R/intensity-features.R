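#' Intensity features of a VOI
#'
#' Computes the 19 first-order features over the (normalized) in-mask
#' intensities: moments (population conventions; kurtosis is excess
#' kurtosis, so a normal distribution scores 0), order statistics, robust
#' dispersion measures, histogram energy and entropy on the discretized
#' grey levels, and the intensity-volume-histogram features "enhancing
#' tumor volume X%" — the fraction of VOI voxels with intensity strictly
#' above X% of the in-VOI intensity range — for X in 30, 40, 70.
#'
#' Degenerate cases are flagged in the `degenerate` attribute with the value
#' set to the documented convention (coefficient of variation with zero mean,
#' enhancing-volume fractions of a constant VOI: 0).
#'
#' @param grid a [voxel_grid()] of (normalized) intensities.
#' @param mask aligned nonempty [voi_mask()].
#' @param dv optional `discretized_volume` supplying the histogram for
#'   energy/entropy; when `NULL` a 32-level fixed-bin-number discretization
#'   of the masked intensities is used.
#' @return named numeric vector of length 19 with attribute `degenerate`.
#' @export
compute_intensity <- function(grid, mask, dv = NULL) {
  check_aligned(grid, mask)
  inm <- mask$data != 0L
  if (!any(inm)) stop("compute_intensity: empty mask")
  v <- grid$data[inm]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)                     # population variance
  sdv <- sqrt(m2)
  degenerate <- character(0)
  if (m2 > 0) {
    skw <- mean((v - mu)^3) / m2^1.5
    krt <- mean((v - mu)^4) / m2^2 - 3
  } else {
    skw <- 0; krt <- 0
    degenerate <- c(degenerate, "skewness", "kurtosis")
  }
  if (mu != 0) cov_ <- sdv / mu else {
    cov_ <- 0
    if (sdv > 0) degenerate <- c(degenerate, "coefficient_of_variation")
  }
  qs <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                        type = 7)
  rmad_sel <- v[v >= qs[1] & v <= qs[5]]
  rmad <- mean(abs(rmad_sel - mean(rmad_sel)))
  if (is.null(dv)) dv <- discretize_local(v, dim(grid$data), inm, grid$spacing)
  lv <- dv$levels[inm]
  p <- tabulate(lv, nbins = dv$G)
  p <- p / sum(p)
  rng <- max(v) - min(v)
  etv <- function(x) {
    if (rng == 0) return(0)
    mean(v > min(v) + x * rng)
  }
  if (rng == 0)
    degenerate <- c(degenerate, "enhancing_tumor_volume_30",
                    "enhancing_tumor_volume_40", "enhancing_tumor_volume_70")
  out <- c(mean = mu,
           variance = m2,
           skewness = skw,
           kurtosis = krt,
           median = qs[3],
           minimum = min(v),
           maximum = max(v),
           range = rng,
           percentile_10 = qs[1],
           percentile_90 = qs[5],
           interquartile_range = qs[4] - qs[2],
           coefficient_of_variation = cov_,
           mean_absolute_deviation = mean(abs(v - mu)),
           robust_mean_absolute_deviation = rmad,
           histogram_energy = sum(p^2),
           histogram_entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
           enhancing_tumor_volume_30 = etv(0.30),
           enhancing_tumor_volume_40 = etv(0.40),
           enhancing_tumor_volume_70 = etv(0.70))
  stopifnot(length(out) == 19L)
  attr(out, "degenerate") <- degenerate
  out
}

# in-memory fixed-bin-number discretization used when the caller does not
# supply one (suppresses the constant-region warning; the flag system
# already records degeneracy)
discretize_local <- function(v, dm, inm, spacing, n_bins = 32) {
  lev <- array(NA_integer_, dm)
  lo <- min(v); hi <- max(v)
  if (hi == lo) lev[inm] <- 1L
  else lev[inm] <- pmin(1L + as.integer(floor(n_bins * (v - lo) / (hi - lo))),
                        as.integer(n_bins))
  new_discretized_volume(lev, n_bins, "fixed_bin_number",
                         list(n_bins = n_bins, i_min = lo, i_max = hi),
                         spacing)
}
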