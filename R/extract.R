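#' Full radiomic feature extraction for one patient
#'
#' Runs the complete per-patient extraction: shape features from the mask
#' resampled to cubic 1 mm, intensity and texture features from the volume
#' resampled to cubic 3 mm after the configured intensity normalization.
#' Each VOI (tumoral, peritumoral) yields exactly 180 features: 24 shape,
#' 19 intensity and 137 texture. Wavelet-filtered features are not computed.
#'
#' With `method = "fixed_bin_number"` the in-VOI intensity range is divided
#' into `n_bins` levels and both the intensity and texture features operate
#' on those levels (the binning is the normalization). With
#' `method = "linear_two_point"` the volume is first rescaled against the
#' white-matter and vitreous-body reference regions, intensity features use
#' the rescaled values, and texture features use a fixed bin width.
#'
#' @param grid post-contrast [voxel_grid()].
#' @param pre_grid optional pre-contrast `voxel_grid` (carried for
#'   provenance; pre-contrast subtraction happens upstream at segmentation
#'   via [subtract_precontrast()]).
#' @param masks named list of [voi_mask()]s: the VOIs to extract (any of
#'   `tumoral`, `peritumoral`) plus `wm_reference` and `vitreous_reference`
#'   when the linear method is used.
#' @param spec a [normalization_spec()].
#' @param shape_mm,texture_mm cubic resampling targets (defaults 1 and 3).
#' @return named list (one entry per VOI) of `feature_vector` objects:
#'   named numeric `values` of length 180, `family` tags, `voi` tag,
#'   `degenerate` flags and `provenance`.
#' @export
extract_all <- function(grid, pre_grid = NULL, masks, spec,
                        shape_mm = 1, texture_mm = 3) {
  stopifnot(inherits(spec, "normalization_spec"))
  vois <- intersect(c("tumoral", "peritumoral"), names(masks))
  if (length(vois) == 0L)
    stop("extract_all: no tumoral/peritumoral mask supplied")
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("extract_all [", what, "]: ", conditionMessage(e), call. = FALSE))
  }
  grid3 <- stage("resample-3mm", resample_trilinear(grid, texture_mm))
  if (spec$method == "linear_two_point") {
    if (is.null(masks$wm_reference) || is.null(masks$vitreous_reference))
      stop("extract_all: linear_two_point normalization needs wm_reference ",
           "and vitreous_reference masks")
    wm3 <- stage("resample-3mm", resample_mask_trilinear(masks$wm_reference,
                                                         texture_mm))
    vit3 <- stage("resample-3mm",
                  resample_mask_trilinear(masks$vitreous_reference, texture_mm))
    norm3 <- stage("normalize", normalize_linear_two_point(grid3, wm3, vit3,
                                                           spec))
  }
  out <- list()
  for (v in vois) {
    mk <- masks[[v]]
    mk1 <- stage("resample-1mm", resample_mask_trilinear(mk, shape_mm))
    shp <- stage("shape", compute_shape(mk1))
    mk3 <- stage("resample-3mm", resample_mask_trilinear(mk, texture_mm))
    if (spec$method == "fixed_bin_number") {
      dv <- stage("discretize", suppressWarnings(
        discretize_fixed_bin_number(grid3, mk3, spec$n_bins)))
      lv_arr <- dv$levels
      lv_arr[is.na(lv_arr)] <- 0L
      int_grid <- voxel_grid(lv_arr + 0, grid3$spacing, grid3$origin)
    } else {
      dv <- stage("discretize", discretize_fixed_bin_size(norm3, mk3,
                                                          spec$bin_size))
      int_grid <- norm3
    }
    intens <- stage("intensity", compute_intensity(int_grid, mk3, dv))
    tex <- stage("texture",
                 compute_texture_features(compute_texture_matrices(dv)))
    vals <- c(stats::setNames(as.numeric(shp), paste0("shape_", names(shp))),
              stats::setNames(as.numeric(intens),
                              paste0("intensity_", names(intens))),
              tex)
    fam <- c(rep("shape", length(shp)), rep("intensity", length(intens)),
             rep("texture", length(tex)))
    names(fam) <- names(vals)
    stopifnot(length(vals) == 180L)
    deg <- c(paste0("shape_", attr(shp, "degenerate")),
             paste0("intensity_", attr(intens, "degenerate")))
    out[[v]] <- structure(
      list(values = vals, family = fam, voi = v, degenerate = deg,
           provenance = list(method = spec$method, n_bins = spec$n_bins,
                             bin_size = spec$bin_size,
                             anchor_wm = spec$anchor_wm,
                             anchor_vitreous = spec$anchor_vitreous,
                             shape_mm = shape_mm, texture_mm = texture_mm,
                             G = dv$G)),
      class = "feature_vector")
  }
  out
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> voi=", x$voi, ", ", length(x$values), " features (",
      paste(sprintf("%s:%d", names(table(x$family)), table(x$family)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Published feature-name aliases
#'
#' Maps the long-form feature names used in the glioblastoma radiomics
#' literature to this package's column names.
#'
#' @return named character vector: alias -> internal feature name.
#' @export
feature_aliases <- function() {
  c("Neighborhood Gray Tone Difference Matrix busyness" = "ngtdm_busyness",
    "Neighborhood Gray Level Dependence Matrix low dependence emphasis" =
      "ngldm_low_dependence_emphasis",
    "Gray Level Size Zone Matrix zone size entropy" =
      "glszm_zone_size_entropy",
    "Gray Level Size Zone Matrix large zone low gray level emphasis" =
      "glszm_large_zone_low_grey_emphasis",
    "Gray Level Run Length Matrix long runs emphasis" =
      "glrlm_long_run_emphasis",
    "Gray Level Run Length Matrix run length variance" =
      "glrlm_run_length_variance",
    "kurtosis" = "intensity_kurtosis",
    "coefficient of variation" = "intensity_coefficient_of_variation",
    "histogram energy" = "intensity_histogram_energy",
    "enhancing tumor volume 30%" = "intensity_enhancing_tumor_volume_30",
    "enhancing tumor volume 40%" = "intensity_enhancing_tumor_volume_40",
    "enhancing tumor volume 70%" = "intensity_enhancing_tumor_volume_70",
    "minor axis" = "shape_minor_axis_length")
}

#' Stack per-patient feature vectors into a feature table
#'
#' @param fvs list of `feature_vector`s (same VOI), one per patient.
#' @param patient_ids character vector of row names.
#' @return a [feature_table()].
#' @export
bind_feature_vectors <- function(fvs, patient_ids) {
  stopifnot(length(fvs) == length(patient_ids))
  vals <- do.call(rbind, lapply(fvs, function(f) f$values))
  rownames(vals) <- patient_ids
  feature_table(vals, family = fvs[[1]]$family, voi = fvs[[1]]$voi,
                provenance = fvs[[1]]$provenance)
}
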