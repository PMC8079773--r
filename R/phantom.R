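#' Synthetic MR phantom with ground-truth regions
#'
#' Generates an aligned pre-/post-contrast pair of T1-like volumes plus the
#' region masks the pipeline needs: an ellipsoidal contrast-enhancing tumor
#' with a concentric necrotic core, a white-matter reference box, a
#' vitreous-body reference box and an optional resection-cavity-like
#' exclusion box. Geometry is restricted to axis-aligned boxes and ellipsoids
#' so that every mask has an analytic ground truth (volumes, distances) for
#' testing. The same spec and seed always reproduce bit-identical output.
#'
#' The enhancing rim (tumor minus necrotic core) is elevated above the
#' surrounding brain intensity by `rim_contrast` in the post-contrast volume
#' before noise; the necrotic core stays near cystic intensity in both
#' volumes. A scanner-dependent affine distortion `gain/offset` is applied to
#' both volumes (same scanner), with independent Gaussian noise per volume.
#'
#' @param grid_dim integer length-3, voxels per axis.
#' @param spacing mm per axis.
#' @param tumor_center_mm,tumor_semiaxes_mm ellipsoid centre and semi-axes in
#'   world mm.
#' @param necrotic_fraction fraction (0-1) of the tumor volume occupied by the
#'   concentric necrotic core.
#' @param rim_contrast enhancement of the viable tumor rim over brain tissue
#'   (intensity units, before noise).
#' @param wm_box_mm,vitreous_box_mm,exclusion_box_mm 2x3 matrices (rows =
#'   lo/hi mm per axis); `exclusion_box_mm = NULL` omits the cavity.
#' @param tissue_means named list of mean intensities for `background`,
#'   `brain`, `wm`, `vitreous`, `necrotic`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param gain,offset scanner affine intensity distortion.
#' @param seed integer seed.
#' @return `phantom_spec()` returns the validated spec; `generate_phantom()`
#'   returns `list(pre, post, masks)` where `masks` holds `tumoral`,
#'   `wm_reference`, `vitreous_reference` and (optionally) `exclusion`
#'   [voi_mask()]s, plus `necrotic_core` as a plain logical array attribute
#'   of the spec for ground-truth checks.
#' @export
phantom_spec <- function(grid_dim = c(96, 96, 40),
                         spacing = c(1, 1, 3),
                         tumor_center_mm = c(58, 48, 60),
                         tumor_semiaxes_mm = c(13.4, 13.4, 13.4),
                         necrotic_fraction = 0.3,
                         rim_contrast = 100,
                         wm_box_mm = rbind(c(12, 30, 45), c(32, 50, 75)),
                         vitreous_box_mm = rbind(c(40, 4, 50), c(54, 16, 66)),
                         exclusion_box_mm = rbind(c(70, 60, 45), c(88, 80, 75)),
                         tissue_means = list(background = 20, brain = 150,
                                             wm = 200, vitreous = 50,
                                             necrotic = 60),
                         noise_sd = 10,
                         gain = 1, offset = 0,
                         seed = 1L) {
  spec <- list(grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
               tumor_center_mm = as.numeric(tumor_center_mm),
               tumor_semiaxes_mm = as.numeric(tumor_semiaxes_mm),
               necrotic_fraction = necrotic_fraction,
               rim_contrast = rim_contrast,
               wm_box_mm = wm_box_mm, vitreous_box_mm = vitreous_box_mm,
               exclusion_box_mm = exclusion_box_mm,
               tissue_means = tissue_means, noise_sd = noise_sd,
               gain = gain, offset = offset, seed = as.integer(seed))
  if (any(spec$tumor_semiaxes_mm <= 0))
    stop("phantom_spec: tumor semi-axes must be > 0")
  if (spec$necrotic_fraction < 0 || spec$necrotic_fraction >= 1)
    stop("phantom_spec: necrotic_fraction must be in [0, 1)")
  if (spec$noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  if (length(spec$grid_dim) != 3L || any(spec$grid_dim < 2))
    stop("phantom_spec: grid_dim must be 3 values >= 2")
  class(spec) <- "phantom_spec"
  spec
}

# evaluate code with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

ellipsoid_mask_array <- function(grid_dim, spacing, center, semiaxes) {
  cx <- (seq_len(grid_dim[1]) - 1) * spacing[1]
  cy <- (seq_len(grid_dim[2]) - 1) * spacing[2]
  cz <- (seq_len(grid_dim[3]) - 1) * spacing[3]
  dx2 <- ((cx - center[1]) / semiaxes[1])^2
  dy2 <- ((cy - center[2]) / semiaxes[2])^2
  dz2 <- ((cz - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

box_mask_array <- function(grid_dim, spacing, box) {
  cx <- (seq_len(grid_dim[1]) - 1) * spacing[1]
  cy <- (seq_len(grid_dim[2]) - 1) * spacing[2]
  cz <- (seq_len(grid_dim[3]) - 1) * spacing[3]
  inx <- cx >= box[1, 1] & cx <= box[2, 1]
  iny <- cy >= box[1, 2] & cy <= box[2, 2]
  inz <- cz >= box[1, 3] & cz <= box[2, 3]
  outer(outer(inx, iny, `&`), inz, `&`)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gd <- spec$grid_dim; sp <- spec$spacing
  tumor <- ellipsoid_mask_array(gd, sp, spec$tumor_center_mm,
                                spec$tumor_semiaxes_mm)
  core <- if (spec$necrotic_fraction > 0)
    ellipsoid_mask_array(gd, sp, spec$tumor_center_mm,
                         spec$tumor_semiaxes_mm * spec$necrotic_fraction^(1 / 3))
  else array(FALSE, gd)
  wm <- box_mask_array(gd, sp, spec$wm_box_mm)
  vit <- box_mask_array(gd, sp, spec$vitreous_box_mm)
  excl <- if (!is.null(spec$exclusion_box_mm))
    box_mask_array(gd, sp, spec$exclusion_box_mm) else NULL

  rois <- list(tumoral = tumor, wm_reference = wm, vitreous_reference = vit)
  if (!is.null(excl)) rois$exclusion <- excl
  nm <- names(rois)
  for (i in seq_along(rois)) for (j in seq_len(i - 1L)) {
    if (any(rois[[i]] & rois[[j]]))
      stop("generate_phantom: ROIs overlap: ", nm[j], " and ", nm[i])
  }

  tm <- spec$tissue_means
  base <- array(tm$background, gd)
  # crude "head": brain everywhere except a background shell of 6 mm
  shell <- !box_mask_array(gd, sp, rbind(c(6, 6, 6) - 1e-9,
                                         (gd - 1) * sp - 6 + 1e-9))
  base[!shell] <- tm$brain
  base[wm] <- tm$wm
  base[vit] <- tm$vitreous
  if (!is.null(excl)) base[excl] <- tm$vitreous  # fluid-filled cavity
  base[tumor] <- tm$brain
  base[core] <- tm$necrotic

  post <- base
  post[tumor & !core] <- post[tumor & !core] + spec$rim_contrast

  vols <- with_seed(spec$seed, {
    n1 <- if (spec$noise_sd > 0)
      array(stats::rnorm(prod(gd), 0, spec$noise_sd), gd) else 0
    n2 <- if (spec$noise_sd > 0)
      array(stats::rnorm(prod(gd), 0, spec$noise_sd), gd) else 0
    list(pre = spec$gain * (base + n1) + spec$offset,
         post = spec$gain * (post + n2) + spec$offset)
  })

  masks <- list(
    tumoral = voi_mask(tumor + 0, sp, c(0, 0, 0), "tumoral"),
    wm_reference = voi_mask(wm + 0, sp, c(0, 0, 0), "wm_reference"),
    vitreous_reference = voi_mask(vit + 0, sp, c(0, 0, 0), "vitreous_reference")
  )
  if (!is.null(excl))
    masks$exclusion <- voi_mask(excl + 0, sp, c(0, 0, 0), "exclusion")

  list(pre = voxel_grid(vols$pre, sp, c(0, 0, 0)),
       post = voxel_grid(vols$post, sp, c(0, 0, 0)),
       masks = masks,
       necrotic_core = core)
}
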