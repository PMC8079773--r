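#' Voxel grids and volume-of-interest masks
#'
#' `voxel_grid()` wraps a 3D scalar intensity lattice together with its
#' per-axis voxel spacing (mm) and world origin (mm, the centre of voxel
#' `[1,1,1]`). It is the unit every image operation in the package consumes
#' and produces. `voi_mask()` wraps a binary lattice aligned to such a grid,
#' tagged with the role the region plays in the analysis.
#'
#' Only axis-aligned lattices are supported: obliquely oriented volumes must
#' be resampled externally before entering the pipeline.
#'
#' @param data 3D numeric array (grid) or 3D array coercible to 0/1 (mask).
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @param role one of `"tumoral"`, `"peritumoral"`, `"wm_reference"`,
#'   `"vitreous_reference"`, `"exclusion"`.
#'
#' @return An object of class `voxel_grid` or `voi_mask`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("voxel_grid: 'data' must be a 3D array, got ",
         paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_grid: 'spacing' must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("voxel_grid: 'origin' must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("voxel_grid: intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @export
voi_mask_roles <- function() {
  c("tumoral", "peritumoral", "wm_reference", "vitreous_reference", "exclusion")
}

#' @rdname voxel_grid
#' @export
voi_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     role = "tumoral") {
  role <- match.arg(role, voi_mask_roles())
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("voi_mask: 'data' must be a 3D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("voi_mask: mask is not binary; found values ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "))
  m <- array(as.integer(data != 0), dim = dim(data))
  if (sum(m) == 0L && role != "exclusion")
    stop("voi_mask: empty mask not allowed for role '", role, "'")
  g <- voxel_grid(array(0, dim = dim(data)), spacing, origin)  # validates geometry
  structure(list(data = m, spacing = g$spacing, origin = g$origin, role = role),
            class = "voi_mask")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> role=", x$role, ", ", sum(x$data), "/",
      length(x$data), " voxels set, spacing ",
      paste(signif(x$spacing, 4), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Grid alignment
#'
#' Two lattices are aligned when they have identical voxel counts and their
#' spacing and origin agree within `tol` mm (absorbs file-format float noise
#' while rejecting genuine mismatch). The check is symmetric.
#'
#' @param a,b `voxel_grid` or `voi_mask` objects.
#' @param tol alignment tolerance in mm.
#' @return `grids_aligned()` returns TRUE/FALSE; `check_aligned()` errors
#'   with a report of both geometries when not aligned.
#' @export
grids_aligned <- function(a, b, tol = 1e-3) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' @rdname grids_aligned
#' @export
check_aligned <- function(a, b, tol = 1e-3) {
  if (!grids_aligned(a, b, tol))
    stop("grids not aligned:\n  A: dim ", paste(dim(a$data), collapse = "x"),
         ", spacing ", paste(signif(a$spacing, 6), collapse = "/"),
         ", origin ", paste(signif(a$origin, 6), collapse = "/"),
         "\n  B: dim ", paste(dim(b$data), collapse = "x"),
         ", spacing ", paste(signif(b$spacing, 6), collapse = "/"),
         ", origin ", paste(signif(b$origin, 6), collapse = "/"))
  invisible(TRUE)
}

# voxel volume in mm^3
voxel_volume_mm3 <- function(x) prod(x$spacing)

# world coordinates (mm) of voxel centres along one axis
axis_coords <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$data)[axis]) - 1) * x$spacing[axis]
}
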