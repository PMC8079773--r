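#' Read and write NIfTI volumes
#'
#' Volumes are stored as scalar 3D NIfTI with an axis-aligned affine: voxel
#' spacing on the diagonal and the world coordinate of the first voxel centre
#' in the translation column. Oblique or axis-permuted orientations are
#' rejected with instruction to resample externally. Round trips preserve
#' intensities (float32-lossless), spacing and origin.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid a [voxel_grid()].
#' @return `read_volume()` returns a `voxel_grid`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # strip NIfTI attributes
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected a 3D volume, got ", length(dim(arr)),
         "D data in ", path)
  aff <- try(RNifti::xform(img), silent = TRUE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  origin <- c(0, 0, 0)
  if (!inherits(aff, "try-error") && is.matrix(aff)) {
    rot <- aff[1:3, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-4) || any(diag(rot) < 0))
      stop("read_volume: volume is not axis-aligned RAS+ (oblique or flipped ",
           "affine); resample/reorient externally before analysis: ", path)
    spacing <- diag(rot)
    origin <- aff[1:3, 4]
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("read_volume: invalid voxel spacing field in ", path, ": ",
         paste(spacing, collapse = "/"))
  voxel_grid(arr, spacing = spacing, origin = origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, c("voxel_grid", "voi_mask")))
  dat <- grid$data
  storage.mode(dat) <- if (inherits(grid, "voi_mask")) "integer" else "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask aligned to a reference grid
#'
#' @param path NIfTI file containing 0/1 data.
#' @param reference `voxel_grid` the mask must align with.
#' @param role region role, see [voi_mask()].
#' @param tol alignment tolerance in mm.
#' @return a [voi_mask()].
#' @export
read_mask <- function(path, reference, role, tol = 1e-3) {
  g <- read_volume(path)
  check_aligned(g, reference, tol)
  vals <- unique(as.vector(g$data))
  if (!all(vals %in% c(0, 1)))
    stop("read_mask: mask in ", path, " is not binary (found ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "), ")")
  voi_mask(g$data, spacing = reference$spacing, origin = reference$origin,
           role = role)
}

#' Read a per-patient clinical table
#'
#' Expects delimited text (comma or tab, auto-detected from the header line)
#' with columns `patient_id, mgmt, pfs2_months, pfs2_event, os_months,
#' os_event, cohort`. MGMT promoter methylation status is
#' `methylated`/`unmethylated`; an empty field, `NA` or `no data` (any case)
#' is parsed as `missing` and the record is kept — exclusion of
#' missing-status patients is a decision for the MGMT modelling branch, not
#' for the reader. Survival times are months since first progression.
#'
#' @param path delimited text file.
#' @return data.frame of class `clinical_table` with columns as above, `mgmt`
#'   a factor with levels methylated/unmethylated/missing and `cohort` a
#'   factor with levels training/validation.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("read_clinical: no such file: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("patient_id", "mgmt", "pfs2_months", "pfs2_event",
           "os_months", "os_event", "cohort")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_clinical: missing required column(s): ",
         paste(miss, collapse = ", "))
  as_clinical_table(df)
}

#' @rdname read_clinical
#' @param df data.frame with the clinical columns already in memory.
#' @export
as_clinical_table <- function(df) {
  n <- nrow(df)
  line_no <- function(i) i + 1L  # header is line 1 in the source file
  mgmt <- tolower(trimws(as.character(df$mgmt)))
  mgmt[is.na(mgmt) | mgmt %in% c("", "na", "no data", "missing")] <- "missing"
  bad <- which(!mgmt %in% c("methylated", "unmethylated", "missing"))
  if (length(bad))
    stop("read_clinical: line ", line_no(bad[1]), ": unknown MGMT status '",
         df$mgmt[bad[1]], "'")
  cohort <- tolower(trimws(as.character(df$cohort)))
  bad <- which(!cohort %in% c("training", "validation"))
  if (length(bad))
    stop("read_clinical: line ", line_no(bad[1]), ": unknown cohort label '",
         df$cohort[bad[1]], "' (expected training/validation)")
  for (tm in c("pfs2_months", "os_months")) {
    v <- suppressWarnings(as.numeric(df[[tm]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop("read_clinical: line ", line_no(bad[1]), ": invalid ", tm, " '",
           df[[tm]][bad[1]], "' (must be a non-negative number of months)")
    df[[tm]] <- v
  }
  for (ev in c("pfs2_event", "os_event")) {
    v <- df[[ev]]
    if (!all(v %in% c(0, 1, TRUE, FALSE)))
      stop("read_clinical: line ",
           line_no(which(!v %in% c(0, 1, TRUE, FALSE))[1]),
           ": event flag ", ev, " must be 0/1")
    df[[ev]] <- as.logical(v)
  }
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    mgmt = factor(mgmt, levels = c("methylated", "unmethylated", "missing")),
    pfs2_months = df$pfs2_months,
    pfs2_event = df$pfs2_event,
    os_months = df$os_months,
    os_event = df$os_event,
    cohort = factor(cohort, levels = c("training", "validation")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' @rdname read_clinical
#' @param x clinical table to write.
#' @export
write_clinical <- function(x, path) {
  df <- as.data.frame(x)
  df$pfs2_event <- as.integer(df$pfs2_event)
  df$os_event <- as.integer(df$os_event)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
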