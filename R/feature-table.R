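#' Feature tables
#'
#' A feature table is a patients-by-features numeric matrix with a family
#' tag per feature (shape/intensity/texture, or synthetic for simulated
#' cohorts), a VOI tag, and a provenance list recording how the features
#' were produced (normalization method, bin parameters).
#'
#' @param values numeric matrix, rows = patients (rownames = patient ids),
#'   columns = named features.
#' @param family character vector of per-feature family tags (recycled if
#'   length 1).
#' @param voi VOI tag (`"tumoral"`, `"peritumoral"`, or `"synthetic"`).
#' @param provenance list of extraction parameters.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, family = "synthetic", voi = "synthetic",
                          provenance = list()) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("feature_table: 'values' must have feature names as colnames")
  if (length(family) == 1L) family <- rep(family, ncol(values))
  if (length(family) != ncol(values))
    stop("feature_table: family tag length mismatch")
  names(family) <- colnames(values)
  structure(list(values = values, family = family, voi = voi,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " patients x ", ncol(x$values),
      " features (", paste(sprintf("%s:%d", names(table(x$family)),
                                   table(x$family)), collapse = ", "),
      "), voi=", x$voi, "\n", sep = "")
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @param path output CSV path; provenance is written as `# key: value`
#'   comment lines above the header.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(voi = x$voi), x$provenance)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  writeLines(paste0("# family: ", paste(x$family, collapse = ",")), con)
  df <- data.frame(patient_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", l)
    kv <- strsplit(kv, "\t")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = paste(lines[-meta_lines], collapse = "\n"),
                        check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$patient_id
  fam <- if (!is.null(meta$family))
    strsplit(meta$family, ",")[[1]] else rep("synthetic", ncol(vals))
  voi <- if (!is.null(meta$voi)) meta$voi else "synthetic"
  feature_table(vals, fam, voi,
                provenance = meta[setdiff(names(meta), c("family", "voi"))])
}
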