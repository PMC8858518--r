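#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with samples in rows and
#' genes in columns, both fully labelled. Any normalized expression measure
#' (normalized RNA-seq counts, proteomics intensities, ...) is acceptable;
#' only the rank structure within each gene is used downstream.
#'
#' Missing-value imputation is deliberately not supported: a missing or
#' non-finite entry aborts with the offending gene and sample named, so the
#' user can fix the input rather than silently propagate fabricated
#' correlations.
#'
#' @param x numeric matrix, samples x genes, with unique row (sample) and
#'   column (gene) names. At least 3 samples and 2 genes.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry sample names (rows) and gene names (columns)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(what, ": duplicated sample names: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(what, ": duplicated gene names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) < 3L) {
    stop(what, " needs at least 3 samples, got ", nrow(x), call. = FALSE)
  }
  if (ncol(x) < 2L) {
    stop(what, " needs at least 2 genes, got ", ncol(x), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    stop(what, ": missing or non-finite value for gene '",
         colnames(x)[bad[1L, 2L]], "' in sample '", rownames(x)[bad[1L, 1L]],
         "'; missing-value imputation is not supported", call. = FALSE)
  }
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers; the remaining cells must all parse as finite numbers.
#' Parsing is strict: an empty, NA, or non-numeric cell aborts with the
#' gene and sample of the first offending cell.
#'
#' @param path file path (TSV by default; pass `sep = ","` for CSV).
#' @param sep field separator. `NULL` picks `","` for a `.csv` extension
#'   and tab otherwise.
#' @param transpose set `TRUE` when the file stores genes as rows and
#'   samples as columns; the matrix is transposed after reading so the
#'   returned object is always samples x genes.
#' @return numeric matrix, samples x genes.
#' @export
read_expression <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  if (ncol(dt) < 2L) {
    stop("expression file must have an id column plus data columns: ", path,
         call. = FALSE)
  }
  row_ids <- dt[[1L]]
  col_ids <- colnames(dt)[-1L]
  raw <- as.matrix(dt[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    gene <- if (transpose) row_ids[i] else col_ids[j]
    samp <- if (transpose) col_ids[j] else row_ids[i]
    stop("non-numeric or missing cell ('", raw[i, j], "') for gene '", gene,
         "' in sample '", samp, "' of ", path,
         "; missing-value imputation is not supported", call. = FALSE)
  }
  rownames(vals) <- row_ids
  colnames(vals) <- col_ids
  if (transpose) vals <- t(vals)
  validate_expression(vals, what = path)
  vals
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: a header of gene names and a first
#' `sample` column of sample names.
#'
#' @param x samples x genes numeric matrix with dimnames.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  validate_expression(x)
  df <- data.frame(sample = rownames(x), x, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}
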