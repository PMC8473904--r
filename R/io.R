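#' Read an expression matrix
#'
#' Reads a TSV/CSV table (first column = identifier, header row present) or a
#' GCT 1.2 file and returns the matrix in the package's canonical orientation:
#' rows are samples, columns are genes. GCT stores genes in rows, so GCT input
#' is always transposed at load; for TSV/CSV the `orientation` flag states how
#' the file is laid out.
#'
#' Identifiers must be unique on both axes and every cell must be numeric.
#' Missing values are a hard error by default; `impute = "mean"` replaces
#' missing cells by the gene mean for foreign data sets known to have holes.
#'
#' @param path File to read.
#' @param orientation `"genes_in_rows"` or `"samples_in_rows"`; ignored for
#'   GCT (always genes in rows).
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"gct"`.
#' @param impute Missing-value policy: `"fail"` (default) or `"mean"`.
#' @return A numeric matrix, samples x genes, with dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows",
                                            "samples_in_rows"),
                            format = c("auto", "tsv", "csv", "gct"),
                            impute = c("fail", "mean")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", gct = "gct", "tsv")
  }
  if (format == "gct") {
    mat <- read_gct(path)           # genes x samples
    mat <- t(mat)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    ids <- as.character(df[[1L]])
    body <- df[, -1L, drop = FALSE]
    mat <- validate_numeric_body(body, ids, path)
    if (orientation == "genes_in_rows") mat <- t(mat)
  }
  finalize_expression(mat, impute)
}

read_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^#1\\.2", lines[1L]))
    stop("malformed GCT header: first line must be '#1.2'", call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || any(is.na(dims[1:2])))
    stop("malformed GCT header: second line must give dimensions",
         call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 3L)
    stop("GCT body must have Name, Description and data columns",
         call. = FALSE)
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
    stop(sprintf(
      "GCT dimensions line (%d x %d) disagrees with body (%d x %d)",
      dims[1L], dims[2L], nrow(df), ncol(df) - 2L), call. = FALSE)
  ids <- as.character(df[[1L]])
  body <- df[, -(1:2), drop = FALSE]   # drop Description
  validate_numeric_body(body, ids, path)
}

validate_numeric_body <- function(body, row_ids, path) {
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(body)[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(row_ids))
    stop("duplicate row identifiers in ", path, call. = FALSE)
  if (anyDuplicated(names(body)))
    stop("duplicate column identifiers in ", path, call. = FALSE)
  mat <- as.matrix(body)
  storage.mode(mat) <- "double"
  rownames(mat) <- row_ids
  mat
}

finalize_expression <- function(mat, impute = "fail") {
  if (anyNA(mat)) {
    if (impute == "fail")
      stop("expression matrix contains missing values ",
           "(set impute = \"mean\" to mean-impute)", call. = FALSE)
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (any(miss)) mat[miss, j] <- mean(mat[, j], na.rm = TRUE)
    }
    if (anyNA(mat)) stop("gene(s) with all values missing", call. = FALSE)
  }
  validate_expression_matrix(mat)
  mat
}

validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs sample (row) and gene (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate gene identifiers", call. = FALSE)
  if (anyNA(mat)) stop("expression matrix contains missing values",
                       call. = FALSE)
  invisible(mat)
}

#' Write an expression matrix as TSV
#'
#' Writes samples in rows with a `sample_id` identifier column, at full
#' double precision so a write/read round trip preserves values to better
#' than 1e-12.
#'
#' @param mat Samples x genes numeric matrix.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(sample_id = rownames(mat),
                   signif(mat, 17), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample x drug response table
#'
#' Rows are samples, columns are drugs, blank cells are missing. Values are
#' ActArea (area above the fitted dose-response curve), which is non-negative
#' by construction; negative entries are rejected.
#'
#' @param path TSV or CSV file; first column = sample identifier.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return Numeric matrix (samples x drugs) possibly containing `NA`.
#' @export
read_drug_response <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("", "NA"))
  ids <- as.character(df[[1L]])
  mat <- validate_numeric_body(df[, -1L, drop = FALSE], ids, path)
  if (any(mat < 0, na.rm = TRUE))
    stop("ActArea values must be non-negative", call. = FALSE)
  mat
}

#' Write a drug-response table as TSV (blank cells = missing)
#' @param mat Samples x drugs numeric matrix, `NA` allowed.
#' @param path Output path.
#' @export
write_drug_response <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Check that a drug table's samples are covered by an expression matrix
#'
#' @param drugs Samples x drugs matrix.
#' @param expr Samples x genes matrix.
#' @return Character vector of drug-table sample ids absent from `expr`
#'   (length 0 when the subset relation holds).
#' @export
drug_samples_missing <- function(drugs, expr) {
  setdiff(rownames(drugs), rownames(expr))
}

#' Remove listed samples from an expression matrix
#'
#' Used to drop curated-out samples (e.g. cell lines excluded after manual
#' review) before re-clustering. Unknown identifiers are an error so typos in
#' an exclusion list never silently pass.
#'
#' @param mat Samples x genes matrix.
#' @param exclusion_list Character vector of sample ids to drop.
#' @return The matrix without the excluded rows; gene axis and remaining
#'   sample order unchanged.
#' @export
exclude_samples <- function(mat, exclusion_list) {
  validate_expression_matrix(mat)
  exclusion_list <- unique(as.character(exclusion_list))
  unknown <- setdiff(exclusion_list, rownames(mat))
  if (length(unknown))
    stop("exclusion list contains unknown sample id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mat[!(rownames(mat) %in% exclusion_list), , drop = FALSE]
}
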