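# Delimited-text matrix I/O. All interchange is plain tab-delimited text
# with one header row and row labels in the first column; binary imaging
# formats are intentionally out of scope.

#' Read a labeled numeric matrix from tab-delimited text
#'
#' Strict parser: a header row is required, row and column labels must be
#' unique, every cell must parse as a number, and all rows must have the
#' same number of fields. Errors name the offending line or label.
#'
#' @param path file path.
#' @param expected_axes optional c(rows, cols) to validate against.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, expected_axes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  col_ids <- header[-1]
  if (anyDuplicated(col_ids))
    stop("duplicate column label(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "),
         call. = FALSE)
  body <- fields[-1]
  bad_len <- which(lengths(body) != ncol_expected)
  if (length(bad_len))
    stop("ragged row at line ", bad_len[1] + 1L, " of ", path, call. = FALSE)
  row_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids))
    stop("duplicate row label(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  num <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(ncol_expected - 1L))
  num <- t(matrix(num, nrow = ncol_expected - 1L))
  bad_cell <- which(is.na(num) , arr.ind = TRUE)
  if (nrow(bad_cell))
    stop("non-numeric cell at line ", bad_cell[1, 1] + 1L, ", column ",
         col_ids[bad_cell[1, 2]], " of ", path, call. = FALSE)
  dimnames(num) <- list(row_ids, col_ids)
  if (!is.null(expected_axes) &&
      !identical(dim(num), as.integer(expected_axes)))
    stop("expected a ", expected_axes[1], " x ", expected_axes[2],
         " matrix, found ", nrow(num), " x ", ncol(num), call. = FALSE)
  num
}

#' Write a labeled numeric matrix to tab-delimited text
#'
#' Full double precision (round-trips bit-identically through
#' [read_matrix()] for finite doubles).
#'
#' @param x numeric matrix.
#' @param path output file path.
#' @param row_label header name of the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, row_label = "id") {
  x <- as.matrix(x)
  rid <- rownames(x); cid <- colnames(x)
  if (is.null(rid)) rid <- sprintf("row%04d", seq_len(nrow(x)))
  if (is.null(cid)) cid <- sprintf("col%04d", seq_len(ncol(x)))
  header <- paste(c(row_label, cid), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rid[i], sprintf("%.17g", x[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-column parcel-vector file
#'
#' @param path tab-delimited file with columns (parcel_id, value) and a
#'   header row.
#' @return named numeric vector.
#' @export
read_parcel_vector <- function(path) {
  m <- utils::read.delim(path, header = TRUE, colClasses = c("character", "numeric"))
  if (ncol(m) != 2L) stop("expected two columns in ", path, call. = FALSE)
  stats::setNames(m[[2]], m[[1]])
}
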