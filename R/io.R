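#' Read a delimited matrix with a declared orientation
#'
#' The canonical on-disk format is delimited text with a first column of row
#' IDs and a header row whose first field labels the row-ID column (e.g.
#' `id`) and whose remaining fields are the column IDs. The orientation is declared, never
#' guessed, so a transposed file fails validation instead of silently fitting
#' a transposed model. Validation applies the target type's invariants:
#' non-negativity for `genes_x_samples` (bulk), simplex columns (with
#' abundance renormalization) and full row rank for `celltypes_x_samples`
#' (proportions), finiteness for `genes_x_celltypes` (signature).
#'
#' @param path file to read.
#' @param orientation one of `"genes_x_samples"`, `"celltypes_x_samples"`,
#'   `"genes_x_celltypes"`.
#' @param delimiter field separator (default tab).
#' @return the validated matrix (see [bulk_matrix()], [proportion_matrix()],
#'   [signature_matrix()]).
#' @export
read_matrix <- function(path,
                        orientation = c("genes_x_samples",
                                        "celltypes_x_samples",
                                        "genes_x_celltypes"),
                        delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("parse error in ", path, ": need a header line and at least one ",
         "data row", call. = FALSE)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  header <- cells[[1L]]
  # first header field labels the row-ID column; the rest are column IDs
  if (length(header) < 2L)
    stop("parse error in ", path, ": header must hold a row-ID label ",
         "followed by at least one column ID", call. = FALSE)
  col_ids <- header[-1L]
  n_cols <- length(col_ids)
  row_ids <- character(length(cells) - 1L)
  values <- matrix(NA_real_, length(cells) - 1L, n_cols)
  for (i in seq_along(cells)[-1L]) {
    row <- cells[[i]]
    if (length(row) != n_cols + 1L)
      stop("parse error in ", path, ", line ", i, ": expected ",
           n_cols + 1L, " fields, found ", length(row), call. = FALSE)
    row_ids[i - 1L] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(v) & !(toupper(row[-1L]) %in% c("NA", "NAN")))
    if (length(bad))
      stop("parse error in ", path, ", line ", i, ", column '",
           col_ids[bad[1L]], "': non-numeric value '", row[bad[1L] + 1L],
           "'", call. = FALSE)
    values[i - 1L, ] <- v
  }
  switch(orientation,
         genes_x_samples = bulk_matrix(values, row_ids, col_ids),
         celltypes_x_samples = proportion_matrix(values, row_ids, col_ids),
         genes_x_celltypes = signature_matrix(values, row_ids, col_ids))
}

#' Write a matrix as delimited text
#'
#' Row and column order are preserved; values are written with 17 significant
#' digits, so a write/read round trip reproduces the doubles bit-for-bit.
#'
#' @param m numeric matrix with row and column names.
#' @param path destination file.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = "\t") {
  m <- as.matrix(m)
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("cannot write an empty matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column names", call. = FALSE)
  check_ids(rownames(m), "row")
  check_ids(colnames(m), "column")
  body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  lines <- c(paste(c("id", colnames(m)), collapse = delimiter),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], body[i, ]), collapse = delimiter),
               character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Key = value sidecar describing how an output was produced.
write_metadata <- function(path, fields) {
  lines <- vapply(names(fields), function(k)
    paste0(k, " = ", paste(fields[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
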