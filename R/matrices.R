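#' Construct and validate a bulk expression matrix
#'
#' A bulk matrix holds non-negative normalized expression values (e.g. TMM,
#' TPM or RMA) with genes as rows and samples as columns. The object is a
#' plain numeric matrix with (unique) gene row names and sample column names;
#' this function validates those invariants and attaches no class.
#'
#' @param values numeric matrix, genes x samples. Row and column names are
#'   taken from `gene_ids` / `sample_ids` if given, otherwise from the
#'   matrix's own dimnames.
#' @param gene_ids,sample_ids optional character vectors of identifiers.
#' @return the validated genes x samples matrix.
#' @export
#' @examples
#' E <- bulk_matrix(matrix(1:6, 3, 2), gene_ids = paste0("g", 1:3),
#'                  sample_ids = c("s1", "s2"))
bulk_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  check_ids(rownames(values), "gene")
  check_ids(colnames(values), "sample")
  if (nrow(values) < 1L)
    stop("a bulk matrix needs at least one gene", call. = FALSE)
  if (ncol(values) < 2L)
    stop("a bulk matrix needs at least two samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("bulk matrix contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("bulk matrix contains negative values; expression must be >= 0",
         call. = FALSE)
  values
}

#' Construct and validate a cell type proportion matrix
#'
#' Proportions are cell types x samples with every column on the unit simplex.
#' Columns that are non-negative but do not sum to 1 (cell type *abundances*)
#' are renormalized with a warning; any negative entry is an error. The rows
#' must be linearly independent across samples (full row rank), otherwise the
#' mixing model is not identifiable.
#'
#' @param values numeric matrix, cell types x samples.
#' @param celltype_ids,sample_ids optional identifier vectors.
#' @param tol tolerance on column sums before renormalization kicks in.
#' @return the validated cell types x samples matrix, columns summing to 1.
#' @export
proportion_matrix <- function(values, celltype_ids = rownames(values),
                              sample_ids = colnames(values), tol = 1e-6) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(celltype_ids)) celltype_ids <- paste0("celltype_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(celltype_ids), as.character(sample_ids))
  check_ids(rownames(values), "cell type")
  check_ids(colnames(values), "sample")
  if (!all(is.finite(values)))
    stop("proportion matrix contains non-finite values", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("proportion matrix has negative entries, e.g. cell type '",
         rownames(values)[neg[1, 1]], "', sample '",
         colnames(values)[neg[1, 2]], "'", call. = FALSE)
  sums <- colSums(values)
  if (any(sums <= 0))
    stop("proportion matrix column(s) sum to zero: ",
         paste(colnames(values)[sums <= 0], collapse = ", "), call. = FALSE)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    warning(sum(off), " column(s) do not sum to 1 (max sum ",
            format(max(sums), digits = 4),
            "); treating values as abundances and renormalizing",
            call. = FALSE)
    values <- sweep(values, 2, sums, "/")
  }
  # with fewer samples than cell types the system is underdetermined, which
  # the estimators report themselves; the rank check targets collinear rows
  if (ncol(values) >= nrow(values) && qr(t(values))$rank < nrow(values))
    stop("proportion matrix is not of full row rank: some cell type is a ",
         "linear combination of the others across samples", call. = FALSE)
  values
}

#' Construct a signature matrix (genes x cell types)
#'
#' One column per cell type-specific expression profile (csGEP). Rodeo and
#' NNLS estimates are non-negative; unconstrained least-squares estimates may
#' contain negative entries, so non-negativity is not enforced here.
#'
#' @param values numeric matrix, genes x cell types.
#' @param gene_ids,celltype_ids optional identifier vectors.
#' @return the validated genes x cell types matrix.
#' @export
signature_matrix <- function(values, gene_ids = rownames(values),
                             celltype_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(celltype_ids)) celltype_ids <- paste0("celltype_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(gene_ids), as.character(celltype_ids))
  check_ids(rownames(values), "gene")
  check_ids(colnames(values), "cell type")
  if (nrow(values) < 1L)
    stop("a signature matrix needs at least one gene", call. = FALSE)
  if (!all(is.finite(values)))
    stop("signature matrix contains non-finite values", call. = FALSE)
  values
}

check_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("missing or empty ", what, " identifiers", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated ", what, " identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  invisible(ids)
}

# Reorder the columns of C to match the sample order of E; the two must carry
# the same sample-ID set.
align_samples <- function(E, C) {
  miss_e <- setdiff(colnames(E), colnames(C))
  miss_c <- setdiff(colnames(C), colnames(E))
  if (length(miss_e) || length(miss_c))
    stop("sample IDs of the bulk and proportion matrices do not match",
         if (length(miss_e)) paste0("; missing from proportions: ",
                                    paste(miss_e, collapse = ", ")),
         if (length(miss_c)) paste0("; missing from bulk: ",
                                    paste(miss_c, collapse = ", ")),
         call. = FALSE)
  C[, colnames(E), drop = FALSE]
}
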