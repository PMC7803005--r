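#' Robust expression deconvolution (Rodeo)
#'
#' Estimates the signature matrix S (genes x cell types) from bulk expression
#' E and known cell type proportions C under the linear mixing model
#' `E = S %*% C`. Each gene is fitted independently by a no-intercept robust
#' linear regression (Huber M-estimation, see [fit_huber()]). Whenever the fit
#' assigns a negative coefficient to some cell types, those cell types are
#' excluded (their expression is fixed at 0) and the model is refitted on the
#' remaining ones, until all coefficients left in the model are non-negative.
#' Excluding rather than merely clipping negative coefficients prevents the
#' other cell types' estimates from being inflated in compensation, and the
#' per-observation Huber weights keep a few outlier samples from biasing the
#' profiles.
#'
#' @param E bulk matrix, genes x samples (see [bulk_matrix()]).
#' @param C proportion matrix, cell types x samples (see
#'   [proportion_matrix()]); sample IDs must match those of `E` (any order).
#' @param config a [huber_config()].
#' @return an object of class `deconv_result`: a list with `signature`
#'   (genes x cell types, non-negative), `excluded` (logical genes x cell
#'   types, `TRUE` where a cell type was forced to 0), `converged` (logical
#'   per gene), `weights` (genes x samples final IRLS sample weights) and
#'   `method` (`"rodeo"`).
#' @seealso [ols_deconv()], [nnls_deconv()] for the least-squares baselines.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 50, n_samples = 30, seed = 1))
#' res <- rodeo(ds$E, ds$C)
#' round(res$signature[1:3, ], 1)
rodeo <- function(E, C, config = huber_config()) {
  config <- as_huber_config(config)
  E <- bulk_matrix(E)
  C <- proportion_matrix(C)
  C <- align_samples(E, C)
  if (ncol(E) < nrow(C))
    stop("underdetermined system: ", ncol(E), " samples for ", nrow(C),
         " cell types", call. = FALSE)
  out <- .rodeo_genes_cpp(E, t(C), config$k, config$max_iter, config$tol,
                          config$scale_floor)
  S <- out$signature
  dimnames(S) <- list(rownames(E), rownames(C))
  excluded <- matrix(as.logical(out$excluded), nrow(E), nrow(C),
                     dimnames = dimnames(S))
  weights <- out$weights
  dimnames(weights) <- dimnames(E)
  new_deconv_result(S, excluded = excluded,
                    converged = stats::setNames(out$converged, rownames(E)),
                    weights = weights, method = "rodeo")
}

#' Rodeo fit for a single gene
#'
#' The per-gene step of [rodeo()]: a Huber IRLS fit of one bulk expression row
#' on the transposed proportions, with iterative exclusion of cell types that
#' receive negative coefficients. Exposed for inspection and testing; for
#' whole matrices use [rodeo()].
#'
#' @param bulk_row numeric vector of one gene's bulk expression, one entry per
#'   sample (same order as the columns of `C`).
#' @param C proportion matrix, cell types x samples.
#' @param config a [huber_config()].
#' @return a list: `signature_row` (non-negative, one entry per cell type),
#'   `excluded` (character vector of excluded cell type IDs), `converged`,
#'   `weights` (final sample weights).
#' @export
rodeo_fit_gene <- function(bulk_row, C, config = huber_config()) {
  config <- as_huber_config(config)
  C <- proportion_matrix(C)
  bulk_row <- as.numeric(bulk_row)
  if (length(bulk_row) != ncol(C))
    stop("bulk_row length must equal the number of samples in C",
         call. = FALSE)
  if (ncol(C) < nrow(C))
    stop("underdetermined system: ", ncol(C), " samples for ", nrow(C),
         " cell types", call. = FALSE)
  out <- .rodeo_genes_cpp(matrix(bulk_row, nrow = 1), t(C), config$k,
                          config$max_iter, config$tol, config$scale_floor)
  excl <- as.logical(out$excluded[1, ])
  list(signature_row = stats::setNames(as.numeric(out$signature[1, ]),
                                       rownames(C)),
       excluded = rownames(C)[excl],
       converged = as.logical(out$converged[1]),
       weights = stats::setNames(as.numeric(out$weights[1, ]), colnames(C)))
}

#' Ordinary least-squares expression deconvolution
#'
#' Per-gene unconstrained least squares of the bulk expression on the
#' transposed proportions (the classical `cs-lsfit`-style baseline). The
#' estimate may contain negative expression values; `clip_negative = TRUE`
#' sets them to 0 after fitting, without refitting.
#'
#' @inheritParams rodeo
#' @param clip_negative set negative entries of the estimate to 0.
#' @return a `deconv_result` (no sample weights; `excluded` marks clipped
#'   entries when `clip_negative = TRUE`).
#' @export
ols_deconv <- function(E, C, clip_negative = FALSE) {
  E <- bulk_matrix(E)
  C <- proportion_matrix(C)
  C <- align_samples(E, C)
  if (ncol(E) < nrow(C))
    stop("underdetermined system: ", ncol(E), " samples for ", nrow(C),
         " cell types", call. = FALSE)
  X <- t(C)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient; collinear predictor(s): ",
         paste(colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]],
               collapse = ", "), call. = FALSE)
  S <- t(qr.coef(qx, t(E)))          # one QR, all genes at once
  dimnames(S) <- list(rownames(E), rownames(C))
  excluded <- matrix(FALSE, nrow(S), ncol(S), dimnames = dimnames(S))
  if (clip_negative) {
    excluded <- S < 0
    S[excluded] <- 0
  }
  new_deconv_result(S, excluded = excluded,
                    converged = stats::setNames(rep(TRUE, nrow(E)),
                                                rownames(E)),
                    weights = NULL,
                    method = if (clip_negative) "ols_clipped" else "ols")
}

#' Non-negative least-squares expression deconvolution
#'
#' Per-gene minimizer of `||bulk_row - t(C) %*% s||^2` subject to `s >= 0`
#' (the quadratic-programming-style baseline), solved by the Lawson-Hanson
#' active-set algorithm.
#'
#' @inheritParams rodeo
#' @return a `deconv_result`; `excluded` marks cell types whose constraint is
#'   active (estimate exactly 0).
#' @export
nnls_deconv <- function(E, C) {
  E <- bulk_matrix(E)
  C <- proportion_matrix(C)
  C <- align_samples(E, C)
  if (ncol(E) < nrow(C))
    stop("underdetermined system: ", ncol(E), " samples for ", nrow(C),
         " cell types", call. = FALSE)
  X <- t(C)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  S <- t(apply(E, 1L, function(y) pracma::lsqnonneg(X, y)$x))
  if (nrow(E) == 1L) S <- matrix(S, nrow = 1L)
  dimnames(S) <- list(rownames(E), rownames(C))
  excluded <- S == 0
  new_deconv_result(S, excluded = excluded,
                    converged = stats::setNames(rep(TRUE, nrow(E)),
                                                rownames(E)),
                    weights = NULL, method = "nnls")
}

new_deconv_result <- function(signature, excluded, converged, weights,
                              method) {
  structure(list(signature = signature, excluded = excluded,
                 converged = converged, weights = weights, method = method),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("Expression deconvolution result (", x$method, ")\n", sep = "")
  cat("  signature:", nrow(x$signature), "genes x", ncol(x$signature),
      "cell types\n")
  cat("  genes with excluded cell types:", sum(rowSums(x$excluded) > 0), "\n")
  if (!all(x$converged))
    cat("  genes not converged:", sum(!x$converged), "\n")
  invisible(x)
}

# Map a method name to an estimator function(E, C) -> deconv_result.
# All three estimators are supervised (consume C).
get_estimator <- function(method) {
  switch(match.arg(method, c("rodeo", "ols", "nnls")),
         rodeo = function(E, C) rodeo(E, C),
         ols = function(E, C) ols_deconv(E, C),
         nnls = function(E, C) nnls_deconv(E, C))
}
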