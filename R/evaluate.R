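#' Correlations between known and estimated cell type profiles
#'
#' Pearson correlation, over genes, between every known csGEP (column of the
#' true signature) and every estimated csGEP — the full cross matrix, rows =
#' known, columns = estimated. A good estimate has high diagonal values and
#' lower off-diagonal ones (though related cell types correlate even in
#' truth). Matrices are aligned on their common gene IDs; a column with zero
#' variance yields undefined (NA) correlations, flagged rather than an error.
#'
#' @param S_true,S_est signature matrices (genes x cell types); gene IDs must
#'   overlap in at least 3 genes. The cell type sets need not match.
#' @param method_name label stored in the report.
#' @return an `eval_report` with `celltype_corr` (known x estimated matrix),
#'   `diag_corr` (named vector, for the cell types present in both), and
#'   `metric_name = "pearson"`.
#' @export
celltype_correlations <- function(S_true, S_est, method_name = "") {
  al <- align_genes(S_true, S_est)
  cc <- suppressWarnings(stats::cor(al$S_true, al$S_est))
  shared <- intersect(colnames(al$S_true), colnames(al$S_est))
  diag_corr <- stats::setNames(cc[cbind(shared, shared)], shared)
  new_eval_report(metric_name = "pearson", method_name = method_name,
                  celltype_corr = cc, diag_corr = diag_corr)
}

#' Per-gene correlations between known and estimated profiles
#'
#' For each gene, the Pearson correlation between its true and estimated
#' expression across cell types; the median over genes summarizes how well
#' relative expression patterns are recovered. Genes whose true or estimated
#' row is constant have an undefined correlation: they are excluded from the
#' median and counted.
#'
#' @param S_true,S_est signature matrices with identical cell type sets
#'   (aligned by ID) and >= 3 cell types; genes aligned on common IDs.
#' @param method_name label stored in the report.
#' @return an `eval_report` with `gene_corr` (named vector, NA where
#'   undefined), `gene_corr_median` and `n_undefined`.
#' @export
gene_correlations <- function(S_true, S_est, method_name = "") {
  al <- align_genes(S_true, S_est)
  if (!setequal(colnames(al$S_true), colnames(al$S_est)))
    stop("cell type sets of the two signature matrices do not match: ",
         paste(union(setdiff(colnames(al$S_true), colnames(al$S_est)),
                     setdiff(colnames(al$S_est), colnames(al$S_true))),
               collapse = ", "), call. = FALSE)
  Se <- al$S_est[, colnames(al$S_true), drop = FALSE]
  St <- al$S_true
  if (ncol(St) < 3L)
    stop("per-gene correlations need at least 3 cell types", call. = FALSE)
  gc <- row_cor(St, Se)
  names(gc) <- rownames(St)
  defined <- gc[!is.na(gc)]
  new_eval_report(metric_name = "pearson", method_name = method_name,
                  gene_corr = gc,
                  gene_corr_median = if (length(defined))
                    stats::median(defined) else NA_real_,
                  n_undefined = sum(is.na(gc)))
}

# Rowwise Pearson correlation between two matrices of equal shape; NA for
# constant rows. Vectorized (no per-gene cor() calls).
row_cor <- function(A, B) {
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  num <- rowSums(Ac * Bc)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Accuracy of an estimated signature under a chosen metric
#'
#' Dispatches on `metric`: `"pearson"` combines [celltype_correlations()] and
#' [gene_correlations()] into one report; `"rmse"` and `"euclidean"` compute,
#' per cell type, the root-mean-square error or Euclidean distance between the
#' true and estimated csGEP (lower is better; `rmse = euclidean /
#' sqrt(n_genes)`).
#'
#' @param S_true,S_est aligned signature matrices (same cell type set).
#' @param metric one of `"pearson"`, `"rmse"`, `"euclidean"`.
#' @param method_name label stored in the report.
#' @return an `eval_report`; for the distance metrics, `per_celltype` holds
#'   the named per-csGEP values.
#' @export
accuracy_metric <- function(S_true, S_est,
                            metric = c("pearson", "rmse", "euclidean"),
                            method_name = "") {
  metric <- match.arg(metric)
  if (metric == "pearson") {
    ct <- celltype_correlations(S_true, S_est, method_name)
    gn <- gene_correlations(S_true, S_est, method_name)
    return(new_eval_report(metric_name = "pearson",
                           method_name = method_name,
                           celltype_corr = ct$celltype_corr,
                           diag_corr = ct$diag_corr,
                           gene_corr = gn$gene_corr,
                           gene_corr_median = gn$gene_corr_median,
                           n_undefined = gn$n_undefined))
  }
  al <- align_genes(S_true, S_est, min_genes = 1L)
  if (!setequal(colnames(al$S_true), colnames(al$S_est)))
    stop("cell type sets of the two signature matrices do not match",
         call. = FALSE)
  Se <- al$S_est[, colnames(al$S_true), drop = FALSE]
  d2 <- colSums((al$S_true - Se)^2)
  per <- if (metric == "euclidean") sqrt(d2) else sqrt(d2 / nrow(al$S_true))
  new_eval_report(metric_name = metric, method_name = method_name,
                  per_celltype = per)
}

# Correlations need >= 3 genes to be meaningful; distance metrics work from
# one gene up.
align_genes <- function(S_true, S_est, min_genes = 3L) {
  S_true <- signature_matrix(S_true)
  S_est <- signature_matrix(S_est)
  shared <- intersect(rownames(S_true), rownames(S_est))
  if (length(shared) < min_genes)
    stop("fewer than ", min_genes,
         " overlapping genes between the signature matrices", call. = FALSE)
  list(S_true = S_true[shared, , drop = FALSE],
       S_est = S_est[shared, , drop = FALSE])
}

new_eval_report <- function(...) {
  structure(list(...), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Deconvolution accuracy report (", x$metric_name,
      if (nzchar(x$method_name %||% "")) paste0(", ", x$method_name),
      ")\n", sep = "")
  if (!is.null(x$diag_corr)) {
    cat("  csGEP correlations (diagonal):\n")
    print(round(x$diag_corr, 3))
  }
  if (!is.null(x$per_celltype)) {
    cat("  per-csGEP ", x$metric_name, ":\n", sep = "")
    print(signif(x$per_celltype, 4))
  }
  if (!is.null(x$gene_corr_median))
    cat("  median per-gene correlation:", round(x$gene_corr_median, 4),
        " (undefined:", x$n_undefined, ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Diagonal csGEP correlations and median gene correlation of one estimate
# against the ground truth. The workhorse of both sweeps.
score_estimate <- function(truth_S, S_est) {
  ct <- celltype_correlations(truth_S, S_est)
  gn <- gene_correlations(truth_S, S_est)
  list(diag_corr = ct$diag_corr, gene_corr_median = gn$gene_corr_median)
}

#' Benchmark accuracy against sample size
#'
#' For each sample size and replicate, obtains a dataset of that size (by
#' default a fresh simulation seeded at `base_seed + replicate`; alternatively
#' by subsampling the columns of one fixed pool), runs the chosen estimator
#' with the known proportions, and scores the estimate against the ground
#' truth. Per size, the medians over replicates of the diagonal csGEP
#' correlations and of the median per-gene correlation are reported. Sizes
#' smaller than the number of cell types are skipped with a warning.
#'
#' @param config a [sim_config()]; in `"subsample"` mode its `n_samples` is
#'   the pool size.
#' @param method one of `"rodeo"`, `"ols"`, `"nnls"`.
#' @param sizes integer vector of sample sizes.
#' @param n_replicates replicates per size.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param mode `"fresh"` simulates a new dataset per replicate; `"subsample"`
#'   draws samples without replacement from one pool dataset.
#' @return a `sweep_result`: `axis_name = "sample_size"`, `axis_values`,
#'   `per_celltype_median` (cell types x sizes), `gene_corr_median`,
#'   `n_replicates`, `seeds`.
#' @export
sample_size_sweep <- function(config, method = "rodeo", sizes,
                              n_replicates = 10L, base_seed = 1L,
                              mode = c("fresh", "subsample")) {
  config <- as_sim_config(config)
  mode <- match.arg(mode)
  estimator <- get_estimator(method)
  stopifnot(n_replicates >= 1)
  n_types <- length(config$celltype_ids)
  keep <- sizes >= n_types
  if (any(!keep)) {
    warning("skipping sample size(s) below the number of cell types (",
            n_types, "): ", paste(sizes[!keep], collapse = ", "),
            call. = FALSE)
    sizes <- sizes[keep]
  }
  if (!length(sizes)) stop("no usable sample sizes", call. = FALSE)
  pool <- if (mode == "subsample") simulate_dataset(config)
  seeds <- base_seed + seq_len(n_replicates)

  per_ct <- matrix(NA_real_, n_types, length(sizes),
                   dimnames = list(config$celltype_ids, sizes))
  gene_med <- stats::setNames(numeric(length(sizes)), sizes)
  for (i in seq_along(sizes)) {
    scores <- lapply(seeds, function(s) {
      if (mode == "fresh") {
        cfg <- config
        cfg$n_samples <- as.integer(sizes[i])
        cfg$seed <- as.integer(s)
        ds <- simulate_dataset(cfg)
      } else {
        idx <- with_seed(s, sample(ncol(pool$E), sizes[i]))
        ds <- list(truth_S = pool$truth_S,
                   E = pool$E[, idx, drop = FALSE],
                   C = pool$C[, idx, drop = FALSE])
      }
      score_estimate(ds$truth_S, estimator(ds$E, ds$C)$signature)
    })
    per_ct[, i] <- apply(vapply(scores, `[[`, numeric(n_types), "diag_corr"),
                         1, stats::median)
    gene_med[i] <- stats::median(vapply(scores, `[[`, numeric(1),
                                        "gene_corr_median"))
  }
  new_sweep_result("sample_size", sizes, per_ct, gene_med,
                   n_replicates, seeds, method)
}

#' Benchmark accuracy against noise in the proportion matrix
#'
#' Simulates one dataset from `config`, then, for each maximum-noise level and
#' replicate, perturbs the known proportions with `Uniform(0, max)` noise
#' (renormalized to the simplex, see [perturb_proportions()]), reruns the
#' estimator with the noisy proportions, and scores against the ground truth
#' (the true proportions are used only for generation, never for fitting).
#' Medians over replicates are reported per level. Only supervised estimators
#' (those consuming C) can be benchmarked this way.
#'
#' @param config a [sim_config()].
#' @param method one of `"rodeo"`, `"ols"`, `"nnls"`.
#' @param max_noise_values non-negative noise levels.
#' @param n_replicates replicates per level.
#' @param base_seed integer; perturbation seeds are derived from it.
#' @return a `sweep_result` with `axis_name = "max_noise"`.
#' @export
noise_sweep <- function(config, method = "rodeo", max_noise_values,
                        n_replicates = 10L, base_seed = 1L) {
  config <- as_sim_config(config)
  estimator <- get_estimator(method)
  stopifnot(all(max_noise_values >= 0), n_replicates >= 1)
  ds <- simulate_dataset(config)
  n_types <- length(config$celltype_ids)

  per_ct <- matrix(NA_real_, n_types, length(max_noise_values),
                   dimnames = list(config$celltype_ids, max_noise_values))
  gene_med <- stats::setNames(numeric(length(max_noise_values)),
                              max_noise_values)
  seeds <- base_seed + seq_len(n_replicates)
  for (i in seq_along(max_noise_values)) {
    scores <- lapply(seq_len(n_replicates), function(r) {
      s <- base_seed + (i - 1L) * n_replicates + r
      C_noisy <- perturb_proportions(ds$C, max_noise_values[i], seed = s)
      score_estimate(ds$truth_S, estimator(ds$E, C_noisy)$signature)
    })
    per_ct[, i] <- apply(vapply(scores, `[[`, numeric(n_types), "diag_corr"),
                         1, stats::median)
    gene_med[i] <- stats::median(vapply(scores, `[[`, numeric(1),
                                        "gene_corr_median"))
  }
  new_sweep_result("max_noise", max_noise_values, per_ct, gene_med,
                   n_replicates, seeds, method)
}

new_sweep_result <- function(axis_name, axis_values, per_celltype_median,
                             gene_corr_median, n_replicates, seeds, method) {
  structure(list(axis_name = axis_name, axis_values = axis_values,
                 per_celltype_median = per_celltype_median,
                 gene_corr_median = gene_corr_median,
                 n_replicates = n_replicates, seeds = seeds,
                 method = method),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Accuracy sweep over ", x$axis_name, " (", x$method, ", ",
      x$n_replicates, " replicates)\n", sep = "")
  tab <- rbind(x$per_celltype_median, median_gene = x$gene_corr_median)
  print(round(tab, 3))
  invisible(x)
}

#' Tabulate a sweep result
#'
#' @param x a `sweep_result`.
#' @param ... unused.
#' @return a data frame in long format: axis value, quantity (cell type ID or
#'   `"median_gene"`), median correlation.
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  tab <- rbind(x$per_celltype_median, median_gene = x$gene_corr_median)
  data.frame(axis = rep(x$axis_values, each = nrow(tab)),
             quantity = rep(rownames(tab), times = ncol(tab)),
             median_correlation = as.numeric(tab),
             row.names = NULL)
}
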