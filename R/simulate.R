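#' Configuration for the pseudo-bulk simulator
#'
#' Defaults emulate a simulated benchmark of five cell types (A-E) with mean
#' proportions 0.5/0.2/0.15/0.09/0.06 over 40 samples and 10,000 genes, where
#' 200 genes carry a batch effect (a different mean in half of the samples).
#'
#' @param n_genes number of genes.
#' @param celltype_ids character vector of cell type identifiers.
#' @param mean_proportions mean cell type proportions; positive, summing to 1,
#'   one per cell type.
#' @param n_samples number of samples.
#' @param n_batch_genes number of genes whose mean expression differs between
#'   the two sample halves (a batch such as age, sex or treatment); the
#'   default 200 is capped at `n_genes` for small simulations.
#' @param batch_effect_size multiplier applied to the batch genes' means in
#'   the affected (first) half of the samples.
#' @param dirichlet_concentration concentration of the Dirichlet distribution
#'   generating per-sample compositions; larger values give compositions
#'   closer to `mean_proportions`.
#' @param expr_meanlog,expr_sdlog log-normal parameters of the base gene x
#'   cell type expression means.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise on the bulk values (truncated at 0).
#' @param n_outliers number of outlier samples to append (samples with an
#'   altered signature matrix, see [add_outlier_samples()]).
#' @param outlier_effect_size multiplier applied to the altered genes of each
#'   outlier sample's signature.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       celltype_ids = c("A", "B", "C", "D", "E"),
                       mean_proportions = c(0.5, 0.2, 0.15, 0.09, 0.06),
                       n_samples = 40L,
                       n_batch_genes = min(200L, n_genes),
                       batch_effect_size = 2.0,
                       dirichlet_concentration = 50,
                       expr_meanlog = 4.0,
                       expr_sdlog = 1.0,
                       noise_cv = 0.15,
                       n_outliers = 0L,
                       outlier_effect_size = 3.0,
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 2,
            length(celltype_ids) == length(mean_proportions),
            all(mean_proportions > 0),
            abs(sum(mean_proportions) - 1) < 1e-8,
            n_batch_genes >= 0, n_batch_genes <= n_genes,
            batch_effect_size > 0, dirichlet_concentration > 0,
            expr_sdlog >= 0, noise_cv >= 0,
            n_outliers >= 0, outlier_effect_size > 0,
            length(seed) == 1L, is.finite(seed))
  structure(list(n_genes = as.integer(n_genes),
                 celltype_ids = as.character(celltype_ids),
                 mean_proportions = as.numeric(mean_proportions),
                 n_samples = as.integer(n_samples),
                 n_batch_genes = as.integer(n_batch_genes),
                 batch_effect_size = batch_effect_size,
                 dirichlet_concentration = dirichlet_concentration,
                 expr_meanlog = expr_meanlog,
                 expr_sdlog = expr_sdlog,
                 noise_cv = noise_cv,
                 n_outliers = as.integer(n_outliers),
                 outlier_effect_size = outlier_effect_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  do.call(sim_config, as.list(config))
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rdirichlet_cols <- function(n, alpha) {
  g <- matrix(stats::rgamma(length(alpha) * n, shape = alpha), length(alpha), n)
  sweep(g, 2, colSums(g), "/")
}

#' Draw cell type compositions from a Dirichlet distribution
#'
#' Each sample's composition is an independent draw from
#' `Dirichlet(concentration * mean_proportions)`, so the expected composition
#' equals `mean_proportions` and `concentration` controls the spread around
#' it.
#'
#' @param mean_proportions positive vector summing to 1; names (if any) become
#'   cell type IDs.
#' @param n_samples number of compositions to draw.
#' @param concentration positive Dirichlet concentration.
#' @param seed integer seed.
#' @return a proportion matrix (cell types x samples, columns summing to 1).
#' @export
#' @examples
#' C <- simulate_proportions(c(A = 0.6, B = 0.4), 5, seed = 1)
#' colSums(C)
simulate_proportions <- function(mean_proportions, n_samples,
                                 concentration = 50, seed = 1L) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0)
    stop("concentration must be a single positive number", call. = FALSE)
  stopifnot(all(mean_proportions > 0),
            abs(sum(mean_proportions) - 1) < 1e-8, n_samples >= 1)
  ids <- names(mean_proportions)
  if (is.null(ids)) ids <- paste0("celltype_", seq_along(mean_proportions))
  vals <- with_seed(seed,
                    rdirichlet_cols(n_samples,
                                    concentration * mean_proportions))
  proportion_matrix(vals, celltype_ids = ids,
                    sample_ids = paste0("sample_", seq_len(n_samples)))
}

#' Simulate a ground-truthed pseudo-bulk dataset
#'
#' Draws a base signature matrix with iid log-normal gene x cell type means,
#' applies a batch effect (the means of `n_batch_genes` genes are multiplied
#' by `batch_effect_size` in the first half of the samples, in every cell
#' type), draws Dirichlet compositions, and mixes per-sample signatures into
#' bulk columns with multiplicative Gaussian measurement noise (coefficient of
#' variation `noise_cv`, truncated at 0). Optionally appends outlier samples
#' whose signatures differ from the base truth (see [add_outlier_samples()]).
#'
#' Ground truth for evaluation is the base, pre-batch, pre-outlier signature
#' `truth_S`; batch and outlier perturbations are nuisance variation.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_dataset` with elements `truth_S`
#'   (genes x cell types), `C` (cell types x samples), `E` (genes x samples),
#'   `batch_genes`, `batch_samples`, `outlier_samples` (character ID vectors)
#'   and `config`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 100, n_samples = 20, seed = 7))
#' dim(ds$E)
simulate_dataset <- function(config = sim_config()) {
  config <- as_sim_config(config)
  n_types <- length(config$celltype_ids)
  gene_ids <- paste0("gene_", seq_len(config$n_genes))
  sample_ids <- paste0("sample_", seq_len(config$n_samples))

  ds <- with_seed(config$seed, {
    truth_S <- matrix(stats::rlnorm(config$n_genes * n_types,
                                    config$expr_meanlog, config$expr_sdlog),
                      config$n_genes, n_types,
                      dimnames = list(gene_ids, config$celltype_ids))
    batch_genes <- if (config$n_batch_genes > 0)
      sort(sample(gene_ids, config$n_batch_genes)) else character(0)
    batch_samples <- sample_ids[seq_len(config$n_samples %/% 2)]

    C <- rdirichlet_cols(config$n_samples,
                         config$dirichlet_concentration *
                           config$mean_proportions)
    dimnames(C) <- list(config$celltype_ids, sample_ids)

    E <- mix_bulk(truth_S, C, batch_genes, batch_samples,
                  config$batch_effect_size, config$noise_cv)

    list(truth_S = signature_matrix(truth_S),
         C = proportion_matrix(C),
         E = bulk_matrix(E),
         batch_genes = batch_genes,
         batch_samples = batch_samples,
         outlier_samples = character(0),
         config = config)
  })
  class(ds) <- "synthetic_dataset"
  if (config$n_outliers > 0)
    ds <- add_outlier_samples(ds, config$n_outliers,
                              config$outlier_effect_size,
                              seed = config$seed + 1L)
  ds
}

# Clean mixture E = S_n %*% C[, n] per sample (S_n = truth_S with the batch
# multiplier on batch_genes for batch_samples), then multiplicative Gaussian
# noise truncated at 0.
mix_bulk <- function(truth_S, C, batch_genes, batch_samples,
                     batch_effect_size, noise_cv) {
  E <- truth_S %*% C
  if (length(batch_genes) && length(batch_samples)) {
    S_batch <- truth_S
    S_batch[batch_genes, ] <- S_batch[batch_genes, ] * batch_effect_size
    E[, batch_samples] <- S_batch %*% C[, batch_samples, drop = FALSE]
  }
  if (noise_cv > 0) {
    noise <- matrix(stats::rnorm(length(E), 1, noise_cv), nrow(E), ncol(E))
    E <- pmax(E * noise, 0)
  }
  E
}

#' Append outlier samples to a simulated dataset
#'
#' An outlier sample is one whose cell type-specific expression differs from
#' the rest of the data: its per-sample signature is the base `truth_S` with a
#' random 10% of genes scaled by `effect_size` (drawn independently per
#' outlier), mixed with a freshly drawn composition and the dataset's
#' measurement noise. The ground truth `truth_S` and the original samples are
#' unchanged; the new sample IDs are recorded in `outlier_samples`.
#'
#' @param dataset a `synthetic_dataset` from [simulate_dataset()].
#' @param n_outliers number of outlier samples to append (>= 1).
#' @param effect_size multiplier for the altered genes.
#' @param seed integer seed.
#' @return the augmented `synthetic_dataset`.
#' @export
add_outlier_samples <- function(dataset, n_outliers,
                                effect_size = 3.0, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            n_outliers >= 1, effect_size > 0)
  cfg <- dataset$config
  n_genes <- nrow(dataset$truth_S)
  out_ids <- paste0("outlier_", seq_len(n_outliers))

  with_seed(seed, {
    C_out <- rdirichlet_cols(n_outliers,
                             cfg$dirichlet_concentration *
                               cfg$mean_proportions)
    dimnames(C_out) <- list(rownames(dataset$C), out_ids)
    E_out <- matrix(0, n_genes, n_outliers,
                    dimnames = list(rownames(dataset$truth_S), out_ids))
    for (j in seq_len(n_outliers)) {
      S_j <- dataset$truth_S
      altered <- sample(n_genes, max(1L, round(0.1 * n_genes)))
      S_j[altered, ] <- S_j[altered, ] * effect_size
      e <- as.numeric(S_j %*% C_out[, j])
      if (cfg$noise_cv > 0)
        e <- pmax(e * stats::rnorm(n_genes, 1, cfg$noise_cv), 0)
      E_out[, j] <- e
    }
    dataset$E <- bulk_matrix(cbind(dataset$E, E_out))
    dataset$C <- proportion_matrix(cbind(dataset$C, C_out))
    dataset$outlier_samples <- c(dataset$outlier_samples, out_ids)
    dataset
  })
}

#' Add uniform noise to a proportion matrix
#'
#' Adds independent `Uniform(0, max_noise)` noise to every entry and rescales
#' each column to sum to 1, emulating an imperfectly estimated composition
#' matrix.
#'
#' @param C proportion matrix (cell types x samples).
#' @param max_noise upper bound of the uniform noise (>= 0); 0 returns `C`
#'   unchanged.
#' @param seed integer seed.
#' @return the perturbed proportion matrix (columns on the simplex).
#' @export
perturb_proportions <- function(C, max_noise, seed = 1L) {
  if (!is.numeric(max_noise) || length(max_noise) != 1L || max_noise < 0)
    stop("max_noise must be a single non-negative number", call. = FALSE)
  C <- proportion_matrix(C)
  if (max_noise == 0) return(C)
  noisy <- with_seed(seed,
                     C + matrix(stats::runif(length(C), 0, max_noise),
                                nrow(C), ncol(C)))
  proportion_matrix(suppressWarnings(sweep(noisy, 2, colSums(noisy), "/")),
                    celltype_ids = rownames(C), sample_ids = colnames(C))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic pseudo-bulk dataset\n")
  cat("  E:", nrow(x$E), "genes x", ncol(x$E), "samples;  cell types:",
      paste(rownames(x$C), collapse = ", "), "\n")
  cat("  batch genes:", length(x$batch_genes),
      " outlier samples:", length(x$outlier_samples),
      " seed:", x$config$seed, "\n")
  invisible(x)
}
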