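test_that("cell type correlation matrix behaves like Pearson should", {
  toy <- make_toy_mixture(n_genes = 20, n_types = 3)
  rep0 <- celltype_correlations(toy$S, toy$S)
  expect_equal(unname(rep0$diag_corr), rep(1, 3))
  # affine invariance
  rep1 <- celltype_correlations(toy$S, 3.2 * toy$S + 5)
  expect_equal(unname(rep1$diag_corr), rep(1, 3))
  # full cross matrix, rows = known, columns = estimated
  expect_equal(dim(rep0$celltype_corr), c(3L, 3L))
  expect_true(all(abs(rep0$celltype_corr) <= 1 + 1e-12))

  # a 4-gene, 2-cell-type instance against the covariance-formula oracle
  S_true <- signature_matrix(matrix(c(1, 2, 3, 4, 2, 1, 5, 3), 4, 2),
                             paste0("g", 1:4), c("A", "B"))
  S_est <- signature_matrix(matrix(c(1.1, 2.2, 2.7, 4.4, 3, 0.5, 5.5, 2.9),
                                   4, 2), paste0("g", 1:4), c("A", "B"))
  cc <- celltype_correlations(S_true, S_est)$celltype_corr
  for (i in 1:2) for (j in 1:2)
    expect_equal(cc[i, j], pearson_oracle(S_true[, i], S_est[, j]),
                 tolerance = 1e-12)
})

test_that("zero-variance columns are flagged, tiny overlaps are errors", {
  toy <- make_toy_mixture(n_genes = 12, n_types = 3)
  S_flat <- toy$S
  S_flat[, 2] <- 7
  rep <- celltype_correlations(toy$S, S_flat)
  expect_true(all(is.na(rep$celltype_corr[, 2])))
  expect_false(anyNA(rep$celltype_corr[, -2]))
  expect_error(celltype_correlations(toy$S[1:2, ], toy$S[1:2, ]),
               "fewer than 3")
  # disjoint cell types: cross matrix only, no diagonal
  S_other <- toy$S
  colnames(S_other) <- c("X", "Y", "Z")
  expect_length(celltype_correlations(toy$S, S_other)$diag_corr, 0)
})

test_that("per-gene correlations handle reversals and constant rows", {
  toy <- make_toy_mixture(n_genes = 15, n_types = 3)
  ident <- gene_correlations(toy$S, toy$S)
  expect_equal(unname(ident$gene_corr), rep(1, 15))
  expect_equal(ident$gene_corr_median, 1)
  expect_equal(ident$n_undefined, 0L)

  # rank-reversed estimated row => negative correlation for that gene
  S_rev <- toy$S
  S_rev[4, ] <- rev(sort(toy$S[4, ])) [rank(toy$S[4, ])]
  rep <- gene_correlations(toy$S, S_rev)
  expect_lt(rep$gene_corr[4], 0)
  expect_equal(rep$gene_corr[4],
               pearson_oracle(toy$S[4, ], S_rev[4, ]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # constant true row => undefined, excluded from the median, counted
  S_const <- toy$S
  S_const[2, ] <- 4
  rep2 <- gene_correlations(S_const, toy$S)
  expect_true(is.na(rep2$gene_corr[2]))
  expect_equal(rep2$n_undefined, 1L)
  expect_equal(rep2$gene_corr_median,
               median(rep2$gene_corr[-2]))

  expect_error(gene_correlations(toy$S[, 1:2], toy$S[, 1:2]),
               "at least 3 cell types")
  S_badnames <- toy$S
  colnames(S_badnames) <- c("A", "B", "Q")
  expect_error(gene_correlations(toy$S, S_badnames), "do not match")
})

test_that("distance metrics satisfy their identities", {
  toy <- make_toy_mixture(n_genes = 10, n_types = 3)
  expect_equal(unname(accuracy_metric(toy$S, toy$S, "rmse")$per_celltype),
               rep(0, 3))
  expect_equal(unname(accuracy_metric(toy$S, toy$S,
                                      "euclidean")$per_celltype),
               rep(0, 3))
  S_e <- toy$S + matrix(rnorm(30), 10, 3)
  eu <- accuracy_metric(toy$S, S_e, "euclidean")$per_celltype
  rm <- accuracy_metric(toy$S, S_e, "rmse")$per_celltype
  expect_equal(rm, eu / sqrt(10))
  # 2-gene toy against hand arithmetic
  A <- signature_matrix(matrix(c(1, 2, 0, 1, 3, 2), 2, 3), c("g1", "g2"),
                        c("A", "B", "C"))
  B <- signature_matrix(matrix(c(2, 4, 0, 1, 3, 0), 2, 3), c("g1", "g2"),
                        c("A", "B", "C"))
  expect_equal(unname(accuracy_metric(A, B, "euclidean")$per_celltype),
               c(sqrt(1 + 4), 0, 2))
  expect_equal(unname(accuracy_metric(A, B, "rmse")$per_celltype),
               c(sqrt(5 / 2), 0, sqrt(2)))
  expect_error(accuracy_metric(A, B, "manhattan"))
})

test_that("pearson computations match the oracle on random instances", {
  set.seed(31)
  for (rep in 1:5) {
    S1 <- signature_matrix(matrix(rlnorm(60), 20, 3))
    S2 <- signature_matrix(matrix(rlnorm(60), 20, 3))
    cc <- celltype_correlations(S1, S2)$celltype_corr
    for (i in 1:3) for (j in 1:3)
      expect_equal(cc[i, j], pearson_oracle(S1[, i], S2[, j]),
                   tolerance = 1e-12)
    gc <- gene_correlations(S1, S2)$gene_corr
    for (g in c(1, 9, 20))
      expect_equal(unname(gc[g]), pearson_oracle(S1[g, ], S2[g, ]),
                   tolerance = 1e-12)
  }
})

test_that("sample-size sweep skips tiny sizes, is deterministic, and improves with n", {
  cfg <- sim_config(n_genes = 250, n_samples = 20, seed = 1)
  expect_warning(
    sw <- sample_size_sweep(cfg, "ols", sizes = c(3, 10, 60),
                            n_replicates = 3, base_seed = 5),
    "skipping")
  expect_equal(sw$axis_values, c(10, 60))
  expect_equal(dim(sw$per_celltype_median), c(5L, 2L))

  sw2 <- suppressWarnings(
    sample_size_sweep(cfg, "ols", sizes = c(3, 10, 60), n_replicates = 3,
                      base_seed = 5))
  expect_identical(sw, sw2)  # bit-identical rerun

  # accuracy benefits from sample size, for every cell type
  expect_true(all(sw$per_celltype_median[, "60"] >
                    sw$per_celltype_median[, "10"]))
  expect_gt(sw$gene_corr_median["60"], sw$gene_corr_median["10"])
})

test_that("subsample mode draws from a fixed pool", {
  cfg <- sim_config(n_genes = 150, n_samples = 30, seed = 2)
  sw <- sample_size_sweep(cfg, "ols", sizes = c(8, 25), n_replicates = 2,
                          base_seed = 1, mode = "subsample")
  expect_equal(sw$axis_values, c(8, 25))
  expect_true(all(is.finite(sw$gene_corr_median)))
})

test_that("noise sweep reproduces the clean accuracy at zero noise", {
  cfg <- sim_config(n_genes = 200, n_samples = 20, seed = 4)
  ds <- simulate_dataset(cfg)
  clean <- rodeo:::score_estimate(ds$truth_S, ols_deconv(ds$E, ds$C)$signature)
  sw <- noise_sweep(cfg, "ols", max_noise_values = c(0, 0.4),
                    n_replicates = 2, base_seed = 9)
  expect_equal(unname(sw$per_celltype_median[, "0"]),
               unname(clean$diag_corr))
  expect_equal(unname(sw$gene_corr_median["0"]), clean$gene_corr_median)
  # heavy noise hurts the dominant cell type less than it hurts the rest
  expect_true(sw$per_celltype_median["A", "0.4"] >=
                min(sw$per_celltype_median[, "0.4"]))
  expect_error(noise_sweep(cfg, "csSAM", 0.1), "'arg'")
})
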