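test_that("all three estimators recover a noise-free mixture exactly", {
  toy <- make_toy_mixture(n_genes = 25, n_samples = 18, n_types = 3)
  for (est in list(rodeo, ols_deconv, nnls_deconv)) {
    res <- est(toy$E, toy$C)
    expect_equal(res$signature, toy$S, tolerance = 1e-6)
    expect_true(all(res$converged))
  }
})

test_that("rodeo_fit_gene handles zero rows and excludes negative cell types", {
  toy <- make_toy_mixture(n_genes = 5, n_samples = 12, n_types = 3)
  z <- rodeo_fit_gene(rep(0, 12), toy$C)
  expect_equal(unname(z$signature_row), rep(0, 3))
  expect_true(z$converged)

  # two cell types; construct data whose unconstrained LS fit is
  # (positive, negative): expression tracks type A and anti-tracks B
  set.seed(4)
  C2 <- simulate_proportions(c(A = 0.5, B = 0.5), 30, concentration = 5,
                             seed = 4)
  y <- as.numeric(10 * C2["A", ] - 4 * C2["B", ]) + rnorm(30, sd = 0.05)
  ls2 <- ols_oracle(y, t(C2))
  expect_true(ls2[1] > 0 && ls2[2] < 0)  # the scenario is as constructed
  fit <- rodeo_fit_gene(y, C2)
  expect_equal(fit$excluded, "B")
  expect_equal(unname(fit$signature_row["B"]), 0)
  # the surviving coefficient matches a robust single-predictor fit on the
  # reduced design (LS oracle is close since the noise is tiny)
  expect_equal(unname(fit$signature_row["A"]),
               ols_oracle(y, t(C2)[, "A", drop = FALSE]),
               tolerance = 0.05)
  expect_length(fit$weights, 30)
  expect_true(all(fit$weights > 0 & fit$weights <= 1))
})

test_that("rodeo output is non-negative with excluded entries exactly zero", {
  set.seed(9)
  toy <- make_toy_mixture(n_genes = 80, n_samples = 20, n_types = 4,
                          noise_sd = 8, seed = 9)
  res <- rodeo(toy$E, toy$C)
  expect_true(all(res$signature >= 0))
  expect_true(all(res$signature[res$excluded] == 0))
  nn <- nnls_deconv(toy$E, toy$C)
  expect_true(all(nn$signature >= 0))
})

test_that("rodeo is equivariant under permutations and scaling", {
  toy <- make_toy_mixture(n_genes = 30, n_samples = 16, n_types = 3,
                          noise_sd = 3, seed = 2)
  cfg <- huber_config(tol = 1e-12, max_iter = 200)
  base <- rodeo(toy$E, toy$C, cfg)

  # permuting cell types permutes the estimate's columns
  perm_t <- c(3, 1, 2)
  res_t <- rodeo(toy$E, toy$C[perm_t, ], cfg)
  expect_equal(res_t$signature, base$signature[, perm_t])

  # permuting samples consistently leaves the estimate unchanged
  perm_s <- sample(ncol(toy$E))
  res_s <- rodeo(toy$E[, perm_s], toy$C[, perm_s], cfg)
  expect_equal(res_s$signature, base$signature, tolerance = 1e-10)

  # sample alignment is by ID, so a shuffled C is realigned internally
  res_shuf <- rodeo(toy$E, toy$C[, rev(colnames(toy$C))], cfg)
  expect_equal(res_shuf$signature, base$signature)

  # scale equivariance
  res_sc <- rodeo(5 * toy$E, toy$C, cfg)
  expect_equal(res_sc$signature, 5 * base$signature, tolerance = 1e-6)
})

test_that("gene estimates are independent of the other genes", {
  toy <- make_toy_mixture(n_genes = 40, n_samples = 15, n_types = 3,
                          noise_sd = 5, seed = 6)
  full <- rodeo(toy$E, toy$C)
  sub <- rodeo(toy$E[c(3, 17, 29), ], toy$C)
  expect_equal(sub$signature, full$signature[c(3, 17, 29), ])
})

test_that("ols_deconv matches the normal-equations oracle and clips on request", {
  set.seed(10)
  toy <- make_toy_mixture(n_genes = 30, n_samples = 14, n_types = 3,
                          noise_sd = 10, seed = 10)
  res <- ols_deconv(toy$E, toy$C)
  X <- t(toy$C)
  for (g in seq_len(nrow(toy$E)))
    expect_equal(unname(res$signature[g, ]), ols_oracle(toy$E[g, ], X),
                 tolerance = 1e-8)

  # a gene with true profile (5, 0) plus noise can go negative; clipping
  # zeroes it without touching the other coefficient
  C2 <- simulate_proportions(c(A = 0.6, B = 0.4), 20, concentration = 8,
                             seed = 3)
  set.seed(33)
  y <- pmax(5 * C2["A", ] + rnorm(20, sd = 0.3), 0)
  E2 <- bulk_matrix(rbind(g1 = y, g2 = y), sample_ids = colnames(C2))
  raw <- ols_deconv(E2, C2)
  if (any(raw$signature < 0)) {
    clipped <- ols_deconv(E2, C2, clip_negative = TRUE)
    expect_true(all(clipped$signature >= 0))
    keep <- raw$signature >= 0
    expect_equal(clipped$signature[keep], raw$signature[keep])
    expect_true(all(clipped$excluded[raw$signature < 0]))
  }
})

test_that("nnls_deconv is the exact constrained minimizer", {
  set.seed(14)
  # random 2- and 3-cell-type instances against exhaustive active sets
  for (p in 2:3) {
    for (rep in 1:8) {
      X <- matrix(runif(12 * p, 0.05, 1), 12, p)
      C <- proportion_matrix(t(sweep(X, 1, rowSums(X), "/")),
                             celltype_ids = paste0("t", 1:p),
                             sample_ids = paste0("s", 1:12))
      y <- as.numeric(t(C) %*% runif(p, -2, 8)) + rnorm(12, sd = 0.5)
      E <- bulk_matrix(rbind(g = pmax(y, 0), g2 = pmax(y, 0)),
                       sample_ids = colnames(C))
      est <- nnls_deconv(E, C)$signature[1, ]
      orc <- nnls_enum_oracle(E[1, ], t(C))
      expect_equal(unname(est), orc, tolerance = 1e-8)
      # NNLS fits at least as well as clipping the OLS solution
      clip <- pmax(ols_oracle(E[1, ], t(C)), 0)
      expect_lte(sum((E[1, ] - t(C) %*% est)^2),
                 sum((E[1, ] - t(C) %*% clip)^2) + 1e-10)
    }
  }
})

test_that("nnls equals ols when the unconstrained solution is non-negative", {
  toy <- make_toy_mixture(n_genes = 40, n_samples = 25, n_types = 3,
                          noise_sd = 1, seed = 20)
  raw <- ols_deconv(toy$E, toy$C)
  ok <- rowSums(raw$signature < 0) == 0
  expect_gt(sum(ok), 0)
  nn <- nnls_deconv(toy$E[ok, ], toy$C)
  expect_equal(nn$signature, raw$signature[ok, ], tolerance = 1e-8)
})

test_that("input validation catches mismatches and degenerate inputs", {
  toy <- make_toy_mixture(n_genes = 10, n_samples = 8, n_types = 3)
  C_bad <- toy$C
  colnames(C_bad)[1] <- "elsewhere"
  expect_error(rodeo(toy$E, C_bad), "sample IDs.*elsewhere")
  expect_error(rodeo(toy$E[, 1:2], toy$C[, 1:2]), "underdetermined")
  expect_error(ols_deconv(toy$E[, 1:2], toy$C[, 1:2]), "underdetermined")
  # rank-deficient proportions (duplicated cell type rows)
  C_dup <- rbind(toy$C[1, , drop = FALSE] / 2, toy$C[1, , drop = FALSE] / 2,
                 toy$C[-1, ] )
  rownames(C_dup) <- c("A1", "A2", rownames(toy$C)[-1])
  expect_error(proportion_matrix(C_dup), "full row rank")
  expect_error(bulk_matrix(matrix(-1, 2, 3)), "negative")
  expect_error(proportion_matrix(matrix(c(-0.1, 1.1, 0.5, 0.5), 2, 2)),
               "negative")
})

test_that("abundance columns are renormalized with a warning", {
  C <- matrix(c(2, 1, 1, 3), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_warning(Cn <- proportion_matrix(C), "renormaliz")
  expect_equal(colSums(Cn), c(s1 = 1, s2 = 1))
})
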