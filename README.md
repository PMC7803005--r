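# rodeo — robust expression deconvolution of bulk transcriptomes

Bulk expression from heterogeneous tissue (blood, tumor, biopsy) mixes the
transcriptomes of many cell types. When the cell type composition of each
sample is known — measured, or estimated by a composition deconvolution tool —
the cell type-specific expression profiles can be recovered from the bulk
data alone. `rodeo` solves this *expression deconvolution* problem: given a
bulk matrix **E** (genes × samples, non-negative normalized expression) and a
proportion matrix **C** (cell types × samples, columns on the simplex), it
estimates the signature matrix **S** (genes × cell types) under the linear
mixing model

```
e_gn = Σ_t s_gt · c_tn          (E = S · C)
```

It is aimed at researchers who want per-cell-type expression from existing
bulk datasets — cohorts too old, too rare or too fragile to re-profile at
single-cell resolution.

## The method

For each gene *g* independently, `rodeo()` minimizes the Huber objective

```
Σ_n f(e_gn − c_·n · βᵀ),   f(x) = x²/2        if |x| ≤ k
                            f(x) = k|x| − k²/2  if |x| > k
```

with k = 1.345 (95% Gaussian efficiency), solved by iteratively reweighted
least squares with a zero-centered MAD residual scale and no intercept. The
quadratic-to-linear loss caps the influence of outlier samples: each sample
receives a continuous weight in (0, 1] per gene, so a sample that is aberrant
for a few genes is downweighted only there instead of being discarded
wholesale. Whenever cell types receive negative coefficients they are
excluded (expression fixed at 0, since no cell type expresses a gene
negatively) and the model is refitted on the rest, until all remaining
coefficients are non-negative — exclusion rather than clipping keeps the other
cell types' estimates from inflating in compensation.

Two classical baselines are included for comparison: per-gene ordinary least
squares (`ols_deconv()`, optionally clipping negatives) and non-negative
least squares (`nnls_deconv()`). The package also ships a ground-truthed
pseudo-bulk simulator (`simulate_dataset()`: log-normal signatures, Dirichlet
compositions, batch-affected genes, outlier samples, multiplicative
measurement noise), accuracy metrics (`celltype_correlations()`,
`gene_correlations()`, `accuracy_metric()`), benchmarking sweeps
(`sample_size_sweep()`, `noise_sweep()`), delimited-matrix I/O and a CLI.

## Worked example

```r
library(rodeo)

# a simulated benchmark: 5 cell types, mean proportions 0.5/0.2/0.15/0.09/0.06,
# 10,000 genes of which 200 carry a batch effect, 40 samples
ds <- simulate_dataset(sim_config(seed = 1))
ds
#> Synthetic pseudo-bulk dataset
#>   E: 10000 genes x 40 samples;  cell types: A, B, C, D, E
#>   batch genes: 200  outlier samples: 0  seed: 1

res <- rodeo(ds$E, ds$C)
res
#> Expression deconvolution result (rodeo)
#>   signature: 10000 genes x 5 cell types
#>   genes with excluded cell types: 4532
#>   genes not converged: 3

accuracy_metric(ds$truth_S, res$signature, "pearson", method_name = "rodeo")
#> Deconvolution accuracy report (pearson, rodeo)
#>   csGEP correlations (diagonal):
#>     A     B     C     D     E
#> 0.984 0.920 0.946 0.861 0.913
#>   median per-gene correlation: 0.9188  (undefined: 0 )
```

The diagonal csGEP correlations say how well each cell type's expression
profile (a column of S) was recovered over genes; the per-gene median says
how well each gene's relative expression across cell types was recovered.
Accuracy rises with abundance (A at 0.98 vs D/E near 0.9 at only 40 samples)
and grows with sample size — at 500 samples all five exceed 0.98.

From a shell, the same pipeline is:

```sh
Rscript inst/scripts/rodeo-cli.R simulate --n-samples 40 --seed 1 --out-dir sim/
Rscript inst/scripts/rodeo-cli.R fit --bulk sim/E.tsv --proportions sim/C.tsv \
    --method rodeo --out S_hat.tsv
Rscript inst/scripts/rodeo-cli.R evaluate --truth sim/truth_S.tsv \
    --estimate S_hat.tsv --out report.tsv
```

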