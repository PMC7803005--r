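---
title: "Robust expression deconvolution: model, estimator and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust expression deconvolution: model, estimator and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodeo)
```

## The mixing model and its assumptions

Bulk expression of a heterogeneous sample is modeled as a proportion-weighted
sum of cell type-specific expression:

$$e_{gn} = \sum_{t \in T} s_{gt}\, c_{tn},$$

where $e_{gn}$ is the measured bulk expression of gene $g$ in sample $n$,
$c_{tn}$ the known proportion of cell type $t$ in sample $n$, and $s_{gt}$
the unknown expression of gene $g$ in pure cell type $t$. Estimating the
signature matrix $S$ given $E$ and $C$ is a per-gene linear regression with
the cell types as predictors and, crucially, **no intercept**: the model is a
pure mixture, and an intercept would absorb genuine signal into a fictitious
"background" cell type.

The model's assumptions are worth stating because they bound what any
estimator of this family can do:

* expression combines **additively and linearly** in proportions — sensible
  for linear-scale normalized values (TPM, TMM, RMA), not for log-scale data;
* $C$ is known (or well estimated) and its rows are linearly independent
  across samples; cell types whose proportions co-vary perfectly are not
  separable;
* one signature describes all samples — per-sample biological variation of
  $S$ is noise from the model's point of view. Robustness to *a few* samples
  violating this is exactly the design goal below.

## The estimator

For each gene independently, `rodeo()` minimizes the Huber objective

$$\sum_{n} f\!\left(e_{gn} - \boldsymbol c_{\cdot n}\boldsymbol\beta^{\mathsf T}\right),
\qquad f(x) = \begin{cases} x^2/2 & |x| \le k \\ k|x| - k^2/2 & |x| > k,\end{cases}$$

by iteratively reweighted least squares (IRLS):

1. initialize $\boldsymbol\beta$ at the ordinary least-squares solution
   (deterministic — the solver has no randomness);
2. compute residuals and re-estimate the robust scale
   $\hat\sigma = \mathrm{median}(|r|)/0.6745$ (MAD **centered at zero**: the
   no-intercept model forces residuals through zero, and centering at the
   median instead would let a skewed residual cloud shrink the scale; the
   user-facing `mad_scale()` defaults to median centering, the textbook
   convention, and the solver passes `center = 0`);
3. set weights $w_n = \min(1,\, k\hat\sigma/|r_n|)$ and solve the weighted
   least-squares problem;
4. stop when $\max_j |\beta_j^{\mathrm{new}} - \beta_j^{\mathrm{old}}| /
   \max(1, |\beta_j^{\mathrm{old}}|) < 10^{-6}$ or after 50 iterations
   (flagged `converged = FALSE`, never an error).

Samples beyond $k\hat\sigma$ get weight $k\hat\sigma/|r|$, so a single
arbitrarily wild sample changes the fit by a bounded amount — and since every
gene is fitted separately, a sample is downweighted only for the genes where
it actually misbehaves.

**Negative-coefficient exclusion.** Expression cannot be negative. When a fit
returns negative coefficients, *all* currently negative cell types are
excluded at once — their expression for that gene is fixed at exactly 0 — and
the model is refitted on the remainder, repeating until every remaining
coefficient is non-negative. Removing them (rather than clipping to 0 after
the fact) prevents the remaining coefficients from having been inflated to
compensate for an impossible negative term. Removing all negatives per pass
rather than one at a time is a deliberate choice: the two schemes can give
different answers, and the all-at-once rule both terminates in at most $|T|$
passes and treats the negative set symmetrically instead of depending on an
arbitrary removal order. If every cell type is excluded, the gene's row is
all-zero and all cell types are marked excluded.

The per-gene IRLS-plus-exclusion loop runs in compiled code
(RcppArmadillo); the R functions `fit_huber()` and `rodeo_fit_gene()` expose
single fits for inspection, and the test suite checks the compiled path
against an independent plain-R IRLS and against `MASS::rlm`.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 1.345 | Huber knot in robust-scale units; 1.345 gives 95% efficiency under Gaussian noise while still bounding outlier influence. Larger `k` approaches OLS (at `k = 1e6` the two agree to 1e-8). |
| `max_iter` | 50 | IRLS iteration cap; non-convergence is flagged, not fatal. |
| `tol` | 1e-6 | relative coefficient-change threshold. The $\max(1,|\beta|)$ denominator makes the rule absolute below magnitude 1 and relative above; it is therefore *not* scale-invariant away from the fixed point, which is why equivariance tests tighten `tol`. |
| `scale_floor` | 0 | scale at or below which data are declared noise-free: the current least-squares solution is returned with unit weights. `MASS::rlm` errors on a zero MAD; returning the exact LS fit instead lets noise-free (e.g. simulated) data pass through gracefully. |

### Baselines

`ols_deconv()` is per-gene unconstrained least squares (one QR of $C^{\mathsf
T}$ solves all genes at once); `clip_negative = TRUE` zeroes negative entries
after fitting, without refitting. `nnls_deconv()` returns the exact per-gene
minimizer under $s \ge 0$ via Lawson–Hanson NNLS (`pracma::lsqnonneg`),
verified in tests against exhaustive enumeration of active sets for up to
three cell types. Both baselines exist so robustness and constraint effects
can be measured rather than asserted.

## The synthetic-data generator

`simulate_dataset()` emulates a benchmark with known ground truth: five cell
types A–E with mean proportions 0.5/0.2/0.15/0.09/0.06, 10,000 genes and 40
samples by default, 200 genes carrying a batch effect. These counts pin the
benchmark's size and composition but leave the generative distributions open,
so the generator makes conventional choices, each exposed in `sim_config()`:

* **base signature**: iid log-normal means (`expr_meanlog = 4`,
  `expr_sdlog = 1`), a standard skewed model for expression levels;
* **compositions**: Dirichlet with mean `mean_proportions` and concentration
  50, giving realistic sample-to-sample compositional spread (s.d. ≈ 0.07
  for the dominant type) while keeping all types present in every sample;
* **batch effect**: the same `n_batch_genes` genes in every cell type have
  their means multiplied by 2 in the first half of the samples — a
  deterministic half, mimicking a binary covariate such as sex or treatment;
* **measurement noise**: multiplicative Gaussian with coefficient of
  variation `noise_cv = 0.15`, truncated at 0 — chosen once as a realistic
  error level for normalized expression, and producing the expected
  qualitative behavior (accuracy degrades sharply below ~30 samples and
  plateaus by a few hundred);
* **outlier samples** (`add_outlier_samples()`): appended samples whose
  *signature* (not merely composition) is altered — a random 10% of genes
  scaled by 3, drawn independently per outlier — because a sample with
  unusual proportions is not an outlier for expression deconvolution, while
  a sample whose cell types express differently is;
* all randomness flows from a single integer seed; identical seeds give
  bit-identical datasets.

Ground truth for scoring is always the base, pre-batch, pre-outlier
signature; batch and outlier effects are nuisance variation the estimator
should see through.

What the generator does **not** emulate: donor-to-donor variation of the
signature itself, correlated gene–gene structure, count-level (negative
binomial) sampling, and closely related cell types with strongly correlated
profiles. Real blood or T-cell-subset data are much harder than this
benchmark, so passing its thresholds demonstrates correct behavior of the
machinery, not field performance on difficult tissues.

## Evaluation procedures

Accuracy is measured two ways, both Pearson correlations between the true
and estimated $S$: per **cell type** (over genes; columns of $S$ — the full
known × estimated cross matrix is returned, its diagonal being the headline
number) and per **gene** (over cell types; rows of $S$, summarized by the
median over genes, computed only over the genes where both rows are
non-constant, with the undefined count reported). Root-mean-square error and
Euclidean distance per cell type profile are available as alternatives
(`accuracy_metric(..., metric = "rmse")`).

`sample_size_sweep()` scores an estimator across dataset sizes —
fresh simulation per replicate by default (self-contained and independent
across replicates), or subsampling from one fixed pool, which matches how a
fixed cohort would be thinned. `noise_sweep()` perturbs the *known* C with
`Uniform(0, max)` entry-wise noise, renormalizes each column, and refits:
this emulates working from an estimated rather than measured composition
matrix. (Benchmarks built on an externally estimated C report essentially the
same accuracy as the known C — the reported gap is under 0.01 — so using the
known C as the noise baseline is a faithful substitution.) Both sweeps report
per-level medians over replicates; replicate counts are parameters with
default 10, a desk-scale reduction of the 50 replicates a full study would
use.

## Numerical choices and degenerate inputs

* Proportion columns that sum to 1 within 1e-6 are accepted as-is; positive
  columns that do not (abundances) are renormalized with a warning; negative
  entries are a hard error.
* Rank-deficient designs raise an error naming the collinear cell types;
  fewer samples than cell types raises an underdetermined-system error (no
  silent fallback).
* An all-zero bulk row yields an all-zero signature row immediately (the
  zero-scale fallback).
* Undefined correlations (zero-variance profile or constant gene row) are
  reported as `NA` and excluded from medians, never silently converted.
* Matrix orientation is fixed throughout (genes × samples for E, cell
  types × samples for C, genes × cell types for S) and declared explicitly
  when reading files, so a transposed input fails validation loudly.

## Scale of the built-in checks

The test suite and the acceptance script exercise the benchmark at 10,000
genes with: one 500-sample run (profile recovery), ten 120-sample replicates
(gene-profile recovery; five in the test suite), a 10-level × 10-replicate
proportion-noise grid at 40 samples, and a 3-outlier robustness comparison at
40 samples — sizes chosen so the full cycle runs in minutes on one CPU while
keeping every conclusion at the benchmark's native gene count. Trend checks
(monotonicity in sample size and noise) run at 2,000 genes, where medians
over replicates are already stable.

## Known limitations

* Accuracy for rare cell types (mean proportion ≤ 0.06) is intrinsically
  limited by their low signal in the mixture; expect correlations well below
  the abundant types at small sample sizes.
* The estimator assumes the given C; systematic bias in C (as opposed to the
  zero-mean noise studied in the sweeps) propagates directly into S.
* Huber weights guard against a *minority* of outlying samples per gene; if
  most samples violate the shared-signature assumption, the notion of a
  single S is itself ill-posed.
* Per-gene independence is a modeling convenience: genes are fitted
  separately, so the method neither exploits nor is confused by co-expression
  structure.
* No standard errors or tests on $S$ are provided; the package estimates
  profiles and benchmarks estimators, it does not do inference.
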