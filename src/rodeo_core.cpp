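// Compiled core: Huber IRLS for a single no-intercept regression, and the
// per-gene Rodeo loop (IRLS fit + exclusion of cell types with negative
// coefficients) applied across all genes of a bulk matrix.
//
// Conventions shared with the R layer:
//   - scale = median(|residuals|)/0.6745 (zero-centred MAD: the mixing model
//     has no intercept, so residuals are centred at zero by construction);
//   - weights w_i = min(1, k*scale/|r_i|);
//   - convergence: max_j |b_new_j - b_old_j| / max(1, |b_old_j|) < tol;
//   - scale <= scale_floor at any iteration => keep the current (weighted)
//     LS solution, set all weights to 1, flag converged (noise-free data).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double MAD_CONSISTENCY = 0.6745;

static double mad_zero(const vec& r) {
  return median(abs(r)) / MAD_CONSISTENCY;
}

struct HuberFit {
  vec beta;
  vec w;
  double scale;
  int iterations;
  bool converged;
};

static HuberFit huber_irls(const vec& y, const mat& X, double k,
                           int max_iter, double tol, double scale_floor) {
  const uword n = y.n_elem;
  HuberFit fit;
  fit.beta = solve(X, y);           // OLS initialisation (QR based)
  fit.w = vec(n, fill::ones);
  fit.scale = 0.0;
  fit.iterations = 0;
  fit.converged = false;

  for (int it = 1; it <= max_iter; ++it) {
    vec r = y - X * fit.beta;
    fit.scale = mad_zero(r);
    if (fit.scale <= scale_floor) {
      fit.w.ones();
      fit.converged = true;
      return fit;
    }
    const double bound = k * fit.scale;
    vec w_new(n, fill::ones);
    for (uword i = 0; i < n; ++i) {
      double a = std::abs(r(i));
      if (a > bound) w_new(i) = bound / a;
    }
    vec sw = sqrt(w_new);
    mat Xw = X.each_col() % sw;
    vec beta_new = solve(Xw, y % sw);

    double delta = 0.0;
    for (uword j = 0; j < beta_new.n_elem; ++j) {
      double d = std::abs(beta_new(j) - fit.beta(j)) /
                 std::max(1.0, std::abs(fit.beta(j)));
      if (d > delta) delta = d;
    }
    fit.beta = beta_new;
    fit.w = w_new;
    fit.iterations = it;
    if (delta < tol) {
      fit.converged = true;
      break;
    }
  }
  return fit;
}

// [[Rcpp::export(name = ".huber_irls_cpp")]]
Rcpp::List huber_irls_cpp(const arma::vec& y, const arma::mat& X, double k,
                          int max_iter, double tol, double scale_floor) {
  HuberFit fit = huber_irls(y, X, k, max_iter, tol, scale_floor);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = fit.beta,
      Rcpp::Named("weights") = fit.w,
      Rcpp::Named("scale") = fit.scale,
      Rcpp::Named("n_iterations") = fit.iterations,
      Rcpp::Named("converged") = fit.converged);
}

// One gene: Huber fit on the active cell types; drop every cell type with a
// negative coefficient and refit until all remaining coefficients are >= 0.
// Excluded cell types get coefficient exactly 0. Terminates in <= T passes.
// [[Rcpp::export(name = ".rodeo_genes_cpp")]]
Rcpp::List rodeo_genes_cpp(const arma::mat& E, const arma::mat& X, double k,
                           int max_iter, double tol, double scale_floor) {
  const uword n_genes = E.n_rows;
  const uword n_types = X.n_cols;
  const uword n_samp = X.n_rows;

  mat S(n_genes, n_types, fill::zeros);
  umat excluded(n_genes, n_types, fill::zeros);
  mat weights(n_genes, n_samp, fill::ones);
  Rcpp::LogicalVector converged(n_genes);

  for (uword g = 0; g < n_genes; ++g) {
    vec y = E.row(g).t();
    uvec active = regspace<uvec>(0, n_types - 1);
    HuberFit fit;
    while (true) {
      fit = huber_irls(y, X.cols(active), k, max_iter, tol, scale_floor);
      uvec neg = find(fit.beta < 0.0);
      if (neg.n_elem == 0) break;
      uvec keep = find(fit.beta >= 0.0);
      active = active(keep);
      if (active.n_elem == 0) break;  // every cell type excluded
    }
    if (active.n_elem > 0) {
      for (uword j = 0; j < active.n_elem; ++j) S(g, active(j)) = fit.beta(j);
    }
    uvec excl_mask(n_types, fill::ones);
    excl_mask(active).zeros();
    excluded.row(g) = excl_mask.t();
    weights.row(g) = fit.w.t();
    converged[g] = fit.converged;
    if (g % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("signature") = S,
      Rcpp::Named("excluded") = excluded,
      Rcpp::Named("weights") = weights,
      Rcpp::Named("converged") = converged);
}
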