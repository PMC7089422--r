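// Per-SNP logistic association scan.
//
// One IRLS fit per dosage column with a shared covariate block. Kept in
// compiled code because a replicate-level simulation study runs hundreds of
// thousands of these small fits.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Logistic regression of y on [C, g] for every column g of G.
// C must contain the intercept column. Returns an m x 4 matrix with columns
// beta (dosage coefficient), se, z, converged (0/1).
// [[Rcpp::export(name = ".logistic_scan_cpp")]]
arma::mat logistic_scan_cpp(const arma::mat& G, const arma::vec& y,
                            const arma::mat& C, int maxit = 30,
                            double tol = 1e-8) {
  const uword n = G.n_rows, m = G.n_cols, pc = C.n_cols, p = pc + 1;
  mat out(m, 4, fill::zeros);
  const double ybar = mean(y);
  const double b0 = std::log(ybar / (1.0 - ybar));

  mat X(n, p);
  X.cols(0, pc - 1) = C;

  for (uword j = 0; j < m; ++j) {
    X.col(p - 1) = G.col(j);
    vec beta(p, fill::zeros);
    beta(0) = b0;  // assumes first covariate column is the intercept
    bool conv = false;
    for (int it = 0; it < maxit; ++it) {
      vec eta = X * beta;
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      w = clamp(w, 1e-10, 0.25);
      vec z = eta + (y - mu) / w;
      mat A = X.t() * (X.each_col() % w);
      vec rhs = X.t() * (w % z);
      vec beta_new;
      bool ok = solve(beta_new, A, rhs, solve_opts::no_approx);
      if (!ok || !beta_new.is_finite()) { conv = false; break; }
      double delta = max(abs(beta_new - beta));
      beta = beta_new;
      if (delta < tol) { conv = true; break; }
    }
    if (conv) {
      vec eta = X * beta;
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
      mat A = X.t() * (X.each_col() % w);
      mat Ainv;
      if (inv_sympd(Ainv, A)) {
        double se = std::sqrt(Ainv(p - 1, p - 1));
        out(j, 0) = beta(p - 1);
        out(j, 1) = se;
        out(j, 2) = beta(p - 1) / se;
        out(j, 3) = 1.0;
      }
    }
  }
  return out;
}
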