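#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Per-SNP logistic regression of y on [1, dosage, covariates] by
// Newton-Raphson, warm-started from the null linear predictor (covariates
// only). Returns per SNP: Wald z^2 for the dosage coefficient, the dosage
// coefficient, and a convergence flag. Missing dosages are handled by
// zero-weighting the affected rows.
// [[Rcpp::export]]
Rcpp::List logistic_scan_cpp(const arma::mat& dos, const arma::vec& y,
                             const arma::mat& covar, const arma::vec& eta0,
                             int max_iter = 25, double tol = 1e-8) {
  const int n = dos.n_rows, m = dos.n_cols;
  const int pc = covar.n_cols;           // includes intercept
  const int p = pc + 1;                  // + dosage
  vec stat(m, fill::value(datum::nan));
  vec beta_out(m, fill::value(datum::nan));
  ivec ok(m, fill::zeros);

  mat X(n, p);
  X.cols(1, pc) = covar;

  for (int j = 0; j < m; ++j) {
    vec x = dos.col(j);
    uvec finite = find_finite(x);
    vec w_mask(n, fill::zeros);
    w_mask.elem(finite).ones();
    vec xj = x;
    xj.elem(find_nonfinite(x)).zeros();
    X.col(0) = xj;

    vec beta(p, fill::zeros);
    // warm start: dosage coefficient 0, covariate part from the null fit
    vec eta = eta0;
    bool converged = false;
    for (int it = 0; it < max_iter; ++it) {
      vec pr = 1.0 / (1.0 + exp(-eta));
      vec w = pr % (1.0 - pr) % w_mask;
      vec z = (y - pr) % w_mask;
      vec grad = X.t() * z;
      mat H = X.t() * (X.each_col() % w);
      vec step;
      if (!solve(step, H, grad, solve_opts::no_approx)) break;
      beta += step;
      eta = eta0;  // eta = eta0 + X*beta: beta holds the update relative to
      eta += X * beta;               // the null linear predictor
      if (norm(step, "inf") < tol) { converged = true; break; }
      if (norm(beta, "inf") > 30) break;   // separation guard
    }
    if (!converged) continue;
    vec pr = 1.0 / (1.0 + exp(-eta));
    vec w = pr % (1.0 - pr) % w_mask;
    mat H = X.t() * (X.each_col() % w);
    mat Hinv;
    if (!inv_sympd(Hinv, H)) continue;
    double se2 = Hinv(0, 0);
    double b = beta(0);
    if (se2 <= 0 || std::abs(b) > 15) continue;
    stat(j) = b * b / se2;
    beta_out(j) = b;
    ok(j) = 1;
  }
  return Rcpp::List::create(Rcpp::_["stat"] = stat,
                            Rcpp::_["beta"] = beta_out,
                            Rcpp::_["converged"] = ok);
}
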