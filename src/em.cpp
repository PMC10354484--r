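// EM algorithm for a two-component Gaussian mixture in 1 or 2 dimensions.
// Log-space E-step for numerical stability; the M-step uses weighted
// moments with full (unconstrained) covariance matrices. A fit is flagged
// degenerate when any covariance eigenvalue drops below `var_floor`
// (component collapse onto tied data points), and non-convergent when the
// relative log-likelihood improvement has not fallen below `tol` within
// `max_iter` iterations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log N(x | mu, Sigma) for each row of X
static vec log_dens(const mat& X, const rowvec& mu, const mat& Sigma) {
  const uword d = X.n_cols;
  mat L;
  if (!chol(L, Sigma, "lower")) {
    return vec(X.n_rows, fill::value(-datum::inf));
  }
  double logdet = 2.0 * accu(log(L.diag()));
  mat centred = X.each_row() - mu;           // n x d
  mat z = solve(trimatl(L), centred.t());    // d x n
  vec quad = sum(square(z), 0).t();
  return -0.5 * (d * std::log(2.0 * datum::pi) + logdet + quad);
}

// [[Rcpp::export]]
Rcpp::List em_gauss2_cpp(const arma::mat& X,
                         arma::vec lambda,
                         arma::mat mu,        // 2 x d
                         const Rcpp::List& sigma0,
                         double tol,
                         int max_iter,
                         double var_floor) {
  const uword n = X.n_rows, d = X.n_cols;
  mat S1 = Rcpp::as<mat>(sigma0[0]);
  mat S2 = Rcpp::as<mat>(sigma0[1]);

  std::vector<double> trace;
  trace.reserve(64);
  double ll = -datum::inf;
  bool converged = false, degenerate = false;
  int iter = 0;

  mat logp(n, 2);
  mat resp(n, 2);

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step
    logp.col(0) = std::log(lambda(0)) + log_dens(X, mu.row(0), S1);
    logp.col(1) = std::log(lambda(1)) + log_dens(X, mu.row(1), S2);
    vec m = max(logp, 1);
    vec lse = m + log(sum(exp(logp.each_col() - m), 1));
    double ll_new = accu(lse);
    resp = exp(logp.each_col() - lse);

    trace.push_back(ll_new);
    if (std::isfinite(ll) &&
        std::fabs(ll_new - ll) < tol * (1.0 + std::fabs(ll_new))) {
      ll = ll_new;
      converged = true;
      break;
    }
    ll = ll_new;

    // M-step
    rowvec nk = sum(resp, 0);  // effective counts
    if (nk(0) < 1e-10 || nk(1) < 1e-10) { degenerate = true; break; }
    lambda(0) = nk(0) / n;
    lambda(1) = nk(1) / n;
    for (int k = 0; k < 2; ++k) {
      rowvec mk = sum(X.each_col() % resp.col(k), 0) / nk(k);
      mat centred = X.each_row() - mk;
      mat Sk = centred.t() * (centred.each_col() % resp.col(k)) / nk(k);
      Sk = symmatu(Sk);
      vec ev;
      if (!eig_sym(ev, Sk) || ev.min() < var_floor) { degenerate = true; break; }
      mu.row(k) = mk;
      if (k == 0) S1 = Sk; else S2 = Sk;
    }
    if (degenerate) break;
  }

  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma") = Rcpp::List::create(S1, S2),
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("degenerate") = degenerate,
    Rcpp::Named("d") = (int)d);
}
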