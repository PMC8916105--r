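// Batch ridge-penalised logistic regression by IRLS.
//
// The vertexwise analyses fit one small logistic model per cortical vertex
// (and per permutation), so the hot path is thousands of n x p fits sharing
// one design matrix X while the binary outcome varies by column of Y.
// A tiny ridge on the (standardized) predictors keeps sparse vertices with
// quasi-separation numerically sane; ridge = 0 gives plain ML and agrees
// with stats::glm to optimizer tolerance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One IRLS fit. Returns false if not converged within maxit or the
// weighted normal equations become singular.
static bool irls_fit(const mat& X, const vec& y, double ridge,
                     int maxit, double tol, vec& beta) {
  const uword p = X.n_cols;
  beta.zeros(p);
  // no penalty on the intercept (column of ones, assumed first)
  vec pen(p, fill::value(ridge));
  pen(0) = 0.0;
  double dev_old = datum::inf;
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * beta;
    eta = clamp(eta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-10, 0.25);
    vec z = eta + (y - mu) / w;
    mat XtWX = X.t() * (X.each_col() % w);
    XtWX.diag() += pen;
    vec beta_new;
    if (!solve(beta_new, XtWX, X.t() * (w % z), solve_opts::no_approx))
      return false;
    beta = beta_new;
    vec mu2 = 1.0 / (1.0 + exp(-clamp(X * beta, -30.0, 30.0)));
    mu2 = clamp(mu2, 1e-12, 1.0 - 1e-12);
    double dev = -2.0 * sum(y % log(mu2) + (1.0 - y) % log(1.0 - mu2)) +
                 dot(pen % beta, beta);
    if (std::abs(dev - dev_old) < tol * (std::abs(dev) + 0.1)) return true;
    dev_old = dev;
  }
  return false;
}

// Fit one logistic model per column of Y against the shared design X.
// Returns a p x V coefficient matrix; non-converged columns are all-NaN.
// [[Rcpp::export(name = ".ridge_logistic_batch")]]
arma::mat ridge_logistic_batch(const arma::mat& X, const arma::mat& Y,
                               double ridge, int maxit = 25,
                               double tol = 1e-8) {
  const uword p = X.n_cols, V = Y.n_cols;
  mat out(p, V);
  out.fill(datum::nan);
  vec beta;
  for (uword v = 0; v < V; ++v) {
    if (irls_fit(X, Y.col(v), ridge, maxit, tol, beta)) out.col(v) = beta;
  }
  return out;
}

// Same model, but one design per column: X is fixed, the rows of X are
// re-ordered per permutation. 'perms' is an n x B matrix of 1-based row
// indices. Returns a cube-flattened (p * V) x B matrix of coefficients.
// [[Rcpp::export(name = ".ridge_logistic_perms")]]
arma::mat ridge_logistic_perms(const arma::mat& X, const arma::mat& Y,
                               const arma::umat& perms, double ridge,
                               int maxit = 25, double tol = 1e-8) {
  const uword p = X.n_cols, V = Y.n_cols, B = perms.n_cols;
  mat out(p * V, B);
  out.fill(datum::nan);
  vec beta;
  for (uword b = 0; b < B; ++b) {
    mat Xb = X.rows(perms.col(b) - 1);
    for (uword v = 0; v < V; ++v) {
      if (irls_fit(Xb, Y.col(v), ridge, maxit, tol, beta))
        out(span(v * p, v * p + p - 1), span(b)) = beta;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
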