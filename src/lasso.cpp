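// Coordinate-descent lasso on the Gram matrix, the inner solver of the
// random-lasso ensemble. Objective (glmnet parameterization, intercept
// unpenalized, predictors not standardized internally):
//   (1/2n) * ||y - b0 - X b||^2 + lambda * ||b||_1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void cd_solve(const mat& C, const vec& cxy, double lambda, vec& beta,
                     double tol, int maxit) {
  const uword p = cxy.n_elem;
  vec dj = C.diag();
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      if (dj(j) <= 0.0) { beta(j) = 0.0; continue; }
      double rj = cxy(j) - dot(C.col(j), beta) + dj(j) * beta(j);
      double bj = 0.0;
      if (rj > lambda) bj = (rj - lambda) / dj(j);
      else if (rj < -lambda) bj = (rj + lambda) / dj(j);
      if (bj != beta(j)) {
        double d = std::abs(bj - beta(j)) * std::sqrt(dj(j));
        if (d > dmax) dmax = d;
        beta(j) = bj;
      }
    }
    if (dmax < tol) break;
  }
}

// Lasso at a fixed penalty. Returns beta and intercept.
// [[Rcpp::export]]
Rcpp::List lasso_fixed_cpp(const arma::mat& X, const arma::vec& y,
                           double lambda, double tol, int maxit) {
  const double n = (double)X.n_rows;
  rowvec xbar = mean(X, 0);
  double ybar = mean(y);
  mat Xc = X.each_row() - xbar;
  vec yc = y - ybar;
  mat C = Xc.t() * Xc / n;
  vec cxy = Xc.t() * yc / n;
  vec beta(X.n_cols, fill::zeros);
  cd_solve(C, cxy, lambda, beta, tol, maxit);
  double intercept = ybar - dot(xbar.t(), beta);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("intercept") = intercept,
                            Rcpp::Named("lambda") = lambda);
}

// Warm-started geometric path from lambda_max; penalty selected by the
// extended BIC (n log(RSS/n) + df (log n + 2 gamma log p)); gamma = 0
// recovers the ordinary BIC. Ties resolve to the larger penalty.
// [[Rcpp::export]]
Rcpp::List lasso_bic_cpp(const arma::mat& X, const arma::vec& y,
                         int n_lambda, double lambda_min_ratio,
                         double gamma, double tol, int maxit) {
  const double n = (double)X.n_rows;
  const uword p = X.n_cols;
  rowvec xbar = mean(X, 0);
  double ybar = mean(y);
  mat Xc = X.each_row() - xbar;
  vec yc = y - ybar;
  mat C = Xc.t() * Xc / n;
  vec cxy = Xc.t() * yc / n;
  double my2 = dot(yc, yc) / n;
  double lam_max = abs(cxy).max();
  if (lam_max <= 0.0) {
    return Rcpp::List::create(Rcpp::Named("beta") = vec(p, fill::zeros),
                              Rcpp::Named("intercept") = ybar,
                              Rcpp::Named("lambda") = 0.0);
  }
  double step = std::log(lambda_min_ratio) / (double)(n_lambda - 1);
  vec beta(p, fill::zeros);
  vec best_beta(p, fill::zeros);
  double best_bic = datum::inf, best_lam = lam_max;
  for (int l = 0; l < n_lambda; ++l) {
    double lam = lam_max * std::exp(step * l);
    cd_solve(C, cxy, lam, beta, tol, maxit);
    double rss_n = my2 - 2.0 * dot(beta, cxy) + as_scalar(beta.t() * C * beta);
    if (rss_n < 1e-12) rss_n = 1e-12;
    double df = (double)sum(beta != 0.0);
    double bic = n * std::log(rss_n) + df * (std::log(n) + 2.0 * gamma * std::log((double)p));
    if (bic < best_bic - 1e-12) {
      best_bic = bic;
      best_beta = beta;
      best_lam = lam;
    }
  }
  double intercept = ybar - dot(xbar.t(), best_beta);
  return Rcpp::List::create(Rcpp::Named("beta") = best_beta,
                            Rcpp::Named("intercept") = intercept,
                            Rcpp::Named("lambda") = best_lam);
}
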