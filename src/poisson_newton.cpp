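// Newton ascent for the ridge-penalized Poisson log-posterior
//   L(w) = sum_t [ r_t eta_t - delta exp(eta_t) ] - xi * ||w_pen||^2
// with eta = X w. The bias coefficient is unpenalized. The objective is
// concave; step halving keeps the recorded objective non-decreasing.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static double objective(const vec& r, const vec& eta, double delta,
                        double xi, const vec& w, const uvec& pen) {
  vec mu = delta * exp(clamp(eta, -datum::inf, 40.0));
  double ridge = 0.0;
  for (uword k = 0; k < pen.n_elem; ++k) {
    if (pen[k]) ridge += w[k] * w[k];
  }
  return dot(r, eta) - accu(mu) - xi * ridge;
}

// H = X' diag(mu) X accumulated row-wise: Xt holds the rows of X as sparse
// columns, so each observation contributes mu_i times the outer product of
// one short sparse column.
static void weighted_crossprod(const sp_mat& Xt, const vec& mu, mat& H) {
  const uword P = Xt.n_rows;
  H.zeros(P, P);
  const uword n = Xt.n_cols;
  for (uword i = 0; i < n; ++i) {
    const double m = mu[i];
    if (m == 0.0) continue;
    sp_mat::const_col_iterator a_end = Xt.end_col(i);
    for (sp_mat::const_col_iterator a = Xt.begin_col(i); a != a_end; ++a) {
      const double va = m * (*a);
      const uword ra = a.row();
      for (sp_mat::const_col_iterator b = a; b != a_end; ++b) {
        H(b.row(), ra) += va * (*b);
      }
    }
  }
  H = symmatl(H);
}

// [[Rcpp::export]]
Rcpp::List poisson_newton_cpp(const arma::sp_mat& X, const arma::vec& r,
                              double delta, double xi, const arma::uvec& pen,
                              arma::vec w, double gtol, int maxit) {
  const uword P = X.n_cols;
  const sp_mat Xt = X.t();
  vec eta = vec(X * w);
  double obj = objective(r, eta, delta, xi, w, pen);
  std::vector<double> trace;
  trace.push_back(obj);
  bool converged = false;
  double gnorm = datum::inf;
  int it = 0;
  vec ridge_diag(P);
  for (uword k = 0; k < P; ++k) ridge_diag[k] = (pen[k] ? 2.0 * xi : 0.0) + 1e-9;
  mat H(P, P);

  while (it < maxit) {
    ++it;
    vec mu = delta * exp(clamp(eta, -datum::inf, 40.0));
    vec g = vec(Xt * (r - mu));
    for (uword k = 0; k < P; ++k) {
      if (pen[k]) g[k] -= 2.0 * xi * w[k];
    }
    gnorm = norm(g, "inf");
    if (gnorm < gtol) { converged = true; break; }

    weighted_crossprod(Xt, mu, H);
    H.diag() += ridge_diag;
    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      return Rcpp::List::create(Rcpp::Named("error") = "singular Hessian");
    }
    // predicted quadratic improvement; once it is below the floating-point
    // resolution of the objective the optimum is reached for all practical
    // purposes and further line searches can only stall
    double pred = 0.5 * dot(g, step);
    if (pred <= 1e-10 * (1.0 + std::abs(obj))) { converged = true; break; }
    double t = 1.0;
    vec Xstep = vec(X * step);
    for (;;) {
      vec eta_new = eta + t * Xstep;
      vec w_new = w + t * step;
      double obj_new = objective(r, eta_new, delta, xi, w_new, pen);
      if (std::isfinite(obj_new) && obj_new >= obj) {
        w = w_new; eta = eta_new; obj = obj_new;
        break;
      }
      t *= 0.5;
      if (t < 1e-10) break;
    }
    trace.push_back(obj);
  }
  if (!converged) {
    vec mu = delta * exp(clamp(eta, -datum::inf, 40.0));
    vec g = vec(Xt * (r - mu));
    for (uword k = 0; k < P; ++k) {
      if (pen[k]) g[k] -= 2.0 * xi * w[k];
    }
    gnorm = norm(g, "inf");
    converged = gnorm < gtol;
  }
  return Rcpp::List::create(
    Rcpp::Named("w") = w,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("gradient_norm") = gnorm,
    Rcpp::Named("converged") = converged);
}

// log-determinant of X' diag(mu) X + diag(ridge), for the Laplace evidence
// [[Rcpp::export]]
double weighted_hessian_logdet_cpp(const arma::sp_mat& X, const arma::vec& mu,
                                   const arma::vec& ridge_diag) {
  const sp_mat Xt = X.t();
  mat H;
  weighted_crossprod(Xt, mu, H);
  H.diag() += ridge_diag;
  mat R;
  if (!chol(R, H)) return NA_REAL;
  return 2.0 * accu(log(R.diag()));
}
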