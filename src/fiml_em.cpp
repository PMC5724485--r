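// EM estimation of a seemingly-unrelated-regressions system under a joint
// multivariate-normal error model, using every participant's observed outcome
// components (full-information ML). Missing outcomes are integrated out in the
// E-step; regression coefficients and the cross-equation residual covariance
// are updated in closed form, so the observed-data log-likelihood is monotone.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Pattern id from the row's missingness mask (K <= 30 equations).
inline unsigned int pattern_id(const mat& Y, uword i, uword K) {
  unsigned int id = 0;
  for (uword k = 0; k < K; ++k)
    if (std::isfinite(Y(i, k))) id |= (1u << k);
  return id;
}

} // namespace

// X: list of n x p_k design matrices (complete, no NA).
// Y: n x K outcome matrix, NaN = missing. Rows with no observed outcome are
//    rejected upstream.
// beta0: list of starting coefficient vectors; Sigma0: starting covariance.
// [[Rcpp::export]]
Rcpp::List fiml_em_cpp(Rcpp::List X, arma::mat Y, Rcpp::List beta0,
                       arma::mat Sigma0, int max_iter, double tol) {
  const uword K = Y.n_cols, n = Y.n_rows;

  std::vector<mat> Xk(K);
  uvec pk(K);
  uword ptot = 0;
  for (uword k = 0; k < K; ++k) {
    Xk[k] = Rcpp::as<mat>(X[k]);
    pk(k) = Xk[k].n_cols;
    ptot += pk(k);
  }
  uvec off(K); // offset of equation k's block in the stacked coefficient
  for (uword k = 0, o = 0; k < K; ++k) { off(k) = o; o += pk(k); }

  // Fixed cross-products X_k' X_l used in every M-step.
  std::vector<std::vector<mat>> XtX(K, std::vector<mat>(K));
  for (uword k = 0; k < K; ++k)
    for (uword l = 0; l < K; ++l)
      XtX[k][l] = Xk[k].t() * Xk[l];

  // Group rows by missingness pattern.
  std::map<unsigned int, std::vector<uword>> groups;
  for (uword i = 0; i < n; ++i)
    groups[pattern_id(Y, i, K)].push_back(i);

  vec beta(ptot);
  for (uword k = 0; k < K; ++k) {
    vec b = Rcpp::as<vec>(beta0[k]);
    beta.subvec(off(k), off(k) + pk(k) - 1) = b;
  }
  mat Sigma = Sigma0;

  const double log2pi = std::log(2.0 * M_PI);
  double ll = -datum::inf, ll_prev = -datum::inf;
  int iter = 0;
  bool converged = false;

  mat Mu(n, K), Yhat(n, K);
  mat Cextra(K, K); // sum over participants of conditional covariances

  for (iter = 1; iter <= max_iter; ++iter) {
    for (uword k = 0; k < K; ++k)
      Mu.col(k) = Xk[k] * beta.subvec(off(k), off(k) + pk(k) - 1);

    // E-step (also evaluates the observed-data log-likelihood at the
    // current parameter value).
    ll = 0.0;
    Yhat = Mu;
    Cextra.zeros();
    for (auto& g : groups) {
      uvec obs, mis;
      {
        std::vector<uword> o, m;
        for (uword k = 0; k < K; ++k)
          (g.first & (1u << k)) ? o.push_back(k) : m.push_back(k);
        obs = uvec(o); mis = uvec(m);
      }
      uvec rows(g.second);
      if (obs.n_elem == 0) {
        // fully missing row: no likelihood contribution; E-step imputes the
        // mean with conditional covariance equal to Sigma itself
        Cextra += (double)rows.n_elem * Sigma;
        continue;
      }
      mat Soo = Sigma.submat(obs, obs);
      mat Soo_inv = inv_sympd(symmatu(Soo));
      double ldet; double sign;
      log_det(ldet, sign, Soo);
      mat R = Y.submat(rows, obs) - Mu.submat(rows, obs); // residuals, obs part
      // log-likelihood contribution
      mat Q = R * Soo_inv; // rows x |obs|
      ll += -0.5 * (double)rows.n_elem * ((double)obs.n_elem * log2pi + ldet)
            -0.5 * accu(Q % R);
      if (mis.n_elem > 0) {
        mat A = Sigma.submat(mis, obs) * Soo_inv;          // |mis| x |obs|
        mat Cg = Sigma.submat(mis, mis) - A * Sigma.submat(obs, mis);
        mat Ymis = Mu.submat(rows, mis) + R * A.t();
        Yhat.submat(rows, mis) = Ymis;
        // accumulate group conditional covariance into full-K layout
        for (uword a = 0; a < mis.n_elem; ++a)
          for (uword b = 0; b < mis.n_elem; ++b)
            Cextra(mis(a), mis(b)) += (double)rows.n_elem * Cg(a, b);
      }
      Yhat.submat(rows, obs) = Y.submat(rows, obs);
    }

    if (std::isfinite(ll) && std::isfinite(ll_prev) &&
        std::abs(ll - ll_prev) < tol * (std::abs(ll_prev) + 1.0)) {
      converged = true;
      break;
    }
    ll_prev = ll;

    // CM-step 1: coefficients by generalised least squares on completed data.
    mat W = inv_sympd(symmatu(Sigma));
    mat H(ptot, ptot, fill::zeros);
    vec gvec(ptot, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      for (uword l = 0; l < K; ++l) {
        H.submat(off(k), off(l), off(k) + pk(k) - 1, off(l) + pk(l) - 1) =
            W(k, l) * XtX[k][l];
        gvec.subvec(off(k), off(k) + pk(k) - 1) +=
            W(k, l) * (Xk[k].t() * Yhat.col(l));
      }
    }
    beta = solve(symmatu(H), gvec,
                 solve_opts::likely_sympd + solve_opts::no_approx);

    // CM-step 2: residual covariance from completed residuals plus the
    // conditional covariance of the imputed components.
    for (uword k = 0; k < K; ++k)
      Mu.col(k) = Xk[k] * beta.subvec(off(k), off(k) + pk(k) - 1);
    mat E = Yhat - Mu;
    Sigma = (E.t() * E + Cextra) / (double)n;
    Sigma = symmatu(Sigma);
  }
  if (iter > max_iter) iter = max_iter;

  // Observed-data information for the coefficients at the final parameters
  // (mean and covariance parameters of a normal are orthogonal, so the
  // coefficient block of the expected information is exactly this).
  mat Hobs(ptot, ptot, fill::zeros);
  for (auto& g : groups) {
    std::vector<uword> o;
    for (uword k = 0; k < K; ++k)
      if (g.first & (1u << k)) o.push_back(k);
    if (o.empty()) continue;
    uvec obs(o);
    uvec rows(g.second);
    mat Soo_inv = inv_sympd(symmatu(Sigma.submat(obs, obs)));
    for (uword a = 0; a < obs.n_elem; ++a) {
      for (uword b = 0; b < obs.n_elem; ++b) {
        uword k = obs(a), l = obs(b);
        mat Xkg = Xk[k].rows(rows), Xlg = Xk[l].rows(rows);
        Hobs.submat(off(k), off(l), off(k) + pk(k) - 1, off(l) + pk(l) - 1) +=
            Soo_inv(a, b) * (Xkg.t() * Xlg);
      }
    }
  }

  // Per-equation observed counts
  Rcpp::IntegerVector n_obs(K);
  for (uword k = 0; k < K; ++k) {
    uword c = 0;
    for (uword i = 0; i < n; ++i)
      if (std::isfinite(Y(i, k))) ++c;
    n_obs[k] = (int)c;
  }

  Rcpp::List beta_out(K);
  for (uword k = 0; k < K; ++k)
    beta_out[k] = Rcpp::wrap(beta.subvec(off(k), off(k) + pk(k) - 1));

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_out,
      Rcpp::Named("Sigma") = Sigma,
      Rcpp::Named("info") = symmatu(Hobs),
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_obs") = n_obs);
}
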