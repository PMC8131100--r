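// Gibbs sampler for Bayesian linear regression with the horseshoe prior.
//
// Model: y | beta, sigma2 ~ N(X beta, sigma2 I)
//        beta_j | lambda_j, tau, sigma ~ N(0, sigma2 tau^2 lambda_j^2)
//        lambda_j ~ C+(0,1), tau ~ C+(0,1), sigma2 ~ IG(eps, eps) (vague)
// The half-Cauchy scales are sampled through inverse-gamma auxiliary
// variables (nu_j, xi), giving closed-form conditionals throughout.
// The beta update uses either a p x p Cholesky solve (standard) or the
// O(n^2 p) data-augmentation sampler suited to p > n (fast).
// All randomness is drawn from R's RNG so results are reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // R::rgamma takes (shape, scale); guard the rate away from 0/Inf
  double g = R::rgamma(shape, 1.0 / std::max(rate, 1e-300));
  return 1.0 / std::max(g, 1e-300);
}

// [[Rcpp::export(name = ".hs_gibbs")]]
List hs_gibbs(const arma::mat& X, const arma::vec& y,
              int n_burn, int n_keep, int mode, bool keep_samples) {
  const int n = X.n_rows, p = X.n_cols;
  // mode: 0 = auto, 1 = standard (p x p Cholesky), 2 = fast (p > n sampler)
  const bool fast = (mode == 2) || (mode == 0 && p > n);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec lambda2(p, arma::fill::ones);
  arma::vec nu(p, arma::fill::ones);
  double tau2 = 1.0, xi = 1.0;
  double sigma2 = arma::var(y);
  if (!(sigma2 > 0)) sigma2 = 1.0;

  arma::mat XtX;
  arma::vec Xty = X.t() * y;
  if (!fast) XtX = X.t() * X;

  const int n_iter = n_burn + n_keep;
  arma::vec coef_sum(p, arma::fill::zeros);
  double sigma2_sum = 0.0, tau_sum = 0.0;
  arma::mat samples;
  if (keep_samples) samples.set_size(n_keep, p);

  for (int it = 0; it < n_iter; ++it) {
    const arma::vec d = arma::clamp(tau2 * lambda2, 1e-12, 1e12); // prior var / sigma2

    if (fast) {
      // Bhattacharya-Chandra-Mallick exact sampler, O(n^2 p)
      const double sigma = std::sqrt(sigma2);
      arma::vec sd = arma::sqrt(sigma2 * d);
      arma::vec u(p), delta(n);
      for (int j = 0; j < p; ++j) u[j] = R::norm_rand() * sd[j];
      for (int i = 0; i < n; ++i) delta[i] = R::norm_rand();
      arma::vec v = X * u / sigma + delta;
      arma::mat M = X * arma::diagmat(d) * X.t() + arma::eye(n, n);
      arma::vec w = arma::solve(M, y / sigma - v, arma::solve_opts::likely_sympd);
      // beta = u + D_full Phi' w with D_full = sigma2 * d, Phi = X / sigma
      beta = u + sigma * (d % (X.t() * w));
    } else {
      arma::mat A = XtX;
      A.diag() += 1.0 / d;
      arma::mat R_chol = arma::chol(A);                 // A = R'R
      arma::vec mu = arma::solve(arma::trimatu(R_chol),
                      arma::solve(arma::trimatl(R_chol.t()), Xty));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
      beta = mu + std::sqrt(sigma2) * arma::solve(arma::trimatu(R_chol), z);
    }

    if (!beta.is_finite())
      stop("sampler divergence: non-finite coefficient draw at iteration %d", it + 1);

    // local shrinkage
    const arma::vec b2s = arma::square(beta) / (2.0 * sigma2);
    for (int j = 0; j < p; ++j) {
      lambda2[j] = rinvgamma(1.0, 1.0 / nu[j] + b2s[j] / tau2);
      nu[j] = rinvgamma(1.0, 1.0 + 1.0 / lambda2[j]);
    }
    // global shrinkage
    double ssl = arma::accu(b2s / arma::clamp(lambda2, 1e-12, 1e12));
    tau2 = rinvgamma(0.5 * (p + 1.0), 1.0 / xi + ssl);
    xi = rinvgamma(1.0, 1.0 + 1.0 / tau2);
    // noise variance
    arma::vec resid = y - X * beta;
    double ssb = arma::accu(arma::square(beta) /
                            arma::clamp(tau2 * lambda2, 1e-12, 1e12));
    sigma2 = rinvgamma(0.5 * (n + p), 0.5 * (arma::dot(resid, resid) + ssb));
    if (!std::isfinite(sigma2) || !std::isfinite(tau2))
      stop("sampler divergence: non-finite scale draw at iteration %d", it + 1);

    if (it >= n_burn) {
      coef_sum += beta;
      sigma2_sum += sigma2;
      tau_sum += std::sqrt(tau2);
      if (keep_samples) samples.row(it - n_burn) = beta.t();
    }
  }

  List out = List::create(
    _["coef_mean"] = coef_sum / n_keep,
    _["sigma2_mean"] = sigma2_sum / n_keep,
    _["global_shrinkage_mean"] = tau_sum / n_keep,
    _["sampler_mode"] = fast ? "fast_p_gt_n" : "standard");
  if (keep_samples) out["coef_samples"] = samples;
  return out;
}
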