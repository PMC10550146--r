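#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Structural model predictions (log TV) shared by the SAEM E-step, the EBE
// search and importance sampling. Model codes:
//   1 final (tumor-angiogenesis-resources), parameters
//     (tv0, lambda, k_ang, k_res, k_consumption, k_death)
//   2 linear (tv0, k); 3 exponential (tv0, k); 4 logistic (tv0, k, K)
//   5 gompertz (tv0, alpha, beta); 6 simeoni (tv0, l0, l1), psi fixed at 20

NumericMatrix solve_final_cpp(NumericVector pars, NumericVector init,
                              NumericVector times, double rtol, double atol);
NumericVector solve_simeoni_cpp(double tv0, double l0, double l1, double psi,
                                NumericVector times, double rtol, double atol);

static bool predict_log_model(int model, const std::vector<double>& p,
                              const NumericVector& times, double rtol,
                              double atol, std::vector<double>& out) {
  int n = times.size();
  out.resize(n);
  switch (model) {
    case 1: {
      NumericVector pv = NumericVector::create(p[1], p[2], p[3], p[4], p[5]);
      NumericVector init = NumericVector::create(p[0], 1.0, 1.0);
      NumericMatrix m;
      try {
        m = solve_final_cpp(pv, init, times, rtol, atol);
      } catch (...) { return false; }
      for (int j = 0; j < n; ++j) {
        double v = m(j, 0);
        if (!(v > 0) || !std::isfinite(v)) return false;
        out[j] = std::log(v);
      }
      return true;
    }
    case 2:
      for (int j = 0; j < n; ++j) {
        double v = p[0] + p[1] * times[j];
        if (!(v > 0)) return false;
        out[j] = std::log(v);
      }
      return true;
    case 3:
      for (int j = 0; j < n; ++j) out[j] = std::log(p[0]) + p[1] * times[j];
      return true;
    case 4:
      for (int j = 0; j < n; ++j) {
        double e = std::exp(p[1] * times[j]);
        double v = p[0] * p[2] * e / (p[2] + p[0] * (e - 1.0));
        if (!(v > 0) || !std::isfinite(v)) return false;
        out[j] = std::log(v);
      }
      return true;
    case 5:
      for (int j = 0; j < n; ++j)
        out[j] = std::log(p[0]) +
          (p[1] / p[2]) * (1.0 - std::exp(-p[2] * times[j]));
      return true;
    case 6: {
      NumericVector v;
      try {
        v = solve_simeoni_cpp(p[0], p[1], p[2], 20.0, times, rtol, atol);
      } catch (...) { return false; }
      for (int j = 0; j < n; ++j) {
        if (!(v[j] > 0) || !std::isfinite(v[j])) return false;
        out[j] = std::log(v[j]);
      }
      return true;
    }
  }
  return false;
}

static double obs_ll(int model, const std::vector<double>& phi,
                     const NumericVector& times, const NumericVector& logy,
                     double sigma, double rtol, double atol,
                     std::vector<double>& buf) {
  std::vector<double> p(phi.size());
  for (size_t k = 0; k < phi.size(); ++k) p[k] = std::exp(phi[k]);
  if (!predict_log_model(model, p, times, rtol, atol, buf))
    return R_NegInf;
  int n = logy.size();
  double ss = 0.0;
  for (int j = 0; j < n; ++j) {
    double r = logy[j] - buf[j];
    ss += r * r;
  }
  double ll = -0.5 * ss / (sigma * sigma) -
    n * (std::log(sigma) + 0.5 * std::log(2.0 * M_PI));
  if (!std::isfinite(ll)) return R_NegInf;
  return ll;
}

// [[Rcpp::export]]
NumericVector predict_log_cpp(int model, NumericVector par,
                              NumericVector times, double rtol, double atol) {
  std::vector<double> p(par.begin(), par.end()), out;
  if (!predict_log_model(model, p, times, rtol, atol, out))
    stop("structural model prediction failed");
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
double obs_ll_cpp(int model, NumericVector phi, NumericVector times,
                  NumericVector logy, double sigma, double rtol, double atol) {
  std::vector<double> f(phi.begin(), phi.end()), buf;
  return obs_ll(model, f, times, logy, sigma, rtol, atol, buf);
}

// One SAEM iteration's MCMC E-step over all animals. Kernels per animal:
// (1) one independence proposal from the current population distribution
//     N(mu, om_eff^2) (prior terms cancel against the proposal density),
// (2) n_mcmc - 1 joint random-walk proposals with per-animal adaptive scale,
// (3) optionally one componentwise random-walk sweep.
// Uses R's RNG so results are reproducible under set.seed().
// Modifies phi, ll_cur, prop_scale in place; returns residual sums of
// squares at the updated phi (for the sufficient-statistic update).
// [[Rcpp::export]]
NumericVector saem_estep_cpp(int model, NumericMatrix phi, NumericVector ll_cur,
                             NumericVector mu, NumericVector om_eff,
                             double sigma, NumericVector prop_scale,
                             List times, List logy, int n_mcmc, bool compwise,
                             double rtol, double atol) {
  int N = phi.nrow(), K = phi.ncol();
  RNGScope scope;
  std::vector<double> cur(K), cand(K), buf;
  NumericVector res2(N);
  for (int i = 0; i < N; ++i) {
    NumericVector ti = times[i];
    NumericVector yi = logy[i];
    for (int k = 0; k < K; ++k) cur[k] = phi(i, k);
    double pr_cur = 0.0;
    for (int k = 0; k < K; ++k) {
      double z = (cur[k] - mu[k]) / om_eff[k];
      pr_cur -= 0.5 * z * z;
    }
    // kernel 1: independence proposal
    {
      double pr_cand = 0.0;
      for (int k = 0; k < K; ++k) {
        double z = R::norm_rand();
        cand[k] = mu[k] + z * om_eff[k];
        pr_cand -= 0.5 * z * z;
      }
      double ll_cand = obs_ll(model, cand, ti, yi, sigma, rtol, atol, buf);
      if (std::isfinite(ll_cand) &&
          std::log(R::unif_rand()) < ll_cand - ll_cur[i]) {
        cur = cand; ll_cur[i] = ll_cand; pr_cur = pr_cand;
      }
    }
    // kernel 2: joint random walks
    for (int m = 1; m < n_mcmc; ++m) {
      double pr_cand = 0.0;
      for (int k = 0; k < K; ++k) {
        cand[k] = cur[k] + R::norm_rand() * prop_scale[i] * om_eff[k];
        double z = (cand[k] - mu[k]) / om_eff[k];
        pr_cand -= 0.5 * z * z;
      }
      double ll_cand = obs_ll(model, cand, ti, yi, sigma, rtol, atol, buf);
      bool acc = std::isfinite(ll_cand) &&
        std::log(R::unif_rand()) < ll_cand + pr_cand - ll_cur[i] - pr_cur;
      if (acc) { cur = cand; ll_cur[i] = ll_cand; pr_cur = pr_cand; }
      double s = prop_scale[i] * std::exp(0.02 * ((acc ? 1.0 : 0.0) - 0.3));
      prop_scale[i] = std::min(10.0, std::max(0.05, s));
    }
    // kernel 3: componentwise sweep
    if (compwise) {
      for (int k = 0; k < K; ++k) {
        cand = cur;
        cand[k] = cur[k] + R::norm_rand() * om_eff[k];
        double pr_cand = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          double z = (cand[kk] - mu[kk]) / om_eff[kk];
          pr_cand -= 0.5 * z * z;
        }
        double ll_cand = obs_ll(model, cand, ti, yi, sigma, rtol, atol, buf);
        if (std::isfinite(ll_cand) &&
            std::log(R::unif_rand()) < ll_cand + pr_cand - ll_cur[i] - pr_cur) {
          cur = cand; ll_cur[i] = ll_cand; pr_cur = pr_cand;
        }
      }
    }
    for (int k = 0; k < K; ++k) phi(i, k) = cur[k];
    // residual sum of squares at the retained phi
    std::vector<double> p(K);
    for (int k = 0; k < K; ++k) p[k] = std::exp(cur[k]);
    double ss = 0.0;
    if (predict_log_model(model, p, ti, rtol, atol, buf)) {
      for (int j = 0; j < yi.size(); ++j) {
        double r = yi[j] - buf[j];
        ss += r * r;
      }
    } else ss = NA_REAL;
    res2[i] = ss;
  }
  return res2;
}

// Importance-sampling observation log-likelihoods for one animal: evaluates
// obs_ll at M sampled phi vectors (rows of phi_s).
// [[Rcpp::export]]
NumericVector obs_ll_batch_cpp(int model, NumericMatrix phi_s,
                               NumericVector times, NumericVector logy,
                               double sigma, double rtol, double atol) {
  int M = phi_s.nrow(), K = phi_s.ncol();
  NumericVector out(M);
  std::vector<double> phi(K), buf;
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < K; ++k) phi[k] = phi_s(m, k);
    out[m] = obs_ll(model, phi, times, logy, sigma, rtol, atol, buf);
  }
  return out;
}
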