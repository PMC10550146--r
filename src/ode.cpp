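#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Dormand-Prince 5(4) adaptive integrator, specialized to the small fixed-size
// systems used in this package.  Error control: per-component
// |err| <= atol + rtol * max(|y_old|, |y_new|).

namespace {

struct FinalParams {
  double lambda, kang, kres, kcons, kdeath;
};

inline void rhs_final(const FinalParams& p, const double* y, double* dy) {
  // y = (TV, ANG, RES)
  dy[0] = p.lambda * y[0] * y[2] - p.kdeath * y[0];
  dy[1] = p.kang * y[0] - p.kdeath * y[1];
  dy[2] = p.kres * y[1] - p.kcons * y[0];
}

struct SimeoniParams {
  double l0, l1, psi;
};

inline void rhs_simeoni(const SimeoniParams& p, const double* y, double* dy) {
  // unperturbed exponential-to-linear growth with smooth switch exponent psi
  double r = p.l0 * y[0] / p.l1;
  double denom = std::pow(1.0 + std::pow(r, p.psi), 1.0 / p.psi);
  dy[0] = p.l0 * y[0] / denom;
}

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

template <int N, typename P, void (*RHS)(const P&, const double*, double*)>
void dp45_solve(const P& pars, const double* y0, const std::vector<double>& times,
                double rtol, double atol, double* out /* times.size() x N, row-major */) {
  double y[N], ynew[N], k1[N], k2[N], k3[N], k4[N], k5[N], k6[N], k7[N], ytmp[N];
  for (int i = 0; i < N; ++i) y[i] = y0[i];
  double t = 0.0;
  size_t iout = 0;
  // emit any outputs at (or numerically before) t = 0
  while (iout < times.size() && times[iout] <= t + 1e-12) {
    for (int i = 0; i < N; ++i) out[iout * N + i] = y[i];
    ++iout;
  }
  if (iout == times.size()) return;

  RHS(pars, y, k1);  // FSAL first stage
  double h = 1e-2;
  const double tend = times.back();
  const double hmin = 1e-12 * std::max(1.0, tend);
  long nstep = 0, maxstep = 1000000;

  while (t < tend && iout < times.size()) {
    if (++nstep > maxstep)
      stop("ODE solver exceeded step limit; last successful time %f", t);
    bool clipped = false;
    if (t + h > times[iout]) { h = times[iout] - t; clipped = true; }
    if (h < hmin) h = hmin;

    for (int i = 0; i < N; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    RHS(pars, ytmp, k2);
    for (int i = 0; i < N; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    RHS(pars, ytmp, k3);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    RHS(pars, ytmp, k4);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    RHS(pars, ytmp, k5);
    for (int i = 0; i < N; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] +
                            a65 * k5[i]);
    RHS(pars, ytmp, k6);
    for (int i = 0; i < N; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                            b6 * k6[i]);
    RHS(pars, ynew, k7);

    double errnorm = 0.0;
    for (int i = 0; i < N; ++i) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                              e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = (ynew[i] - y4) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / N);

    if (errnorm <= 1.0 || h <= hmin * 1.0001) {
      t += h;
      for (int i = 0; i < N; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }
      while (iout < times.size() && times[iout] <= t + 1e-12) {
        for (int i = 0; i < N; ++i) out[iout * N + i] = y[i];
        ++iout;
      }
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    double hprev = h;
    h = hprev * fac;
    if (clipped && errnorm <= 1.0) h = std::max(h, hprev * 5.0);  // recover from clipping
    if (h < hmin) {
      if (errnorm > 1.0)
        stop("ODE solver step size underflow; last successful time %f", t);
      h = hmin;
    }
  }
}

std::vector<double> as_times(const NumericVector& times) {
  std::vector<double> tt(times.begin(), times.end());
  for (size_t i = 0; i < tt.size(); ++i) {
    if (tt[i] < 0) stop("output times must be non-negative");
    if (i > 0 && tt[i] < tt[i - 1]) stop("output times must be non-decreasing");
  }
  return tt;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix solve_final_cpp(NumericVector pars, NumericVector init,
                              NumericVector times, double rtol, double atol) {
  // pars = (lambda, k_ang, k_res, k_consumption, k_death), init = (tv0, ang0, res0)
  if (pars.size() != 5) stop("pars must have length 5");
  if (init.size() != 3) stop("init must have length 3");
  FinalParams p{pars[0], pars[1], pars[2], pars[3], pars[4]};
  std::vector<double> tt = as_times(times);
  NumericMatrix out(tt.size(), 3);
  std::vector<double> buf(tt.size() * 3);
  double y0[3] = {init[0], init[1], init[2]};
  dp45_solve<3, FinalParams, rhs_final>(p, y0, tt, rtol, atol, buf.data());
  for (size_t i = 0; i < tt.size(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = buf[i * 3 + j];
  colnames(out) = CharacterVector::create("tv", "ang", "res");
  return out;
}

// [[Rcpp::export]]
NumericVector solve_simeoni_cpp(double tv0, double l0, double l1, double psi,
                                NumericVector times, double rtol, double atol) {
  SimeoniParams p{l0, l1, psi};
  std::vector<double> tt = as_times(times);
  std::vector<double> buf(tt.size());
  double y0[1] = {tv0};
  dp45_solve<1, SimeoniParams, rhs_simeoni>(p, y0, tt, rtol, atol, buf.data());
  return NumericVector(buf.begin(), buf.end());
}
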