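#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

static inline double wrap_deg(double w) {
  w -= 360.0 * std::floor((w + 180.0) / 360.0);  // [-180, 180)
  if (w <= -180.0) w += 360.0;                   // -> (-180, 180]
  return w;
}

static inline double torsion_u(double w, const NumericVector &n,
                               const NumericVector &v,
                               const NumericVector &g) {
  double u = 0.0;
  for (int i = 0; i < n.size(); ++i)
    u += 0.5 * v[i] * (1.0 + std::cos((n[i] * w - g[i]) * DEG));
  return u;
}

// Metropolis chain on the boosted potential U* = U + dV. Proposals are
// symmetric uniform perturbations of half-width `width` degrees, so the
// acceptance rule exp(-(U*' - U*)/kT) satisfies detailed balance.
// Every post-burn-in step is retained. Uses R's RNG for reproducibility.
// [[Rcpp::export]]
List metropolis_omega(NumericVector n_mult, NumericVector v_n,
                      NumericVector gamma_deg, double boost_E, double boost_k,
                      bool has_boost, double kT, int n_frames, int burn_in,
                      double width, double omega0) {
  NumericVector omega(n_frames), dv_out(n_frames);
  double w = wrap_deg(omega0);
  double u = torsion_u(w, n_mult, v_n, gamma_deg);
  double dv = (has_boost && u < boost_E)
                  ? 0.5 * boost_k * (boost_E - u) * (boost_E - u)
                  : 0.0;
  double ustar = u + dv;
  long total = (long)n_frames + burn_in;
  for (long step = 0; step < total; ++step) {
    double wp = wrap_deg(w + (2.0 * R::runif(0.0, 1.0) - 1.0) * width);
    double up = torsion_u(wp, n_mult, v_n, gamma_deg);
    double dvp = (has_boost && up < boost_E)
                     ? 0.5 * boost_k * (boost_E - up) * (boost_E - up)
                     : 0.0;
    double ustarp = up + dvp;
    if (ustarp <= ustar || R::runif(0.0, 1.0) < std::exp(-(ustarp - ustar) / kT)) {
      w = wp; dv = dvp; ustar = ustarp;
    }
    if (step >= burn_in) {
      omega[step - burn_in] = w;
      dv_out[step - burn_in] = dv;
    }
  }
  return List::create(_["omega"] = omega, _["deltaV"] = dv_out);
}
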