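#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-compartment exchange model residue function R(t).
// Flow/exchange parameters are in ml/min per ml tissue; time in seconds,
// so rates are divided by 60. R(t) = A exp(l1 t) + (1-A) exp(l2 t) with
// l1, l2 the eigenvalues of the plasma/interstitium exchange system:
//   vp dCp/dt = Fp (Ca - Cp) + PS (Ce - Cp)
//   ve dCe/dt = PS (Cp - Ce)
// R(0) = 1 and, for Fp > 0, integral(R) = (vp + ve) / Fp (mean transit time).
static void cxm_residue(double Fp, double PS, double vp, double ve,
                        const double *t, int n, double *R) {
  const double fs = Fp / 60.0, ps = PS / 60.0;
  const double a = (fs + ps) / vp;
  const double b = ps / ve;
  const double disc = (a + b) * (a + b) - 4.0 * b * fs / vp;
  const double sq = std::sqrt(disc > 0.0 ? disc : 0.0);

  if (sq > 1e-12 * (a + b)) {
    const double l1 = 0.5 * (-(a + b) + sq);
    const double l2 = 0.5 * (-(a + b) - sq);
    const double A = (vp * (l1 + b) + ve * b) / (vp * (l1 - l2));
    for (int i = 0; i < n; ++i)
      R[i] = A * std::exp(l1 * t[i]) + (1.0 - A) * std::exp(l2 * t[i]);
  } else {
    // confluent (equal-eigenvalue) limit
    const double l = -0.5 * (a + b);
    const double c = (l + b) + (ve / vp) * b;
    for (int i = 0; i < n; ++i)
      R[i] = (1.0 + c * t[i]) * std::exp(l * t[i]);
  }
}

// [[Rcpp::export(name = ".cxm_impulse_cpp")]]
NumericVector cxm_impulse_cpp(double Fp, double PS, double vp, double ve,
                              NumericVector times) {
  int n = times.size();
  NumericVector out(n);
  cxm_residue(Fp, PS, vp, ve, times.begin(), n, out.begin());
  return out;
}

// linear interpolation of (x, y) at xi; sorted x; value 0 left of x[0],
// clamped to y[n-1] right of x[n-1]
static double interp_zero_left(const double *x, const double *y, int n,
                               double xi) {
  if (xi < x[0]) return 0.0;
  if (xi >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= xi) lo = mid; else hi = mid;
  }
  double w = (xi - x[lo]) / (x[lo + 1] - x[lo]);
  return (1.0 - w) * y[lo] + w * y[lo + 1];
}

// Tissue curve Fp * (Ca(t - t0) conv R)(t) on the output time grid.
// The convolution runs on a uniform internal grid of step dt spanning
// [aifTimes[0], max(outTimes, aifTimes)] with trapezoid weights; the AIF is
// linearly interpolated (zero before its first sample) and the result is
// linearly interpolated back onto outTimes.
// [[Rcpp::export(name = ".cxm_forward_cpp")]]
NumericVector cxm_forward_cpp(NumericVector outTimes, NumericVector aifTimes,
                              NumericVector aifValues, double Fp, double PS,
                              double vp, double ve, double t0, double dt) {
  const int nOut = outTimes.size(), nA = aifTimes.size();
  const double tmin = aifTimes[0];
  double tmax = outTimes[nOut - 1];
  if (aifTimes[nA - 1] > tmax) tmax = aifTimes[nA - 1];

  const int m = (int)std::ceil((tmax - tmin) / dt) + 1;
  std::vector<double> grid(m), ca(m), res(m), ct(m);
  for (int i = 0; i < m; ++i) {
    grid[i] = tmin + i * dt;
    ca[i] = interp_zero_left(aifTimes.begin(), aifValues.begin(), nA,
                             grid[i] - t0);
  }
  // residue argument is the lag i*dt, not absolute time
  std::vector<double> lag(m);
  for (int i = 0; i < m; ++i) lag[i] = i * dt;
  cxm_residue(Fp, PS, vp, ve, lag.data(), m, res.data());

  const double fs = Fp / 60.0;
  for (int k = 0; k < m; ++k) {
    double acc = 0.0;
    for (int j = 0; j <= k; ++j) {
      double w = (j == 0 || j == k) ? 0.5 : 1.0;
      acc += w * ca[j] * res[k - j];
    }
    ct[k] = fs * dt * acc;
  }
  ct[0] = 0.0; // zero-width integral

  NumericVector out(nOut);
  for (int i = 0; i < nOut; ++i)
    out[i] = interp_zero_left(grid.data(), ct.data(), m, outTimes[i]);
  return out;
}
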