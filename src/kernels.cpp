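#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Approximate entropy (classical Pincus form, self-matches included).
// Chebyshev distance, counts for embedding lengths m and m+1 in one
// pairwise sweep; O(N^2 * m) time, O(N) memory.
// [[Rcpp::export]]
double apen_kernel(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (n <= m + 1) stop("series too short for the requested embedding");
  if (r < 0) stop("tolerance r must be non-negative");
  const int nm = n - m + 1;   // number of length-m templates
  const int nm1 = n - m;      // number of length-(m+1) templates
  std::vector<double> cm(nm, 1.0), cm1(nm1, 1.0);  // self-matches
  const double *xs = REAL(x);
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(xs[i + k] - xs[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) {
        cm[i] += 1.0; cm[j] += 1.0;
        if (i < nm1 && j < nm1) {
          double a = std::fabs(xs[i + m] - xs[j + m]);
          if (a > d) d = a;
          if (d <= r) { cm1[i] += 1.0; cm1[j] += 1.0; }
        }
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i) phim += std::log(cm[i] / nm);
  phim /= nm;
  for (int i = 0; i < nm1; ++i) phim1 += std::log(cm1[i] / nm1);
  phim1 /= nm1;
  return phim - phim1;
}

// Hampel running-median despiking. Centered window of 2*halfwin+1
// samples; a sample deviating from the window median by more than
// t0 * 1.4826 * MAD is replaced by that median. Edge samples without a
// full window are left untouched. Returns filtered series and 1-based
// indices of replaced samples.
// [[Rcpp::export]]
List hampel_kernel(NumericVector x, int halfwin, double t0) {
  const int n = x.size();
  if (halfwin < 1) stop("window must span at least 3 samples");
  if (2 * halfwin + 1 > n) stop("window longer than the series");
  NumericVector y = clone(x);
  std::vector<int> idx;
  const int w = 2 * halfwin + 1;
  std::vector<double> buf(w), dev(w);
  const double *xs = REAL(x);
  for (int i = halfwin; i < n - halfwin; ++i) {
    for (int k = 0; k < w; ++k) buf[k] = xs[i - halfwin + k];
    std::nth_element(buf.begin(), buf.begin() + halfwin, buf.end());
    double med = buf[halfwin];
    for (int k = 0; k < w; ++k) dev[k] = std::fabs(xs[i - halfwin + k] - med);
    std::nth_element(dev.begin(), dev.begin() + halfwin, dev.end());
    double s0 = 1.4826 * dev[halfwin];
    if (std::fabs(xs[i] - med) > t0 * s0) {
      y[i] = med;
      idx.push_back(i + 1);
    }
  }
  return List::create(_["y"] = y, _["ind"] = wrap(idx));
}
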