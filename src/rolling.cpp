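#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Type-7 quantile (R's default) on an already-sorted window.
static inline double q7(const std::vector<double>& w, double p) {
  const int n = (int)w.size();
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const double g = h - lo;
  if (g == 0.0) return w[lo];
  return w[lo] + g * (w[lo + 1] - w[lo]);
}

// Sliding order-statistic window over x (step 1): the window is kept as a
// sorted vector updated by binary-search insert/erase, giving direct access
// to the median and quartiles of every window of `window` consecutive
// values. Emits n - window + 1 rows.
// [[Rcpp::export]]
List roll_quantiles_cpp(NumericVector x, int window) {
  const int n = x.size();
  if (window < 1 || window > n) stop("window must be in [1, length(x)]");
  const int m = n - window + 1;
  NumericVector med(m), q25(m), q75(m);
  std::vector<double> w(x.begin(), x.begin() + window);
  std::sort(w.begin(), w.end());
  for (int i = 0;; ++i) {
    // median as R computes it: mean of the two central order statistics
    if (window % 2 == 1) {
      med[i] = w[window / 2];
    } else {
      med[i] = (w[window / 2 - 1] + w[window / 2]) / 2.0;
    }
    q25[i] = q7(w, 0.25);
    q75[i] = q7(w, 0.75);
    if (i == m - 1) break;
    const double out = x[i];
    const double in = x[i + window];
    w.erase(std::lower_bound(w.begin(), w.end(), out));
    w.insert(std::upper_bound(w.begin(), w.end(), in), in);
  }
  return List::create(_["median"] = med, _["q25"] = q25, _["q75"] = q75);
}

// Bootstrap medians: n_boot resamples (with replacement, R's RNG stream)
// of x, median of each via nth_element.
// [[Rcpp::export]]
NumericVector boot_median_cpp(NumericVector x, int n_boot) {
  const int n = x.size();
  NumericVector out(n_boot);
  std::vector<double> buf(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j == n) j = n - 1;
      buf[i] = x[j];
    }
    const int mid = n / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (n % 2 == 0) {
      const double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      m = (lo + m) / 2.0;
    }
    out[b] = m;
  }
  return out;
}
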