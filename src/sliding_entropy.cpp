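#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window entropy of a single-channel signal.
//
// Windows of width w start at 0, delta, 2*delta, ... while start + w <= L;
// in each window an equal-width amplitude histogram over [min, max] with
// nbins bins gives probabilities P_i = count_i / w, and the entropy is
// Tsallis (1 - sum P_i^q) / (q - 1) for q != 1 or Shannon -sum P_i ln P_i
// for q == 1. A degenerate window (min == max) has a single bin, P = 1,
// entropy 0. Returns a matrix with one row per window and one column per q.
// [[Rcpp::export(name = ".sliding_entropy_cpp")]]
NumericMatrix sliding_entropy_cpp(NumericVector x, int w, int delta,
                                  int nbins, NumericVector qs) {
  const int L = x.size();
  if (w < 2) stop("window width must be >= 2");
  if (delta < 1 || delta > w) stop("step must satisfy 1 <= step <= width");
  if (L < w) stop("signal shorter than one window");
  if (nbins < 1) stop("nbins must be >= 1");
  const int n_win = (L - w) / delta + 1;
  const int n_q = qs.size();
  NumericMatrix out(n_win, n_q);
  std::vector<int> counts(nbins);

  for (int wi = 0; wi < n_win; ++wi) {
    const int s = wi * delta;
    double mn = x[s], mx = x[s];
    for (int j = s; j < s + w; ++j) {
      if (!R_finite(x[j])) stop("non-finite sample in window");
      if (x[j] < mn) mn = x[j];
      if (x[j] > mx) mx = x[j];
    }
    std::fill(counts.begin(), counts.end(), 0);
    if (mx == mn) {
      counts[0] = w;
    } else {
      const double scale = nbins / (mx - mn);
      for (int j = s; j < s + w; ++j) {
        int b = (int)std::floor((x[j] - mn) * scale);
        if (b >= nbins) b = nbins - 1;
        if (b < 0) b = 0;
        counts[b]++;
      }
    }
    for (int qi = 0; qi < n_q; ++qi) {
      const double q = qs[qi];
      double e = 0.0;
      if (q == 1.0) {
        for (int b = 0; b < nbins; ++b) {
          if (counts[b] > 0) {
            const double p = (double)counts[b] / w;
            e -= p * std::log(p);
          }
        }
      } else {
        double s_pq = 0.0;
        for (int b = 0; b < nbins; ++b) {
          if (counts[b] > 0) {
            const double p = (double)counts[b] / w;
            s_pq += std::pow(p, q);
          }
        }
        e = (1.0 - s_pq) / (q - 1.0);
      }
      out(wi, qi) = e;
    }
  }
  return out;
}
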