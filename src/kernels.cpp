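#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect an out-of-range index back into [0, n-1].
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2-D median filter with reflected edges; kr x kc must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_2d(const NumericMatrix& img, int kr, int kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> win((size_t)kr * kc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t m = 0;
      for (int dj = -hc; dj <= hc; ++dj) {
        const int jj = reflect(j + dj, nc);
        for (int di = -hr; di <= hr; ++di) {
          win[m++] = img(reflect(i + di, nr), jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
      out(i, j) = win[m / 2];
    }
  }
  return out;
}

// Shear-alignment scores for the streak-angle estimator.
//
// For each candidate per-line shift s (pixels per line, signed), every row r
// is displaced by round(s * r) columns onto a wide canvas and the image is
// averaged down each canvas column. The raw score is the count-weighted
// variance of the column means; since columns with few samples inflate that
// variance by sigma^2/n_c purely through sampling noise, the pooled
// within-column variance is subtracted (one-way ANOVA decomposition), so a
// shear that merely scatters pixels scores ~0 while the shift matching the
// streak slope keeps the full shadow/plasma contrast.
// [[Rcpp::export]]
NumericVector shear_scores(const NumericMatrix& img, const NumericVector& shifts) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ns = shifts.size();
  NumericVector scores(ns);
  std::vector<double> sum, sumsq;
  std::vector<int> cnt;
  for (int s = 0; s < ns; ++s) {
    const double sh = shifts[s];
    // offset range over rows
    long omin = 0, omax = 0;
    for (int r = 0; r < nr; ++r) {
      long o = (long)std::lround(sh * r);
      if (o < omin) omin = o;
      if (o > omax) omax = o;
    }
    const long width = (long)nc + (omax - omin);
    sum.assign((size_t)width, 0.0);
    sumsq.assign((size_t)width, 0.0);
    cnt.assign((size_t)width, 0);
    for (int r = 0; r < nr; ++r) {
      const long o = (long)std::lround(sh * r) - omin;
      for (int c = 0; c < nc; ++c) {
        const double v = img(r, c);
        sum[(size_t)(o + c)] += v;
        sumsq[(size_t)(o + c)] += v * v;
        cnt[(size_t)(o + c)] += 1;
      }
    }
    double tot = 0.0; long ntot = 0, ncols = 0;
    for (long c = 0; c < width; ++c) {
      if (cnt[(size_t)c] > 0) { tot += sum[(size_t)c]; ntot += cnt[(size_t)c]; ++ncols; }
    }
    const double grand = tot / (double)ntot;
    double between = 0.0, within = 0.0;
    for (long c = 0; c < width; ++c) {
      const int n = cnt[(size_t)c];
      if (n > 0) {
        const double mu = sum[(size_t)c] / n;
        between += n * (mu - grand) * (mu - grand);
        within += sumsq[(size_t)c] - n * mu * mu;
      }
    }
    double score = between;
    if (ntot > ncols) {
      const double ms_within = within / (double)(ntot - ncols);
      score -= (double)(ncols - 1) * ms_within;
    }
    scores[s] = score / (double)ntot;
  }
  return scores;
}
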