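#include <Rcpp.h>
using namespace Rcpp;

// Second-order-sections IIR filter, direct form II transposed.
// sos: k x 6 matrix (b0 b1 b2 a0 a1 a2), a0 assumed 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int nsec = sos.nrow();
  const int n = x.size();
  NumericVector y = clone(x);
  std::vector<double> z1(nsec, 0.0), z2(nsec, 0.0);
  for (int i = 0; i < n; ++i) {
    double v = y[i];
    for (int s = 0; s < nsec; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double w = v;
      v = b0 * w + z1[s];
      z1[s] = b1 * w - a1 * v + z2[s];
      z2[s] = b2 * w - a2 * v;
    }
    y[i] = v;
  }
  return y;
}

// Nonlinear correlation coefficient h2 of y given x: equal-width binning of
// the x range, knots at per-bin means, piecewise-linear interpolation with
// linear extrapolation from the outer segments, explained-variance ratio
// clamped to [0, 1]. Degenerate inputs (constant x or y, fewer than two
// non-empty bins) give 0.
static double h2_core(const double* x, const double* y, int n, int bins,
                      std::vector<double>& kx, std::vector<double>& ky,
                      std::vector<int>& cnt) {
  double xmin = x[0], xmax = x[0], ysum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    ysum += y[i];
  }
  const double ymean = ysum / n;
  double sstot = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = y[i] - ymean;
    sstot += d * d;
  }
  if (sstot <= 0.0 || xmax <= xmin) return 0.0;

  kx.assign(bins, 0.0);
  ky.assign(bins, 0.0);
  cnt.assign(bins, 0);
  const double inv_w = bins / (xmax - xmin);
  for (int i = 0; i < n; ++i) {
    int b = (int)((x[i] - xmin) * inv_w);
    if (b >= bins) b = bins - 1;
    if (b < 0) b = 0;
    kx[b] += x[i];
    ky[b] += y[i];
    cnt[b] += 1;
  }
  int nk = 0;
  for (int b = 0; b < bins; ++b) {
    if (cnt[b] > 0) {
      kx[nk] = kx[b] / cnt[b];
      ky[nk] = ky[b] / cnt[b];
      ++nk;
    }
  }
  if (nk < 2) return 0.0;

  double ssres = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    // locate segment: knots are sorted (bins are ordered intervals)
    int j = 0;
    if (xi <= kx[0]) j = 0;
    else if (xi >= kx[nk - 1]) j = nk - 2;
    else {
      int lo = 0, hi = nk - 1;
      while (hi - lo > 1) {
        const int mid = (lo + hi) / 2;
        if (kx[mid] <= xi) lo = mid; else hi = mid;
      }
      j = lo;
    }
    const double f = ky[j] + (ky[j + 1] - ky[j]) *
      ((xi - kx[j]) / (kx[j + 1] - kx[j]));
    const double r = y[i] - f;
    ssres += r * r;
  }
  double h2 = 1.0 - ssres / sstot;
  if (h2 < 0.0) h2 = 0.0;
  if (h2 > 1.0) h2 = 1.0;
  return h2;
}

// [[Rcpp::export]]
double h2_pair_cpp(NumericVector x, NumericVector y, int bins) {
  std::vector<double> kx, ky;
  std::vector<int> cnt;
  return h2_core(REAL(x), REAL(y), x.size(), bins, kx, ky, cnt);
}

// Correlated-pair count per sliding window: for each window position,
// count ordered pairs (driver, response) whose h2 strictly exceeds s1.
// signals: channels x samples; pairs: m x 2 (1-based channel indices).
// [[Rcpp::export]]
IntegerVector sliding_counts_cpp(NumericMatrix signals, IntegerMatrix pairs,
                                 int window_len, int window_step,
                                 double s1, int bins) {
  const int nch = signals.nrow();
  const int ns = signals.ncol();
  const int npair = pairs.nrow();
  const int nwin = (ns - window_len) / window_step + 1;
  IntegerVector counts(nwin);
  std::vector<double> xv(window_len), yv(window_len);
  std::vector<double> kx, ky;
  std::vector<int> cnt;
  // signals is column-major (R): copy each window's channels row-wise
  std::vector< std::vector<double> > win((size_t)nch,
                                         std::vector<double>(window_len));
  for (int w = 0; w < nwin; ++w) {
    const int off = w * window_step;
    for (int ch = 0; ch < nch; ++ch) {
      double* dst = win[ch].data();
      for (int t = 0; t < window_len; ++t)
        dst[t] = signals(ch, off + t);
    }
    int c = 0;
    for (int p = 0; p < npair; ++p) {
      const int xi = pairs(p, 0) - 1;
      const int yi = pairs(p, 1) - 1;
      const double h2 = h2_core(win[xi].data(), win[yi].data(), window_len,
                                bins, kx, ky, cnt);
      if (h2 > s1) ++c;
    }
    counts[w] = c;
  }
  return counts;
}
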