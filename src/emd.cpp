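#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Strict local extrema by sign change of the first difference; a flat plateau
// contributes its midpoint (floored) once. Indices are 0-based internally.
static void extrema_idx(const std::vector<double>& x,
                        std::vector<int>& maxima, std::vector<int>& minima) {
  const int n = (int)x.size();
  maxima.clear(); minima.clear();
  int prev_sign = 0;
  int plateau_start = -1;
  for (int k = 1; k < n; ++k) {
    double d = x[k] - x[k - 1];
    int s = (d > 0.0) - (d < 0.0);
    if (s == 0) {
      if (plateau_start < 0) plateau_start = k - 1;
      continue;
    }
    int at = (plateau_start >= 0) ? (plateau_start + (k - 1)) / 2 : (k - 1);
    if (prev_sign > 0 && s < 0) maxima.push_back(at);
    else if (prev_sign < 0 && s > 0) minima.push_back(at);
    prev_sign = s;
    plateau_start = -1;
  }
}

// Natural cubic spline through (t, y), evaluated at integer abscissae 0..n-1.
// Second derivatives solved by the Thomas algorithm; linear if only 2 knots.
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, std::vector<double>& out) {
  const int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  std::vector<double> h(m - 1), M(m, 0.0), a(m, 0.0), b(m, 0.0), c(m, 0.0), r(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  // interior rows of the tridiagonal system; natural ends M[0]=M[m-1]=0
  for (int i = 1; i < m - 1; ++i) {
    a[i] = h[i - 1];
    b[i] = 2.0 * (h[i - 1] + h[i]);
    c[i] = h[i];
    r[i] = 6.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  }
  for (int i = 2; i < m - 1; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    r[i] -= w * r[i - 1];
  }
  for (int i = m - 2; i >= 1; --i)
    M[i] = (r[i] - c[i] * (i + 1 < m - 1 ? M[i + 1] : 0.0)) / b[i];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double xi = (double)i;
    while (seg < m - 2 && xi > t[seg + 1]) ++seg;
    // extrapolation beyond the extended knots keeps the end segment's cubic
    double hh = h[seg];
    double A = (t[seg + 1] - xi) / hh, B = (xi - t[seg]) / hh;
    out[i] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hh * hh / 6.0;
  }
}

// Mirror-extend the two extrema nearest each end about the first/last sample,
// then spline through the extended knots.
static void envelope(const std::vector<double>& x, const std::vector<int>& idx,
                     std::vector<double>& out) {
  const int n = (int)x.size();
  const int m = (int)idx.size();
  std::vector<double> t, y;
  t.reserve(m + 4); y.reserve(m + 4);
  // left reflections about sample 0: positions -idx[j], farthest first
  for (int j = std::min(2, m) - 1; j >= 0; --j) {
    double pos = -(double)idx[j];
    if (pos < (double)idx[0]) { t.push_back(pos); y.push_back(x[idx[j]]); }
  }
  for (int j = 0; j < m; ++j) { t.push_back((double)idx[j]); y.push_back(x[idx[j]]); }
  // right reflections about sample n-1
  for (int j = m - 1; j >= std::max(0, m - 2); --j) {
    double pos = 2.0 * (n - 1) - (double)idx[j];
    if (pos > (double)idx[m - 1]) { t.push_back(pos); y.push_back(x[idx[j]]); }
  }
  natural_spline_eval(t, y, n, out);
}

static inline bool siftable(const std::vector<int>& mx, const std::vector<int>& mn) {
  return mx.size() >= 1 && mn.size() >= 1 && mx.size() + mn.size() >= 2;
}

// One IMF by fixed-count sifting. Returns (imf, completed_all_iterations).
static bool sift_one(std::vector<double>& h, int iterations) {
  const int n = (int)h.size();
  std::vector<int> mx, mn;
  std::vector<double> eu, el;
  for (int it = 0; it < iterations; ++it) {
    extrema_idx(h, mx, mn);
    if (!siftable(mx, mn)) return false;
    envelope(h, mx, eu);
    envelope(h, mn, el);
    for (int i = 0; i < n; ++i) h[i] -= 0.5 * (eu[i] + el[i]);
  }
  return true;
}

// [[Rcpp::export(name = ".find_extrema_cpp")]]
List find_extrema_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> mx, mn;
  extrema_idx(xv, mx, mn);
  IntegerVector M(mx.size()), N(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) M[i] = mx[i] + 1;  // 1-based for R
  for (size_t i = 0; i < mn.size(); ++i) N[i] = mn[i] + 1;
  return List::create(_["maxima"] = M, _["minima"] = N);
}

// [[Rcpp::export(name = ".spline_envelopes_cpp")]]
List spline_envelopes_cpp(NumericVector x, IntegerVector maxima, IntegerVector minima) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> mx(maxima.size()), mn(minima.size());
  for (int i = 0; i < maxima.size(); ++i) mx[i] = maxima[i] - 1;
  for (int i = 0; i < minima.size(); ++i) mn[i] = minima[i] - 1;
  std::vector<double> eu, el;
  envelope(xv, mx, eu);
  envelope(xv, mn, el);
  NumericVector U(eu.begin(), eu.end()), L(el.begin(), el.end());
  NumericVector M(x.size());
  for (int i = 0; i < x.size(); ++i) M[i] = 0.5 * (U[i] + L[i]);
  return List::create(_["upper"] = U, _["lower"] = L, _["mean"] = M);
}

// [[Rcpp::export(name = ".sift_imf_cpp")]]
List sift_imf_cpp(NumericVector x, int sift_iterations) {
  std::vector<double> h(x.begin(), x.end());
  bool complete = sift_one(h, sift_iterations);
  NumericVector C(h.begin(), h.end());
  NumericVector R(x.size());
  for (int i = 0; i < x.size(); ++i) R[i] = x[i] - C[i];
  return List::create(_["imf"] = C, _["residual_after"] = R,
                      _["completed"] = complete);
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int sift_iterations, int max_imfs) {
  const int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> mx, mn;
  for (int k = 0; k < max_imfs; ++k) {
    extrema_idx(r, mx, mn);
    if (!siftable(mx, mn)) break;   // residual monotone or <= 1 extremum
    std::vector<double> h(r);
    sift_one(h, sift_iterations);
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }
  NumericMatrix C(n, (int)imfs.size());
  for (size_t k = 0; k < imfs.size(); ++k)
    std::copy(imfs[k].begin(), imfs[k].end(), C.column((int)k).begin());
  NumericVector R(r.begin(), r.end());
  return List::create(_["imfs"] = C, _["residual"] = R);
}

// 2-D moving-average smoothing with shrinking edge windows (constants are
// preserved exactly). kr/kc are kernel extents along rows / columns.
// [[Rcpp::export(name = ".box_smooth2d_cpp")]]
NumericMatrix box_smooth2d_cpp(NumericMatrix M, int kr, int kc) {
  const int nr = M.nrow(), nc = M.ncol();
  NumericMatrix A(nr, nc), B(nr, nc);
  const int hr = kr / 2, hc = kc / 2;
  // along columns (time)
  for (int i = 0; i < nr; ++i) {
    std::vector<double> cs(nc + 1, 0.0);
    for (int j = 0; j < nc; ++j) cs[j + 1] = cs[j] + M(i, j);
    for (int j = 0; j < nc; ++j) {
      int lo = std::max(0, j - hc), hi = std::min(nc - 1, j + hc);
      A(i, j) = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
  // along rows (frequency)
  for (int j = 0; j < nc; ++j) {
    std::vector<double> cs(nr + 1, 0.0);
    for (int i = 0; i < nr; ++i) cs[i + 1] = cs[i] + A(i, j);
    for (int i = 0; i < nr; ++i) {
      int lo = std::max(0, i - hr), hi = std::min(nr - 1, i + hr);
      B(i, j) = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
  return B;
}

// EEMD ensemble loop: noise matrix is generated in R (seeded there) and passed
// in; this averages member IMF matrices index-wise with zero-padding at the
// slow end.
// [[Rcpp::export(name = ".eemd_cpp")]]
List eemd_cpp(NumericVector x, NumericMatrix noise, int sift_iterations, int max_imfs) {
  const int n = x.size();
  const int NE = noise.ncol();
  std::vector<std::vector<double> > acc;  // summed IMFs
  for (int j = 0; j < NE; ++j) {
    std::vector<double> r(n);
    for (int i = 0; i < n; ++i) r[i] = x[i] + noise(i, j);
    std::vector<int> mx, mn;
    for (int k = 0; k < max_imfs; ++k) {
      extrema_idx(r, mx, mn);
      if (!siftable(mx, mn)) break;
      std::vector<double> h(r);
      sift_one(h, sift_iterations);
      if ((int)acc.size() <= k) acc.push_back(std::vector<double>(n, 0.0));
      for (int i = 0; i < n; ++i) { acc[k][i] += h[i]; r[i] -= h[i]; }
    }
  }
  NumericMatrix C(n, (int)acc.size());
  for (size_t k = 0; k < acc.size(); ++k)
    for (int i = 0; i < n; ++i) C(i, (int)k) = acc[k][i] / NE;
  return List::create(_["imfs"] = C);
}
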