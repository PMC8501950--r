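#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Connected-component labelling of a binary mask, 8-connectivity.
// Labels are assigned 1..n in raster-scan order of first encounter,
// so the output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_objects") = next;
  return lab;
}

// Fill interior holes: background (4-connected) not reachable from the
// image border becomes foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  auto push_if_bg = [&](int r, int c) {
    size_t i = static_cast<size_t>(r) + static_cast<size_t>(c) * nr;
    if (!mask(r, c) && !outside[i]) {
      outside[i] = 1;
      stack.push_back(r + c * nr);
    }
  };
  for (int r = 0; r < nr; ++r) { push_if_bg(r, 0); push_if_bg(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push_if_bg(0, c); push_if_bg(nr - 1, c); }
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr4[k], c2 = c + dc4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      push_if_bg(r2, c2);
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) ||
        !outside[static_cast<size_t>(r) + static_cast<size_t>(c) * nr];
  return out;
}

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary mask: distance from each
// foreground pixel to the nearest background pixel (0 on background).
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns first
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// Separable sliding-window maximum filter with a square (2*radius+1) window.
// [[Rcpp::export]]
NumericMatrix cpp_maxfilter(const NumericMatrix& x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      int lo = std::max(0, r - radius), hi = std::min(nr - 1, r + radius);
      for (int k = lo; k <= hi; ++k) m = std::max(m, x(k, c));
      tmp(r, c) = m;
    }
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double m = -std::numeric_limits<double>::infinity();
      int lo = std::max(0, c - radius), hi = std::min(nc - 1, c + radius);
      for (int k = lo; k <= hi; ++k) m = std::max(m, tmp(r, k));
      out(r, c) = m;
    }
  }
  return out;
}

// Marker-based watershed on the NEGATIVE of `elev` (flood from seeds in
// order of decreasing elevation), restricted to `mask`. Seeds carry labels
// > 0. FIFO tie-break makes the flood deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev,
                            const IntegerMatrix& seeds,
                            const LogicalMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  struct Node { double v; long long order; int idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.v != b.v) return a.v < b.v;   // highest elevation first
      return a.order > b.order;           // then FIFO
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long counter = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({elev(r, c), counter++, r + c * nr});
      }
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr4[k], c2 = c + dc4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      pq.push({elev(r2, c2), counter++, r2 + c2 * nr});
    }
  }
  return lab;
}
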