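// Low-level raster primitives used by the segmentation and feature code.
// All functions treat matrices in R's column-major layout; (i, j) = (row, col),
// 0-based internally, and are deterministic (no RNG).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// 8- and 4-neighbourhood offsets (row, col)
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Connected-component labelling of a logical mask. Labels are assigned in
// raster-scan order of each component's first pixel, so the result is
// deterministic. connectivity: 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity = 8) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int* DR = (connectivity == 4) ? DR4 : DR8;
  const int* DC = (connectivity == 4) ? DC4 : DC8;
  int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + DR[k], qj = pj + DC[k];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2004).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -DBL_MAX; z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from each pixel to the nearest TRUE
// pixel of `mask`. Pixels of the mask itself get 0. All-false mask -> Inf.
// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d2(H, W);
  const double INF = 1e18;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d2(i, j) = mask(i, j) ? 0.0 : INF;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {            // columns
    for (int i = 0; i < H; ++i) f[i] = d2(i, j);
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {            // rows
    for (int j = 0; j < W; ++j) f[j] = d2(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) d2(i, j) = d[j];
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d2(i, j) = (d2(i, j) >= INF) ? R_PosInf : std::sqrt(d2(i, j));
  return d2;
}

struct QNode {
  double prio; int order; int idx; int label;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // lower priority first
    return a.order > b.order;                       // FIFO tie-break
  }
};

// Marker-based watershed / seeded region growing. Seeds (label > 0) flood the
// priority surface in increasing order of `prio`; every pixel with
// mask == TRUE receives the label of the seed that reaches it first.
// Deterministic: ties broken by insertion order.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerMatrix watershed_seeded(const NumericMatrix& prio,
                               const IntegerMatrix& seeds,
                               const LogicalMatrix& mask) {
  int H = prio.nrow(), W = prio.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  int order = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push(QNode{prio(i, j), order++, i + j * H, seeds(i, j)});
      }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int pi = nd.idx % H, pj = nd.idx / H;
    for (int k = 0; k < 4; ++k) {
      int qi = pi + DR4[k], qj = pj + DC4[k];
      if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
      if (!mask(qi, qj) || lab(qi, qj) != 0) continue;
      lab(qi, qj) = nd.label;
      double p = prio(qi, qj);
      if (p < nd.prio) p = nd.prio;  // flood never runs downhill
      pq.push(QNode{p, order++, qi + qj * H, nd.label});
    }
  }
  return lab;
}

// Separable Gaussian blur with edge replication. sigma <= 0 returns a copy.
// [[Rcpp::export(name = ".gauss_blur")]]
NumericMatrix gauss_blur(const NumericMatrix& img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  if (sigma <= 0) { std::copy(img.begin(), img.end(), out.begin()); return out; }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) { k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += k[t + r]; }
  for (double& v : k) v /= s;
  NumericMatrix tmp(H, W);
  for (int j = 0; j < W; ++j)            // vertical pass
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t; if (ii < 0) ii = 0; if (ii >= H) ii = H - 1;
        acc += k[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)            // horizontal pass
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t; if (jj < 0) jj = 0; if (jj >= W) jj = W - 1;
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// Running min/max filter over a (2r+1) window, separable (square structuring
// element), used for grayscale erosion/dilation in background estimation.
static void runline(const std::vector<double>& x, std::vector<double>& y,
                    int n, int r, bool mx) {
  // simple two-sided scan; window small relative to image so O(n r) is fine
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    double v = x[lo];
    for (int t = lo + 1; t <= hi; ++t)
      v = mx ? std::max(v, x[t]) : std::min(v, x[t]);
    y[i] = v;
  }
}

// [[Rcpp::export(name = ".minmax_filter")]]
NumericMatrix minmax_filter(const NumericMatrix& img, int radius, bool maximum) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  std::vector<double> x(std::max(H, W)), y(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) x[i] = img(i, j);
    runline(x, y, H, radius, maximum);
    for (int i = 0; i < H; ++i) tmp(i, j) = y[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) x[j] = tmp(i, j);
    runline(x, y, W, radius, maximum);
    for (int j = 0; j < W; ++j) out(i, j) = y[j];
  }
  return out;
}

// Zhang-Suen thinning: reduces a binary mask to a 1-px skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<char> img(H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) img[i + j * H] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return img[i + j * H];
  };
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          if (!img[i + j * H]) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {at(i - 1, j), at(i - 1, j + 1), at(i, j + 1), at(i + 1, j + 1),
                      at(i + 1, j), at(i + 1, j - 1), at(i, j - 1), at(i - 1, j - 1)};
          int B = 0; for (int t = 0; t < 8; ++t) B += p[t];
          if (B < 2 || B > 6) continue;
          int A = 0; for (int t = 0; t < 8; ++t) A += (p[t] == 0 && p[(t + 1) % 8] == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(i + j * H);
        }
      if (!kill.empty()) changed = true;
      for (int idx : kill) img[idx] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = img[i + j * H] != 0;
  return out;
}

// Histogram of 2x2 binary configurations over the zero-padded mask, used for
// the Crofton perimeter estimate. Bin index = p(i,j) + 2 p(i,j+1) +
// 4 p(i+1,j) + 8 p(i+1,j+1), sweeping the padded image.
// [[Rcpp::export(name = ".config_hist2x2")]]
IntegerVector config_hist2x2(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerVector h(16);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return mask(i, j) ? 1 : 0;
  };
  for (int i = -1; i < H; ++i)
    for (int j = -1; j < W; ++j) {
      int c = at(i, j) + 2 * at(i, j + 1) + 4 * at(i + 1, j) + 8 * at(i + 1, j + 1);
      ++h[c];
    }
  return h;
}
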