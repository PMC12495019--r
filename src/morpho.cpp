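// Low-level image primitives shared by the focal-correction and segmentation
// stages. Conventions (documented in the methods vignette and pinned by the
// oracle-equivalence tests):
//   * matrices are [row = y, col = x], 1-based on the R side;
//   * min/max filters ignore out-of-frame samples (equivalent to padding with
//     +Inf for erosion and -Inf for dilation);
//   * grayscale reconstruction and regional maxima are 8-connected;
//   * the marker-controlled watershed flood and component labelling used for
//     the partition contract are 4-connected;
//   * all tie-breaks are deterministic (raster order / FIFO).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// min/max filter with an arbitrary structuring element given as (dy, dx)
// offset pairs; out-of-frame offsets are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_minmax_filter(const NumericMatrix img, const IntegerMatrix off,
                                const bool take_max) {
  const int H = img.nrow(), W = img.ncol(), K = off.nrow();
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double v = take_max ? -std::numeric_limits<double>::infinity()
                          :  std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        const int yy = y + off(k, 0), xx = x + off(k, 1);
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        const double s = img(yy, xx);
        if (take_max ? (s > v) : (s < v)) v = s;
      }
      out(y, x) = v;
    }
  }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] =  std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k]))
               / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k]))
          / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Distance from every pixel to the nearest true pixel of `mask`.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(H, W);
  // columns first
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) f[y] = mask(y, x) ? 0.0 : INF;
    dt1d(f, d, H);
    for (int y = 0; y < H; ++y) g(y, x) = d[y];
  }
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) f[x] = g(y, x);
    dt1d(f, d, W);
    for (int x = 0; x < W; ++x) out(y, x) = std::sqrt(d[x]);
  }
  return out;
}

// ---- grayscale reconstruction by dilation (Vincent's hybrid algorithm) -----

static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(const NumericMatrix marker, const NumericMatrix mask) {
  const int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J(H, W);
  for (int i = 0; i < H * W; ++i) {
    J[i] = std::min(marker[i], mask[i]);
  }
  // forward raster scan (N+ neighbours: up row and left)
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double m = J(y, x);
      if (y > 0) {
        if (x > 0) m = std::max(m, J(y - 1, x - 1));
        m = std::max(m, J(y - 1, x));
        if (x < W - 1) m = std::max(m, J(y - 1, x + 1));
      }
      if (x > 0) m = std::max(m, J(y, x - 1));
      J(y, x) = std::min(m, mask(y, x));
    }
  }
  // backward raster scan, queueing pixels that can still propagate
  std::queue<int> fifo;
  for (int y = H - 1; y >= 0; --y) {
    for (int x = W - 1; x >= 0; --x) {
      double m = J(y, x);
      if (y < H - 1) {
        if (x > 0) m = std::max(m, J(y + 1, x - 1));
        m = std::max(m, J(y + 1, x));
        if (x < W - 1) m = std::max(m, J(y + 1, x + 1));
      }
      if (x < W - 1) m = std::max(m, J(y, x + 1));
      J(y, x) = std::min(m, mask(y, x));
      for (int k = 0; k < 8; ++k) {
        const int yy = y + DY8[k], xx = x + DX8[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        if (J(yy, xx) < J(y, x) && J(yy, xx) < mask(yy, xx)) {
          fifo.push(y + x * H);
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    const int p = fifo.front(); fifo.pop();
    const int y = p % H, x = p / H;
    for (int k = 0; k < 8; ++k) {
      const int yy = y + DY8[k], xx = x + DX8[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (J(yy, xx) < J(y, x) && mask(yy, xx) != J(yy, xx)) {
        const double v = std::min(J(y, x), mask(yy, xx));
        if (v > J(yy, xx)) {
          J(yy, xx) = v;
          fifo.push(yy + xx * H);
        }
      }
    }
  }
  return J;
}

// 8-connected regional maxima: plateaus with no strictly higher neighbour.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(const NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  LogicalMatrix out(H, W);
  std::vector<char> visited(H * W, 0);
  std::vector<int> plateau;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      const int p0 = y0 + x0 * H;
      if (visited[p0]) continue;
      const double v = img(y0, x0);
      bool is_max = true;
      plateau.clear();
      std::queue<int> q;
      q.push(p0);
      visited[p0] = 1;
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        plateau.push_back(p);
        const int y = p % H, x = p / H;
        for (int k = 0; k < 8; ++k) {
          const int yy = y + DY8[k], xx = x + DX8[k];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          const double u = img(yy, xx);
          if (u > v) is_max = false;
          else if (u == v) {
            const int pn = yy + xx * H;
            if (!visited[pn]) { visited[pn] = 1; q.push(pn); }
          }
        }
      }
      if (is_max)
        for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = true;
    }
  }
  return out;
}

// Connected-component labelling in raster order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix mask, const int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  IntegerMatrix lab(H, W);
  int next = 0;
  const int n_nb = conn;
  static const int DY4[4] = {-1, 0, 0, 1};
  static const int DX4[4] = {0, -1, 1, 0};
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (!mask(y0, x0) || lab(y0, x0) > 0) continue;
      ++next;
      std::queue<int> q;
      q.push(y0 + x0 * H);
      lab(y0, x0) = next;
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int y = p % H, x = p / H;
        for (int k = 0; k < n_nb; ++k) {
          const int yy = y + (conn == 4 ? DY4[k] : DY8[k]);
          const int xx = x + (conn == 4 ? DX4[k] : DX8[k]);
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            q.push(yy + xx * H);
          }
        }
      }
    }
  }
  return lab;
}

// ---- marker-controlled watershed (priority flood, 4-connected) -------------

struct QItem {
  double prio;
  long long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // min-heap on priority
    return a.order > b.order;                       // FIFO on ties
  }
};

// markers: 0 = unlabelled, >0 = seed labels. Every pixel receives the label of
// the seed region that reaches it first when flooding `surface` from below.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix surface, const IntegerMatrix markers) {
  const int H = surface.nrow(), W = surface.ncol();
  if (markers.nrow() != H || markers.ncol() != W)
    stop("surface and markers must have identical dimensions");
  IntegerMatrix lab(H, W);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long order = 0;
  static const int DY4[4] = {-1, 0, 0, 1};
  static const int DX4[4] = {0, -1, 1, 0};
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (markers(y, x) > 0) {
        lab(y, x) = markers(y, x);
        pq.push({surface(y, x), order++, y + x * H});
      }
  if (pq.empty()) stop("watershed requires at least one marker pixel");
  while (!pq.empty()) {
    const QItem it = pq.top(); pq.pop();
    const int y = it.idx % H, x = it.idx / H;
    const int l = lab(y, x);
    for (int k = 0; k < 4; ++k) {
      const int yy = y + DY4[k], xx = x + DX4[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (lab(yy, xx) == 0) {
        lab(yy, xx) = l;
        pq.push({surface(yy, xx), order++, yy + xx * H});
      }
    }
  }
  return lab;
}

// Separable convolution with replicate (edge-clamp) padding. `kx` runs along
// columns (x), `ky` along rows (y); both must have odd length.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix img, const NumericVector kx,
                           const NumericVector ky) {
  const int H = img.nrow(), W = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  if (kx.size() % 2 == 0 || ky.size() % 2 == 0) stop("kernels must have odd length");
  NumericMatrix tmp(H, W), out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double s = 0.0;
      for (int k = -rx; k <= rx; ++k) {
        int xx = x + k;
        if (xx < 0) xx = 0; else if (xx >= W) xx = W - 1;
        s += img(y, xx) * kx[rx - k];   // true convolution (kernel flipped)
      }
      tmp(y, x) = s;
    }
  }
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int yy = y + k;
        if (yy < 0) yy = 0; else if (yy >= H) yy = H - 1;
        s += tmp(yy, x) * ky[ry - k];
      }
      out(y, x) = s;
    }
  }
  return out;
}
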