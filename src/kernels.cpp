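// Pixel-level kernels shared by the label-movie model, the correction
// operators and the simulator. All matrices are row-major in the R sense
// (column-major storage, indexed [y, x] with y = row). Label 0 is background.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline bool inside(int y, int x, int h, int w) {
  return y >= 0 && y < h && x >= 0 && x < w;
}

// Connected components of the nonzero pixels, 4-connectivity, where two
// pixels join only if they carry the same label value. Returns a matrix of
// component ids (1..K, 0 on background), components numbered in raster order.
// [[Rcpp::export]]
IntegerMatrix cpp_components4(const IntegerMatrix& lab) {
  int h = lab.nrow(), w = lab.ncol();
  IntegerMatrix comp(h, w);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (lab(y, x) == 0 || comp(y, x) != 0) continue;
      int v = lab(y, x);
      comp(y, x) = ++next;
      stack.clear();
      stack.push_back({y, x});
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int k = 0; k < 4; ++k) {
          int ny = p.first + dy[k], nx = p.second + dx[k];
          if (inside(ny, nx, h, w) && comp(ny, nx) == 0 && lab(ny, nx) == v) {
            comp(ny, nx) = next;
            stack.push_back({ny, nx});
          }
        }
      }
    }
  }
  return comp;
}

// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher): distance
// from every true pixel of `mask` to the nearest false pixel. Pixels outside
// the image count as false, so border object pixels get distance 1.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
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

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  int h = mask.nrow(), w = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(h, w);
  // pad conceptually with background: seed distance along columns
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) f[y] = mask(y, x) ? INF : 0.0;
    dt1d(f, d, h);
    for (int y = 0; y < h; ++y) {
      // account for implicit background just outside the column ends
      double lim1 = (y + 1) * (double)(y + 1);
      double lim2 = (h - y) * (double)(h - y);
      g(y, x) = std::min(d[y], std::min(lim1, lim2));
    }
  }
  NumericMatrix out(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) f[x] = g(y, x);
    dt1d(f, d, w);
    for (int x = 0; x < w; ++x) {
      double lim1 = (x + 1) * (double)(x + 1);
      double lim2 = (w - x) * (double)(w - x);
      out(y, x) = std::sqrt(std::min(d[x], std::min(lim1, lim2)));
    }
  }
  return out;
}

// Zhang-Suen thinning of a binary mask down to 1-pixel-wide lines.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  int h = mask.nrow(), w = mask.ncol();
  std::vector<char> img(h * w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) img[y * w + x] = mask(y, x) ? 1 : 0;
  auto at = [&](int y, int x) -> int {
    return inside(y, x, h, w) ? img[y * w + x] : 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      kill.clear();
      for (int y = 0; y < h; ++y) {
        for (int x = 0; x < w; ++x) {
          if (!img[y * w + x]) continue;
          int p2 = at(y - 1, x), p3 = at(y - 1, x + 1), p4 = at(y, x + 1),
              p5 = at(y + 1, x + 1), p6 = at(y + 1, x), p7 = at(y + 1, x - 1),
              p8 = at(y, x - 1), p9 = at(y - 1, x - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (phase == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({y, x});
        }
      }
      for (auto& p : kill) img[p.first * w + p.second] = 0;
      if (!kill.empty()) changed = true;
    }
  }
  LogicalMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) out(y, x) = img[y * w + x] != 0;
  return out;
}

// Power-diagram tessellation: pixel (y, x) goes to the seed minimising
// (y-sy)^2 + (x-sx)^2 - wt, ties to the lowest seed index. Returns 1-based
// seed indices. Seed coordinates are 0-based pixel coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_tessellate(int h, int w, const NumericVector& sy,
                             const NumericVector& sx, const NumericVector& wt) {
  int n = sy.size();
  IntegerMatrix lab(h, w);
  std::vector<double> best((size_t)h * w,
                           std::numeric_limits<double>::infinity());
  // local pass: a pixel's winning seed lies within sqrt(d_near^2 + w_range)
  // of it, so each seed only competes inside a bounded window; pixels no
  // window reached fall back to the full scan below
  double wmax = 0, wmin = 0;
  for (int i = 0; i < n; ++i) { wmax = std::max(wmax, wt[i]);
                                wmin = std::min(wmin, wt[i]); }
  double spacing2 = 9.0 * (double)h * w / std::max(n, 1);
  int R = (int)std::ceil(std::sqrt(spacing2 + wmax - wmin)) + 2;
  for (int i = 0; i < n; ++i) {
    int y0 = std::max(0, (int)std::floor(sy[i]) - R);
    int y1 = std::min(h - 1, (int)std::ceil(sy[i]) + R);
    int x0 = std::max(0, (int)std::floor(sx[i]) - R);
    int x1 = std::min(w - 1, (int)std::ceil(sx[i]) + R);
    for (int x = x0; x <= x1; ++x) {
      double dx = x - sx[i];
      for (int y = y0; y <= y1; ++y) {
        double dy = y - sy[i];
        double c = dy * dy + dx * dx - wt[i];
        size_t k = (size_t)x * h + y;
        // strict < keeps the lowest seed index on ties (ascending i)
        if (c < best[k]) { best[k] = c; lab(y, x) = i + 1; }
      }
    }
  }
  // a seed outside every window has cost > R^2 - wmax at this pixel, so a
  // local result at or below that bound is provably optimal
  double trust = (double)R * R - wmax;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (lab(y, x) != 0 && best[(size_t)x * h + y] <= trust) continue;
      lab(y, x) = 0;
      double b = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dy = y - sy[i], dx = x - sx[i];
        double c = dy * dy + dx * dx - wt[i];
        if (c < b) { b = c; bi = i + 1; }
      }
      lab(y, x) = bi;
    }
  }
  return lab;
}

// Assign every true pixel of `mask` to the nearest seed (Euclidean distance
// to continuous seed coordinates), ties to the first seed in the input order.
// Returns 1-based seed indices, 0 outside the mask. Same arithmetic and
// tie-break as cpp_tessellate with zero weights, so splitting a union of two
// equal-weight power cells by their seeds reproduces the original boundary.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_seed(const LogicalMatrix& mask, const NumericVector& sy,
                               const NumericVector& sx) {
  int h = mask.nrow(), w = mask.ncol(), n = sy.size();
  IntegerMatrix out(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (!mask(y, x)) continue;
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dy = y - sy[i], dx = x - sx[i];
        double c = dy * dy + dx * dx - 0.0;
        if (c < best) { best = c; bi = i + 1; }
      }
      out(y, x) = bi;
    }
  }
  return out;
}

// Marker-controlled watershed restricted to `mask`: flood ascending `relief`
// from the labelled markers (4-connectivity), deterministic via FIFO order
// among equal relief values.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& relief, const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  int h = relief.nrow(), w = relief.ncol();
  IntegerMatrix lab(h, w);
  typedef std::tuple<double, long, int, int> Node; // relief, order, y, x
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  long order = 0;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (mask(y, x) && markers(y, x) > 0) {
        lab(y, x) = markers(y, x);
        pq.push({relief(y, x), order++, y, x});
      }
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    auto nd = pq.top();
    pq.pop();
    int y = std::get<2>(nd), x = std::get<3>(nd);
    for (int k = 0; k < 4; ++k) {
      int ny = y + dy[k], nx = x + dx[k];
      if (inside(ny, nx, h, w) && mask(ny, nx) && lab(ny, nx) == 0) {
        lab(ny, nx) = lab(y, x);
        pq.push({relief(ny, nx), order++, ny, nx});
      }
    }
  }
  return lab;
}

// Neighbour pairs of a label frame. Two labels are neighbours when some
// pixel of one lies within Chebyshev distance `reach` of a pixel of the
// other (reach = 2 bridges a 1-pixel junction gap). `contact` counts the
// unordered close pixel pairs and serves as a shared-boundary-length proxy.
// [[Rcpp::export]]
DataFrame cpp_adjacency(const IntegerMatrix& lab, int reach) {
  int h = lab.nrow(), w = lab.ncol();
  std::map<std::pair<int, int>, double> cnt;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int a = lab(y, x);
      if (a == 0) continue;
      // scan the forward half-neighbourhood so each pixel pair counts once
      for (int dy = 0; dy <= reach; ++dy) {
        for (int dx = (dy == 0 ? 1 : -reach); dx <= reach; ++dx) {
          int ny = y + dy, nx = x + dx;
          if (!inside(ny, nx, h, w)) continue;
          int b = lab(ny, nx);
          if (b == 0 || b == a) continue;
          std::pair<int, int> key(std::min(a, b), std::max(a, b));
          cnt[key] += 1.0;
        }
      }
    }
  }
  int m = cnt.size();
  IntegerVector av(m), bv(m);
  NumericVector cv(m);
  int i = 0;
  for (auto& kv : cnt) {
    av[i] = kv.first.first;
    bv[i] = kv.first.second;
    cv[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["a"] = av, _["b"] = bv, _["contact"] = cv);
}

// Mask of pixels whose 3x3 neighbourhood (including the pixel) contains at
// least two distinct nonzero labels: the raw junction band before thinning.
// [[Rcpp::export]]
LogicalMatrix cpp_junction_band(const IntegerMatrix& lab) {
  int h = lab.nrow(), w = lab.ncol();
  LogicalMatrix out(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int first = 0;
      bool multi = false;
      for (int dy = -1; dy <= 1 && !multi; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int ny = y + dy, nx = x + dx;
          if (!inside(ny, nx, h, w)) continue;
          int v = lab(ny, nx);
          if (v == 0) continue;
          if (first == 0) first = v;
          else if (v != first) { multi = true; break; }
        }
      }
      out(y, x) = multi;
    }
  }
  return out;
}

// Square linear assignment problem, Jonker-Volgenant style potentials
// (the classic O(n^3) shortest-augmenting-path Hungarian). cost may hold
// large-but-finite values for forbidden links. Returns, for each row, the
// 1-based assigned column.
// [[Rcpp::export]]
IntegerVector cpp_lap(const NumericMatrix& cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) ans[p[j] - 1] = j;
  return ans;
}

// Pixel-overlap counts between two label frames: for every co-occurring
// (label_a > 0, label_b > 0) pair, the number of shared pixels.
// [[Rcpp::export]]
DataFrame cpp_overlap(const IntegerMatrix& a, const IntegerMatrix& b) {
  int h = a.nrow(), w = a.ncol();
  std::map<std::pair<int, int>, int> cnt;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (a(y, x) > 0 && b(y, x) > 0) cnt[{a(y, x), b(y, x)}] += 1;
  int m = cnt.size(), i = 0;
  IntegerVector av(m), bv(m), nv(m);
  for (auto& kv : cnt) {
    av[i] = kv.first.first;
    bv[i] = kv.first.second;
    nv[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["a"] = av, _["b"] = bv, _["n"] = nv);
}
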