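#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Fast marching: solve |grad T| = 1/v on a uniform grid with spacing h.
// Matrices are indexed [i, j] with i along x (nrow) and j along y (ncol).
// `init` supplies frozen seed values (finite), NA elsewhere; seeds may be
// negative (subpixel signed-distance initialisation inside the baseline).
// Cells with v <= 0 are impermeable and keep T = +Inf.
// ---------------------------------------------------------------------------

struct HeapNode {
  double t;
  int idx;
};
struct HeapCmp {
  bool operator()(const HeapNode& a, const HeapNode& b) const { return a.t > b.t; }
};

// Solve sum_d alpha_d (T - t_d)^2 = rhs for the larger root, requiring
// causality T >= max(lo_d) over the axes used. Falls back to dropping the
// later axis, then to a single-axis update.
static double eikonal_update(bool hasx, double tx, double ax, double lox,
                             bool hasy, double ty, double ay, double loy,
                             double rhs) {
  if (hasx && hasy) {
    double a = ax + ay;
    double b = -2.0 * (ax * tx + ay * ty);
    double c = ax * tx * tx + ay * ty * ty - rhs;
    double disc = b * b - 4.0 * a * c;
    if (disc >= 0.0) {
      double T = (-b + std::sqrt(disc)) / (2.0 * a);
      if (T >= lox && T >= loy) return T;
    }
    // drop the axis with the larger first-order neighbour
    if (lox <= loy) { hasy = false; } else { hasx = false; }
  }
  if (hasx) return tx + std::sqrt(rhs / ax);
  if (hasy) return ty + std::sqrt(rhs / ay);
  return DINF;
}

// [[Rcpp::export]]
NumericMatrix fmm_arrival_cpp(NumericMatrix speed, NumericMatrix init,
                              double h, bool second_order = true) {
  const int nx = speed.nrow(), ny = speed.ncol();
  const int n = nx * ny;
  NumericMatrix T(nx, ny);
  std::vector<char> state(n, 0);  // 0 far, 1 trial, 2 accepted

  for (int k = 0; k < n; ++k) {
    if (R_finite(init[k])) {
      T[k] = init[k];
      state[k] = 2;
    } else {
      T[k] = DINF;
    }
  }

  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> heap;

  // axis candidate: best accepted neighbour (first order), optionally
  // upgraded to second order when the next cell in the same direction is
  // accepted with a smaller or equal value.
  auto axis_candidate = [&](int i, int j, int di, int dj,
                            bool& has, double& t, double& alpha, double& lo) {
    has = false;
    double best = DINF;
    int bdi = 0, bdj = 0;
    for (int s = -1; s <= 1; s += 2) {
      int ii = i + s * di, jj = j + s * dj;
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
      int kk = ii + jj * nx;
      if (state[kk] == 2 && T[kk] < best) {
        best = T[kk];
        bdi = s * di;
        bdj = s * dj;
      }
    }
    if (!R_finite(best)) return;
    has = true;
    lo = best;
    t = best;
    alpha = 1.0;
    if (second_order) {
      int i2 = i + 2 * bdi, j2 = j + 2 * bdj;
      if (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny) {
        int k2 = i2 + j2 * nx;
        if (state[k2] == 2 && R_finite(T[k2]) && T[k2] <= best) {
          t = (4.0 * best - T[k2]) / 3.0;
          alpha = 9.0 / 4.0;
        }
      }
    }
  };

  auto try_update = [&](int i, int j) {
    int k = i + j * nx;
    if (state[k] == 2) return;
    double v = speed[k];
    if (!(v > 0.0)) return;
    double rhs = (h * h) / (v * v);
    bool hx, hy;
    double tx = 0, ax = 1, lx = 0, ty = 0, ay = 1, ly = 0;
    axis_candidate(i, j, 1, 0, hx, tx, ax, lx);
    axis_candidate(i, j, 0, 1, hy, ty, ay, ly);
    if (!hx && !hy) return;
    double Tnew = eikonal_update(hx, tx, ax, lx, hy, ty, ay, ly, rhs);
    if (Tnew < T[k]) {
      T[k] = Tnew;
      state[k] = 1;
      heap.push({Tnew, k});
    }
  };

  // seed the trial band from accepted cells
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int k = i + j * nx;
      if (state[k] != 2) continue;
      if (i > 0) try_update(i - 1, j);
      if (i < nx - 1) try_update(i + 1, j);
      if (j > 0) try_update(i, j - 1);
      if (j < ny - 1) try_update(i, j + 1);
    }
  }

  while (!heap.empty()) {
    HeapNode nd = heap.top();
    heap.pop();
    int k = nd.idx;
    if (state[k] == 2) continue;
    if (nd.t > T[k] + 1e-12) continue;  // stale entry
    state[k] = 2;
    int i = k % nx, j = k / nx;
    if (i > 0) try_update(i - 1, j);
    if (i < nx - 1) try_update(i + 1, j);
    if (j > 0) try_update(i, j - 1);
    if (j < ny - 1) try_update(i, j + 1);
  }

  return T;
}

// ---------------------------------------------------------------------------
// Unsigned distance (mm) from each pixel centre to the nearest point of a set
// of polyline chains, computed only within a band of width band_mm around the
// chains; +Inf elsewhere. Chains are closed polygons in mm coordinates.
// ---------------------------------------------------------------------------

static inline double dist_point_segment(double x, double y,
                                        double x1, double y1,
                                        double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((x - x1) * dx + (y - y1) * dy) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  double px = x1 + t * dx - x, py = y1 + t * dy - y;
  return std::sqrt(px * px + py * py);
}

// [[Rcpp::export]]
NumericMatrix band_distance_cpp(List chains, int nx, int ny,
                                double x0, double y0, double h,
                                double band_mm) {
  NumericMatrix D(nx, ny);
  std::fill(D.begin(), D.end(), DINF);
  for (int c = 0; c < chains.size(); ++c) {
    NumericMatrix ch = chains[c];
    int m = ch.nrow();
    for (int s = 0; s < m - 1; ++s) {
      double x1 = ch(s, 0), y1 = ch(s, 1);
      double x2 = ch(s + 1, 0), y2 = ch(s + 1, 1);
      double xmin = std::min(x1, x2) - band_mm, xmax = std::max(x1, x2) + band_mm;
      double ymin = std::min(y1, y2) - band_mm, ymax = std::max(y1, y2) + band_mm;
      int i0 = std::max(0, (int)std::ceil((xmin - x0) / h));
      int i1 = std::min(nx - 1, (int)std::floor((xmax - x0) / h));
      int j0 = std::max(0, (int)std::ceil((ymin - y0) / h));
      int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / h));
      for (int j = j0; j <= j1; ++j) {
        double py = y0 + j * h;
        for (int i = i0; i <= i1; ++i) {
          double px = x0 + i * h;
          double d = dist_point_segment(px, py, x1, y1, x2, y2);
          if (d < D(i, j)) D(i, j) = d;
        }
      }
    }
  }
  for (int k = 0; k < nx * ny; ++k)
    if (D[k] > band_mm) D[k] = DINF;
  return D;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance in pixel units from every cell to the nearest TRUE cell.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // indices with finite parabola heights
  std::vector<int> idx;
  idx.reserve(n);
  for (int q = 0; q < n; ++q)
    if (R_finite(f[q])) idx.push_back(q);
  if (idx.empty()) {
    std::fill(d.begin(), d.begin() + n, DINF);
    return;
  }
  std::vector<int> v(idx.size());
  std::vector<double> z(idx.size() + 1);
  int k = 0;
  v[0] = idx[0];
  z[0] = -DINF;
  z[1] = DINF;
  // lower envelope of parabolas; z[0] = -Inf guarantees k never underflows
  for (size_t r = 1; r < idx.size(); ++r) {
    int q = idx[r];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = ((double)(q - p)) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_cpp(LogicalMatrix fg) {
  const int nx = fg.nrow(), ny = fg.ncol();
  NumericMatrix D(nx, ny);
  bool any_fg = false;
  for (int k = 0; k < nx * ny; ++k) {
    D[k] = fg[k] ? 0.0 : DINF;
    if (fg[k]) any_fg = true;
  }
  if (!any_fg) return D;
  // columns (along x, i index)
  {
    std::vector<double> f(nx), d(nx);
    for (int j = 0; j < ny; ++j) {
      bool all_inf = true;
      for (int i = 0; i < nx; ++i) { f[i] = D(i, j); if (R_finite(f[i])) all_inf = false; }
      if (all_inf) continue;
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) D(i, j) = d[i];
    }
  }
  // rows (along y, j index)
  {
    std::vector<double> f(ny), d(ny);
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D(i, j);
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) D(i, j) = d[j];
    }
  }
  for (int k = 0; k < nx * ny; ++k)
    if (R_finite(D[k])) D[k] = std::sqrt(D[k]);
  return D;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS), 8- or 4-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool eight = true) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nd = eight ? 8 : 4;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int k = i + j * nx;
      if (!mask[k] || lab[k]) continue;
      ++next;
      lab[k] = next;
      stack.push_back(k);
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        int qi = q % nx, qj = q / nx;
        for (int d = 0; d < nd; ++d) {
          int ii = qi + dx8[d], jj = qj + dy8[d];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
          int kk = ii + jj * nx;
          if (mask[kk] && !lab[kk]) {
            lab[kk] = next;
            stack.push_back(kk);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Even-odd point-in-polygon test against a set of chains taken jointly
// (odd total crossing parity = inside; holes handled automatically).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector points_in_chains_cpp(NumericVector px, NumericVector py,
                                   List chains) {
  const int np = px.size();
  LogicalVector inside(np, false);
  for (int c = 0; c < chains.size(); ++c) {
    NumericMatrix ch = chains[c];
    int m = ch.nrow();
    for (int q = 0; q < np; ++q) {
      double x = px[q], y = py[q];
      bool flip = false;
      for (int s = 0, t = m - 1; s < m; t = s++) {
        double x1 = ch(s, 0), y1 = ch(s, 1);
        double x2 = ch(t, 0), y2 = ch(t, 1);
        if (((y1 > y) != (y2 > y)) &&
            (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1))
          flip = !flip;
      }
      if (flip) inside[q] = !inside[q];
    }
  }
  return inside;
}
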