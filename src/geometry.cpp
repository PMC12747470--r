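// Periodic distance-grid machinery behind the pore-geometry module:
// distance transform to the nearest van der Waals surface, incremental
// union-find percolation (pore-limiting diameter), component labelling at
// a threshold, and the largest-covering-sphere field for pore-size
// distributions.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double wrap_half(double d) {
  d -= std::round(d);
  return d;
}

// distance grid: value(g) = min over sites (and periodic images) of
// |g - site| - rvdw(site). lattice rows are lattice vectors; ortho = all
// angles 90 (per-axis wrap is then the exact minimum image).
// [[Rcpp::export]]
NumericVector dist_grid_cpp(NumericMatrix lattice, NumericMatrix frac,
                            NumericVector radii, IntegerVector dims,
                            bool ortho) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ns = frac.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> L(9);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) L[3 * r + c] = lattice(r, c);

  // shifts for triclinic minimum image
  std::vector<int> sh;
  if (!ortho) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) { sh.push_back(a); sh.push_back(b); sh.push_back(c); }
  }

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double gz = (double)k / nz;
    for (int j = 0; j < ny; ++j) {
      double gy = (double)j / ny;
      for (int i = 0; i < nx; ++i, ++idx) {
        double gx = (double)i / nx;
        double best = R_PosInf;
        for (int s = 0; s < ns; ++s) {
          double dx = wrap_half(gx - frac(s, 0));
          double dy = wrap_half(gy - frac(s, 1));
          double dz = wrap_half(gz - frac(s, 2));
          double d2best;
          if (ortho) {
            double cx = dx * L[0], cy = dy * L[4], cz = dz * L[8];
            d2best = cx * cx + cy * cy + cz * cz;
          } else {
            d2best = R_PosInf;
            for (size_t m = 0; m < sh.size(); m += 3) {
              double fx = dx + sh[m], fy = dy + sh[m + 1], fz = dz + sh[m + 2];
              double cx = fx * L[0] + fy * L[3] + fz * L[6];
              double cy = fx * L[1] + fy * L[4] + fz * L[7];
              double cz = fx * L[2] + fy * L[5] + fz * L[8];
              double d2 = cx * cx + cy * cy + cz * cz;
              if (d2 < d2best) d2best = d2;
            }
          }
          double v = std::sqrt(d2best) - radii[s];
          if (v < best) best = v;
        }
        out[idx] = (ns == 0) ? R_PosInf : best;
      }
    }
  }
  return out;
}

struct OffsetUF {
  std::vector<int> parent;
  std::vector<int> off;  // 3 ints per node: cell wraps relative to parent
  OffsetUF(int n) : parent(n), off(3 * n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x, int w[3]) {
    w[0] = w[1] = w[2] = 0;
    // find root
    int root = x;
    while (parent[root] != root) root = parent[root];
    // path compression with offset accumulation
    int cur = x;
    int acc[3] = {0, 0, 0};
    while (parent[cur] != cur) {
      acc[0] += off[3 * cur]; acc[1] += off[3 * cur + 1]; acc[2] += off[3 * cur + 2];
      cur = parent[cur];
    }
    w[0] = acc[0]; w[1] = acc[1]; w[2] = acc[2];
    // second pass: repoint to root
    cur = x;
    int run[3] = {0, 0, 0};
    while (parent[cur] != cur) {
      int nxt = parent[cur];
      int o0 = off[3 * cur], o1 = off[3 * cur + 1], o2 = off[3 * cur + 2];
      off[3 * cur] = acc[0] - run[0];
      off[3 * cur + 1] = acc[1] - run[1];
      off[3 * cur + 2] = acc[2] - run[2];
      parent[cur] = root;
      run[0] += o0; run[1] += o1; run[2] += o2;
      cur = nxt;
    }
    return root;
  }
};

static inline R_xlen_t gidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
}

// Pore-limiting diameter by incremental percolation: activate grid cells in
// decreasing value order, union 6-neighbors (tracking periodic wrap
// offsets); the first union joining a component to its own periodic image
// fixes the percolation threshold t, and PLD = 2 t. Returns -Inf if the
// structure never percolates with positive clearance.
// [[Rcpp::export]]
double percolation_threshold_cpp(NumericVector values, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> order(n);
  for (R_xlen_t i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](R_xlen_t a, R_xlen_t b) {
    return values[a] > values[b];
  });
  OffsetUF uf((int)n);
  std::vector<char> active(n, 0);
  const int steps[6][4] = {  // di dj dk axis
    {1, 0, 0, 0}, {-1, 0, 0, 0}, {0, 1, 0, 1},
    {0, -1, 0, 1}, {0, 0, 1, 2}, {0, 0, -1, 2}};
  for (R_xlen_t oi = 0; oi < n; ++oi) {
    R_xlen_t c = order[oi];
    double v = values[c];
    if (!R_finite(v)) { if (v == R_NegInf) break; }
    active[c] = 1;
    int i = (int)(c % nx);
    int j = (int)((c / nx) % ny);
    int k = (int)(c / ((R_xlen_t)nx * ny));
    for (int s = 0; s < 6; ++s) {
      int ii = i + steps[s][0], jj = j + steps[s][1], kk = k + steps[s][2];
      int w[3] = {0, 0, 0};
      if (ii < 0) { ii += nx; w[0] = -1; } else if (ii >= nx) { ii -= nx; w[0] = 1; }
      if (jj < 0) { jj += ny; w[1] = -1; } else if (jj >= ny) { jj -= ny; w[1] = 1; }
      if (kk < 0) { kk += nz; w[2] = -1; } else if (kk >= nz) { kk -= nz; w[2] = 1; }
      R_xlen_t nb = gidx(ii, jj, kk, nx, ny);
      if (!active[nb]) continue;
      int wa[3], wb[3];
      int ra = uf.find((int)c, wa);
      int rb = uf.find((int)nb, wb);
      if (ra == rb) {
        // neighbor constraint: W(nb) - W(c) should equal w
        if (wb[0] - wa[0] != w[0] || wb[1] - wa[1] != w[1] || wb[2] - wa[2] != w[2])
          return v;  // percolates at this clearance
      } else {
        uf.parent[ra] = rb;
        uf.off[3 * ra] = wb[0] - w[0] - wa[0];
        uf.off[3 * ra + 1] = wb[1] - w[1] - wa[1];
        uf.off[3 * ra + 2] = wb[2] - w[2] - wa[2];
      }
    }
  }
  return R_NegInf;
}

// Label connected components of {value >= threshold} with periodic
// 6-adjacency. Returns list(labels = integer grid vector, 0 = below
// threshold, percolating = logical per label).
// [[Rcpp::export]]
List label_components_cpp(NumericVector values, IntegerVector dims,
                          double threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  OffsetUF uf((int)n);
  std::vector<char> in(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) in[i] = values[i] >= threshold;
  std::vector<char> perc(n, 0);  // flagged on roots
  const int steps[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t c = gidx(i, j, k, nx, ny);
        if (!in[c]) continue;
        for (int s = 0; s < 3; ++s) {
          int ii = i + steps[s][0], jj = j + steps[s][1], kk = k + steps[s][2];
          int w[3] = {0, 0, 0};
          if (ii >= nx) { ii -= nx; w[0] = 1; }
          if (jj >= ny) { jj -= ny; w[1] = 1; }
          if (kk >= nz) { kk -= nz; w[2] = 1; }
          R_xlen_t nb = gidx(ii, jj, kk, nx, ny);
          if (!in[nb]) continue;
          int wa[3], wb[3];
          int ra = uf.find((int)c, wa);
          int rb = uf.find((int)nb, wb);
          if (ra == rb) {
            if (wb[0] - wa[0] != w[0] || wb[1] - wa[1] != w[1] ||
                wb[2] - wa[2] != w[2]) perc[ra] = 1;
          } else {
            uf.parent[ra] = rb;
            uf.off[3 * ra] = wb[0] - w[0] - wa[0];
            uf.off[3 * ra + 1] = wb[1] - w[1] - wa[1];
            uf.off[3 * ra + 2] = wb[2] - w[2] - wa[2];
            if (perc[ra]) perc[rb] = 1;
          }
        }
      }
  IntegerVector labels(n);
  LogicalVector percl;
  std::vector<int> root_label(n, 0);
  std::vector<char> root_perc;
  int next = 0;
  int w[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!in[i]) { labels[i] = 0; continue; }
    int r = uf.find((int)i, w);
    if (root_label[r] == 0) {
      root_label[r] = ++next;
      root_perc.push_back(perc[r]);
    }
    labels[i] = root_label[r];
  }
  percl = LogicalVector(next);
  for (int i = 0; i < next; ++i) percl[i] = root_perc[i] != 0;
  return List::create(_["labels"] = labels, _["percolating"] = percl);
}

// Largest-covering-sphere radius field (Gelb-Gubbins style PSD substrate)
// for an orthorhombic grid with per-axis Cartesian steps hx, hy, hz.
// Greedy descending-radius ball marking with a subsumption skip: a center
// already covered by a sphere at least as large as its own is not
// re-expanded. Exact on convex channel/cavity fixtures; a documented
// approximation in general.
// [[Rcpp::export]]
NumericVector covering_radius_cpp(NumericVector values, IntegerVector dims,
                                  double hx, double hy, double hz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cover(n, R_NegInf);
  std::vector<R_xlen_t> order;
  order.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) if (values[i] > 0) order.push_back(i);
  std::sort(order.begin(), order.end(), [&](R_xlen_t a, R_xlen_t b) {
    return values[a] > values[b];
  });
  for (size_t oi = 0; oi < order.size(); ++oi) {
    R_xlen_t c = order[oi];
    double r = values[c];
    if (cover[c] >= r) continue;  // subsumed by a larger sphere
    int i = (int)(c % nx);
    int j = (int)((c / nx) % ny);
    int k = (int)(c / ((R_xlen_t)nx * ny));
    int ri = (int)std::floor(r / hx), rj = (int)std::floor(r / hy),
        rk = (int)std::floor(r / hz);
    ri = std::min(ri, nx / 2); rj = std::min(rj, ny / 2); rk = std::min(rk, nz / 2);
    double r2 = r * r;
    for (int dk = -rk; dk <= rk; ++dk) {
      double z2 = dk * hz * dk * hz;
      int kk = k + dk; kk %= nz; if (kk < 0) kk += nz;
      for (int dj = -rj; dj <= rj; ++dj) {
        double y2 = dj * hy * dj * hy;
        if (z2 + y2 > r2) continue;
        int jj = j + dj; jj %= ny; if (jj < 0) jj += ny;
        for (int di = -ri; di <= ri; ++di) {
          double x2 = di * hx * di * hx;
          if (x2 + y2 + z2 > r2) continue;
          int ii = i + di; ii %= nx; if (ii < 0) ii += nx;
          R_xlen_t t = gidx(ii, jj, kk, nx, ny);
          if (cover[t] < r) cover[t] = r;
        }
      }
    }
  }
  return cover;
}

// clearance (distance to nearest vdW surface) at arbitrary fractional
// points; used by the Monte-Carlo pore-volume sampler.
// [[Rcpp::export]]
NumericVector clearance_cpp(NumericMatrix lattice, NumericMatrix site_frac,
                            NumericVector radii, NumericMatrix pts_frac,
                            bool ortho) {
  const int ns = site_frac.nrow();
  const int np = pts_frac.nrow();
  NumericVector out(np);
  std::vector<double> L(9);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) L[3 * r + c] = lattice(r, c);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      double dx = wrap_half(pts_frac(p, 0) - site_frac(s, 0));
      double dy = wrap_half(pts_frac(p, 1) - site_frac(s, 1));
      double dz = wrap_half(pts_frac(p, 2) - site_frac(s, 2));
      double d2best = R_PosInf;
      if (ortho) {
        double cx = dx * L[0], cy = dy * L[4], cz = dz * L[8];
        d2best = cx * cx + cy * cy + cz * cz;
      } else {
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              double fx = dx + a, fy = dy + b, fz = dz + c;
              double cx = fx * L[0] + fy * L[3] + fz * L[6];
              double cy = fx * L[1] + fy * L[4] + fz * L[7];
              double cz = fx * L[2] + fy * L[5] + fz * L[8];
              double d2 = cx * cx + cy * cy + cz * cz;
              if (d2 < d2best) d2best = d2;
            }
      }
      double v = std::sqrt(d2best) - radii[s];
      if (v < best) best = v;
    }
    out[p] = (ns == 0) ? R_PosInf : best;
  }
  return out;
}
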