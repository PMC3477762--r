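#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, 2012).
// Distances in pixels from every pixel to the nearest foreground pixel.
// ---------------------------------------------------------------------------

static const double EDT_INF = 1e20;

// lower envelope of parabolas; f = input squared distances, d = output
static void edt_1d(const double* f, double* d, int n,
                   std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_cpp(IntegerMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  std::vector<double> g(nr * nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      g[j * nr + i] = fg(i, j) ? 0.0 : EDT_INF;

  int nmax = std::max(nr, nc);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), f(nmax), d(nmax);

  // transform along columns
  for (int j = 0; j < nc; j++) {
    edt_1d(&g[j * nr], d.data(), nr, v, z);
    std::copy(d.begin(), d.begin() + nr, g.begin() + j * nr);
  }
  // transform along rows
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = g[j * nr + i];
    edt_1d(f.data(), d.data(), nc, v, z);
    for (int j = 0; j < nc; j++) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bresenham line rasterisation
// ---------------------------------------------------------------------------

template <typename PUSH>
static void bresenham(int x0, int y0, int x1, int y1, PUSH push) {
  int dx = std::abs(x1 - x0), dy = -std::abs(y1 - y0);
  int sx = x0 < x1 ? 1 : -1, sy = y0 < y1 ? 1 : -1;
  int err = dx + dy;
  for (;;) {
    push(x0, y0);
    if (x0 == x1 && y0 == y1) break;
    int e2 = 2 * err;
    if (e2 >= dy) { err += dy; x0 += sx; }
    if (e2 <= dx) { err += dx; y0 += sy; }
  }
}

// segs: n x 4 matrix of 0-based pixel endpoints (x0, y0, x1, y1);
// returns binary image (nr x nc), pixels outside the raster silently clipped
// [[Rcpp::export]]
IntegerMatrix raster_segments_cpp(IntegerMatrix segs, int nr, int nc) {
  IntegerMatrix img(nr, nc);
  for (int s = 0; s < segs.nrow(); s++) {
    bresenham(segs(s, 0), segs(s, 1), segs(s, 2), segs(s, 3),
              [&](int x, int y) {
                if (x >= 0 && x < nc && y >= 0 && y < nr) img(y, x) = 1;
              });
  }
  return img;
}

// ---------------------------------------------------------------------------
// Silhouette projection core
// ---------------------------------------------------------------------------

struct SilPix {
  std::vector<int> in_pix;                      // encoded y*nc + x, unique
  std::vector<std::pair<int, double> > out_pix; // clamped encoding + extra px
};

// V: n x 3 vertices, F: m x 3 faces (1-based), E: ne x 4 (v1, v2, f1, f2;
// 1-based, f2 = 0 for boundary edges). rot: 3x3, about `center`, then +trans.
static void silhouette_pixels(const NumericMatrix& V, const IntegerMatrix& F,
                              const IntegerMatrix& E, const NumericMatrix& rot,
                              const NumericVector& trans,
                              const NumericVector& center,
                              const NumericVector& source,
                              const NumericVector& det_origin,
                              const NumericVector& axis_u,
                              const NumericVector& axis_v, double spacing,
                              int nr, int nc, SilPix& out) {
  int nv = V.nrow(), nf = F.nrow(), ne = E.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  double r20 = rot(2, 0), r21 = rot(2, 1), r22 = rot(2, 2);
  double cx = center[0], cy = center[1], cz = center[2];
  double tx = trans[0] + cx, ty = trans[1] + cy, tz = trans[2] + cz;
  for (int i = 0; i < nv; i++) {
    double px = V(i, 0) - cx, py = V(i, 1) - cy, pz = V(i, 2) - cz;
    X[i] = r00 * px + r01 * py + r02 * pz + tx;
    Y[i] = r10 * px + r11 * py + r12 * pz + ty;
    Z[i] = r20 * px + r21 * py + r22 * pz + tz;
  }

  // facing sign of every face as seen from the source
  std::vector<signed char> sign(nf);
  double sx = source[0], sy = source[1], sz = source[2];
  for (int f = 0; f < nf; f++) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double e1x = X[b] - X[a], e1y = Y[b] - Y[a], e1z = Z[b] - Z[a];
    double e2x = X[c] - X[a], e2y = Y[c] - Y[a], e2z = Z[c] - Z[a];
    double nx = e1y * e2z - e1z * e2y;
    double ny = e1z * e2x - e1x * e2z;
    double nz = e1x * e2y - e1y * e2x;
    double gx = (X[a] + X[b] + X[c]) / 3.0 - sx;
    double gy = (Y[a] + Y[b] + Y[c]) / 3.0 - sy;
    double gz = (Z[a] + Z[b] + Z[c]) / 3.0 - sz;
    sign[f] = (nx * gx + ny * gy + nz * gz) > 0 ? 1 : -1;
  }

  // detector plane normal
  double ux = axis_u[0], uy = axis_u[1], uz = axis_u[2];
  double vx = axis_v[0], vy = axis_v[1], vz = axis_v[2];
  double wx = uy * vz - uz * vy, wy = uz * vx - ux * vz, wz = ux * vy - uy * vx;
  double ox = det_origin[0], oy = det_origin[1], oz = det_origin[2];
  double d_num = (ox - sx) * wx + (oy - sy) * wy + (oz - sz) * wz;

  std::vector<unsigned char> seen((size_t)nr * nc, 0);
  std::vector<int> proj_x(nv, INT_MIN), proj_y(nv, INT_MIN);
  std::vector<unsigned char> have(nv, 0);

  auto project = [&](int i, bool& ok, int& pxi, int& pyi) {
    if (have[i]) {
      ok = proj_x[i] != INT_MIN;
      pxi = proj_x[i];
      pyi = proj_y[i];
      return;
    }
    have[i] = 1;
    double dx = X[i] - sx, dy = Y[i] - sy, dz = Z[i] - sz;
    double den = dx * wx + dy * wy + dz * wz;
    if (std::fabs(den) < 1e-12) { ok = false; return; }
    double t = d_num / den;
    double ix = sx + t * dx - ox, iy = sy + t * dy - oy, iz = sz + t * dz - oz;
    double mm_u = ix * ux + iy * uy + iz * uz;
    double mm_v = ix * vx + iy * vy + iz * vz;
    pxi = (int)std::floor(mm_u / spacing);
    pyi = (int)std::floor(mm_v / spacing);
    proj_x[i] = pxi;
    proj_y[i] = pyi;
    ok = true;
  };

  for (int e = 0; e < ne; e++) {
    int f1 = E(e, 2) - 1, f2 = E(e, 3) - 1;
    bool sil = (f2 < 0) || (sign[f1] != sign[f2]);
    if (!sil) continue;
    int v1 = E(e, 0) - 1, v2 = E(e, 1) - 1;
    bool ok1, ok2;
    int x0, y0, x1, y1;
    project(v1, ok1, x0, y0);
    project(v2, ok2, x1, y1);
    if (!ok1 || !ok2) continue;
    bresenham(x0, y0, x1, y1, [&](int x, int y) {
      if (x >= 0 && x < nc && y >= 0 && y < nr) {
        size_t idx = (size_t)y * nc + x;
        if (!seen[idx]) {
          seen[idx] = 1;
          out.in_pix.push_back((int)idx);
        }
      } else {
        int xc = std::min(std::max(x, 0), nc - 1);
        int yc = std::min(std::max(y, 0), nr - 1);
        double ex = x - xc, ey = y - yc;
        out.out_pix.push_back(
            std::make_pair(yc * nc + xc, std::sqrt(ex * ex + ey * ey)));
      }
    });
  }
}

// [[Rcpp::export]]
IntegerMatrix render_silhouette_cpp(NumericMatrix V, IntegerMatrix F,
                                    IntegerMatrix E, NumericMatrix rot,
                                    NumericVector trans, NumericVector center,
                                    NumericVector source,
                                    NumericVector det_origin,
                                    NumericVector axis_u, NumericVector axis_v,
                                    double spacing, int nr, int nc) {
  SilPix sp;
  silhouette_pixels(V, F, E, rot, trans, center, source, det_origin, axis_u,
                    axis_v, spacing, nr, nc, sp);
  IntegerMatrix img(nr, nc);
  for (size_t i = 0; i < sp.in_pix.size(); i++) {
    int idx = sp.in_pix[i];
    img(idx / nc, idx % nc) = 1;
  }
  return img;
}

// exact nearest-neighbour distances from query pixels to a model pixel set,
// bucket grid with expanding ring search
struct PixGrid {
  int cell, gw, gh, nc;
  std::vector<int> start, items;
  void build(const std::vector<int>& pix, int nr, int nc_, int cell_) {
    cell = cell_;
    nc = nc_;
    gw = (nc + cell - 1) / cell;
    gh = (nr + cell - 1) / cell;
    std::vector<int> count(gw * gh, 0);
    std::vector<int> cellof(pix.size());
    for (size_t i = 0; i < pix.size(); i++) {
      int x = pix[i] % nc, y = pix[i] / nc;
      int c = (y / cell) * gw + (x / cell);
      cellof[i] = c;
      count[c]++;
    }
    start.assign(gw * gh + 1, 0);
    for (int c = 0; c < gw * gh; c++) start[c + 1] = start[c] + count[c];
    items.resize(pix.size());
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (size_t i = 0; i < pix.size(); i++) items[fill[cellof[i]]++] = (int)i;
  }
};

static double nn_dist(const PixGrid& g, const std::vector<int>& pix, int qx,
                      int qy) {
  int cx = qx / g.cell, cy = qy / g.cell;
  double best = std::numeric_limits<double>::infinity();
  for (int r = 0;; r++) {
    double ring_min = (r - 1) * (double)g.cell;
    if (r > 1 && ring_min * ring_min >= best) break;
    bool any_cell = false;
    for (int dy = -r; dy <= r; dy++) {
      int yy = cy + dy;
      if (yy < 0 || yy >= g.gh) continue;
      int step = (std::abs(dy) == r) ? 1 : 2 * r;
      if (step == 0) step = 1;
      for (int dx = -r; dx <= r; dx += step) {
        int xx = cx + dx;
        if (xx < 0 || xx >= g.gw) continue;
        any_cell = true;
        int c = yy * g.gw + xx;
        for (int k = g.start[c]; k < g.start[c + 1]; k++) {
          int p = pix[g.items[k]];
          double ddx = (p % g.nc) - qx, ddy = (p / g.nc) - qy;
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < best) best = d2;
        }
      }
    }
    if (!any_cell && r > std::max(g.gw, g.gh)) break;
  }
  return std::sqrt(best);
}

// Symmetric mean distance cost between the projected model silhouette and a
// fixed target edge image, in mm.  target_dt: distance transform of the
// target (pixels); target_px: n x 2 (0-based y, x) target foreground pixels.
// [[Rcpp::export]]
double silhouette_cost_cpp(NumericMatrix V, IntegerMatrix F, IntegerMatrix E,
                           NumericMatrix rot, NumericVector trans,
                           NumericVector center, NumericVector source,
                           NumericVector det_origin, NumericVector axis_u,
                           NumericVector axis_v, double spacing, int nr,
                           int nc, NumericMatrix target_dt,
                           IntegerMatrix target_px) {
  SilPix sp;
  silhouette_pixels(V, F, E, rot, trans, center, source, det_origin, axis_u,
                    axis_v, spacing, nr, nc, sp);
  size_t n_model = sp.in_pix.size() + sp.out_pix.size();
  // a silhouette entirely outside the raster carries no alignment signal
  if (sp.in_pix.empty()) return R_PosInf;

  // forward: model pixels against the target distance transform
  double s1 = 0.0;
  for (size_t i = 0; i < sp.in_pix.size(); i++) {
    int idx = sp.in_pix[i];
    s1 += target_dt(idx / nc, idx % nc);
  }
  std::vector<int> model_pix(sp.in_pix);
  for (size_t i = 0; i < sp.out_pix.size(); i++) {
    int idx = sp.out_pix[i].first;
    s1 += target_dt(idx / nc, idx % nc) + sp.out_pix[i].second;
    model_pix.push_back(idx);
  }
  double fwd = s1 / (double)n_model;

  // backward: target pixels against the model pixel set
  PixGrid grid;
  grid.build(model_pix, nr, nc, 8);
  double s2 = 0.0;
  int nt = target_px.nrow();
  for (int i = 0; i < nt; i++)
    s2 += nn_dist(grid, model_pix, target_px(i, 1), target_px(i, 0));
  double bwd = nt > 0 ? s2 / nt : 0.0;

  return 0.5 * (fwd + bwd) * spacing;
}

// ---------------------------------------------------------------------------
// Nearest neighbour within radius (3D uniform grid), exact, ties -> lowest
// reference index.  Returns 1-based indices (0 = none) and distances.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nearest_within_cpp(NumericMatrix query, NumericMatrix ref, double radius) {
  int nq = query.nrow(), nref = ref.nrow();
  IntegerVector idx(nq, 0);
  NumericVector dist(nq, NA_REAL);
  if (nref == 0 || nq == 0 || radius <= 0) return List::create(_["idx"] = idx, _["dist"] = dist);

  double mn[3], mx[3];
  for (int d = 0; d < 3; d++) {
    mn[d] = R_PosInf;
    mx[d] = R_NegInf;
    for (int i = 0; i < nref; i++) {
      if (ref(i, d) < mn[d]) mn[d] = ref(i, d);
      if (ref(i, d) > mx[d]) mx[d] = ref(i, d);
    }
  }
  int dims[3];
  for (int d = 0; d < 3; d++) {
    dims[d] = std::max(1, (int)std::floor((mx[d] - mn[d]) / radius) + 1);
  }
  size_t ncell = (size_t)dims[0] * dims[1] * dims[2];
  std::vector<int> count(ncell, 0), cellof(nref);
  for (int i = 0; i < nref; i++) {
    int c[3];
    for (int d = 0; d < 3; d++) {
      c[d] = (int)std::floor((ref(i, d) - mn[d]) / radius);
      if (c[d] >= dims[d]) c[d] = dims[d] - 1;
      if (c[d] < 0) c[d] = 0;
    }
    int cc = (c[2] * dims[1] + c[1]) * dims[0] + c[0];
    cellof[i] = cc;
    count[cc]++;
  }
  std::vector<int> start(ncell + 1, 0);
  for (size_t c = 0; c < ncell; c++) start[c + 1] = start[c] + count[c];
  std::vector<int> items(nref);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int i = 0; i < nref; i++) items[fill[cellof[i]]++] = i;

  double r2 = radius * radius;
  for (int q = 0; q < nq; q++) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int c0 = (int)std::floor((qx - mn[0]) / radius);
    int c1 = (int)std::floor((qy - mn[1]) / radius);
    int c2 = (int)std::floor((qz - mn[2]) / radius);
    double bestd2 = R_PosInf;
    int bestj = -1;
    for (int z = std::max(0, c2 - 1); z <= std::min(dims[2] - 1, c2 + 1); z++)
      for (int y = std::max(0, c1 - 1); y <= std::min(dims[1] - 1, c1 + 1); y++)
        for (int x = std::max(0, c0 - 1); x <= std::min(dims[0] - 1, c0 + 1);
             x++) {
          int cc = (z * dims[1] + y) * dims[0] + x;
          for (int k = start[cc]; k < start[cc + 1]; k++) {
            int j = items[k];
            double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy,
                   dz = ref(j, 2) - qz;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 <= r2 && (d2 < bestd2 || (d2 == bestd2 && j < bestj))) {
              bestd2 = d2;
              bestj = j;
            }
          }
        }
    if (bestj >= 0) {
      idx[q] = bestj + 1;
      dist[q] = std::sqrt(bestd2);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
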