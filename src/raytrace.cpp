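#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Regular voxel grid. World coordinates refer to voxel centers; the grid
// occupies the half-open box [origin - spacing/2, origin + (n - 1/2) * spacing)
// on each axis, so the box minimum corner is origin - spacing/2.
struct Grid {
  const double* mu;
  int nx, ny, nz;
  double sx, sy, sz;
  double x0, y0, z0; // box minimum corner
};

static inline bool clip_axis(double p, double d, double lo, double hi,
                             double& a0, double& a1) {
  if (d == 0.0) return p >= lo && p < hi;
  double t1 = (lo - p) / d, t2 = (hi - p) / d;
  if (t1 > t2) std::swap(t1, t2);
  if (t1 > a0) a0 = t1;
  if (t2 < a1) a1 = t2;
  return a0 < a1;
}

// Exact line integral of mu along segment p1 -> p2 (Siddon-style parametric
// traversal; segment lengths recovered from consecutive plane-crossing
// parameters, voxel identified by the segment midpoint).
static double siddon_one(const Grid& g,
                         double p1x, double p1y, double p1z,
                         double p2x, double p2y, double p2z) {
  const double dx = p2x - p1x, dy = p2y - p1y, dz = p2z - p1z;
  const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L == 0.0) return 0.0; // validated upstream
  double a0 = 0.0, a1 = 1.0;
  const double bx1 = g.x0 + g.nx * g.sx;
  const double by1 = g.y0 + g.ny * g.sy;
  const double bz1 = g.z0 + g.nz * g.sz;
  if (!clip_axis(p1x, dx, g.x0, bx1, a0, a1)) return 0.0;
  if (!clip_axis(p1y, dy, g.y0, by1, a0, a1)) return 0.0;
  if (!clip_axis(p1z, dz, g.z0, bz1, a0, a1)) return 0.0;
  if (a0 >= a1) return 0.0;

  // next plane-crossing parameter and per-plane increment, per axis
  const double INF = std::numeric_limits<double>::infinity();
  double axn = INF, ayn = INF, azn = INF, dax = INF, day = INF, daz = INF;
  if (dx != 0.0) {
    dax = g.sx / std::fabs(dx);
    double f = (p1x + a0 * dx - g.x0) / g.sx;
    axn = (dx > 0.0) ? (std::floor(f) + 1.0) * g.sx / dx + (g.x0 - p1x) / dx
                     : (std::ceil(f) - 1.0) * g.sx / dx + (g.x0 - p1x) / dx;
    while (axn <= a0) axn += dax;
  }
  if (dy != 0.0) {
    day = g.sy / std::fabs(dy);
    double f = (p1y + a0 * dy - g.y0) / g.sy;
    ayn = (dy > 0.0) ? (std::floor(f) + 1.0) * g.sy / dy + (g.y0 - p1y) / dy
                     : (std::ceil(f) - 1.0) * g.sy / dy + (g.y0 - p1y) / dy;
    while (ayn <= a0) ayn += day;
  }
  if (dz != 0.0) {
    daz = g.sz / std::fabs(dz);
    double f = (p1z + a0 * dz - g.z0) / g.sz;
    azn = (dz > 0.0) ? (std::floor(f) + 1.0) * g.sz / dz + (g.z0 - p1z) / dz
                     : (std::ceil(f) - 1.0) * g.sz / dz + (g.z0 - p1z) / dz;
    while (azn <= a0) azn += daz;
  }

  double total = 0.0, ac = a0;
  const double tiny = 1e-14;
  while (ac < a1 - tiny) {
    double an = a1;
    if (axn < an) an = axn;
    if (ayn < an) an = ayn;
    if (azn < an) an = azn;
    if (an > a1) an = a1;
    const double seg = an - ac;
    if (seg > 0.0) {
      const double mid = 0.5 * (ac + an);
      int i = (int)std::floor((p1x + mid * dx - g.x0) / g.sx);
      int j = (int)std::floor((p1y + mid * dy - g.y0) / g.sy);
      int k = (int)std::floor((p1z + mid * dz - g.z0) / g.sz);
      if (i >= 0 && i < g.nx && j >= 0 && j < g.ny && k >= 0 && k < g.nz)
        total += g.mu[(size_t)i + (size_t)g.nx * ((size_t)j + (size_t)g.ny * k)] * seg * L;
    }
    if (axn <= an + tiny) axn += dax;
    if (ayn <= an + tiny) ayn += day;
    if (azn <= an + tiny) azn += daz;
    ac = an;
  }
  return total;
}

static Grid make_grid(const NumericVector& mu, const IntegerVector& dim,
                      const NumericVector& spacing, const NumericVector& origin) {
  Grid g;
  g.mu = REAL(mu);
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.x0 = origin[0] - 0.5 * spacing[0];
  g.y0 = origin[1] - 0.5 * spacing[1];
  g.z0 = origin[2] - 0.5 * spacing[2];
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_siddon(NumericVector mu, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix p1, NumericMatrix p2) {
  Grid g = make_grid(mu, dim, spacing, origin);
  const int n = p1.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = siddon_one(g, p1(r, 0), p1(r, 1), p1(r, 2),
                        p2(r, 0), p2(r, 1), p2(r, 2));
  return out;
}

// Primary-fluence dose proxy: proxy(v) = sum_i q_i * exp(-int(src_i -> v)) * mu(v)
// [[Rcpp::export]]
NumericVector cpp_dose_proxy(NumericVector mu, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix src, NumericVector quanta) {
  Grid g = make_grid(mu, dim, spacing, origin);
  const int P = src.nrow();
  const size_t nvox = (size_t)g.nx * g.ny * g.nz;
  NumericVector out(nvox);
  for (int k = 0; k < g.nz; ++k) {
    const double z = origin[2] + k * g.sz;
    for (int j = 0; j < g.ny; ++j) {
      const double y = origin[1] + j * g.sy;
      for (int i = 0; i < g.nx; ++i) {
        const size_t idx = (size_t)i + (size_t)g.nx * ((size_t)j + (size_t)g.ny * k);
        const double m = g.mu[idx];
        if (m <= 0.0) continue;
        const double x = origin[0] + i * g.sx;
        double acc = 0.0;
        for (int p = 0; p < P; ++p) {
          const double I = siddon_one(g, src(p, 0), src(p, 1), src(p, 2), x, y, z);
          acc += quanta[p] * std::exp(-I);
        }
        out[idx] = acc * m;
      }
    }
  }
  return out;
}

// Voxel-driven backprojection for circular fan-beam / FDK on a flat detector.
// filt: filtered projections, dim (P, rows, cols), detector coordinates already
// rescaled to the virtual detector through the isocenter (u0/du/v0/dv in that
// frame). Source at angle b sits at sad * (-sin b, cos b, 0); detector u axis
// is (cos b, sin b, 0), v axis is +z. Accumulates dbeta * sad^2/U^2 * interp.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector filt, IntegerVector pdim,
                              NumericVector beta, double sad,
                              double u0, double du, double v0, double dv,
                              IntegerVector gdim, NumericVector spacing,
                              NumericVector origin, double dbeta) {
  const int P = pdim[0], rows = pdim[1], cols = pdim[2];
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const double* f = REAL(filt);
  NumericVector out((size_t)nx * ny * nz);
  double* o = REAL(out);
  std::vector<double> sb(P), cb(P);
  for (int p = 0; p < P; ++p) { sb[p] = std::sin(beta[p]); cb[p] = std::cos(beta[p]); }

  for (int p = 0; p < P; ++p) {
    const double s = sb[p], c = cb[p];
    for (int k = 0; k < nz; ++k) {
      const double z = origin[2] + k * spacing[2];
      for (int j = 0; j < ny; ++j) {
        const double y = origin[1] + j * spacing[1];
        const double tc_y = y * s;      // part of t = x*c + y*s
        const double sc_y = y * c;      // part of s_comp = -x*s + y*c
        double* orow = o + (size_t)nx * ((size_t)j + (size_t)ny * k);
        for (int i = 0; i < nx; ++i) {
          const double x = origin[0] + i * spacing[0];
          const double t = x * c + tc_y;
          const double U = sad - (-x * s + sc_y);
          if (U <= 1e-9) continue;
          const double up = sad * t / U;
          const double cf = (up - u0) / du;
          if (cf < 0.0 || cf > cols - 1) continue;
          int c0 = (int)cf; if (c0 > cols - 2) c0 = cols - 2;
          const double wc = cf - c0;
          double val;
          if (rows == 1) {
            const double g0 = f[(size_t)p + (size_t)P * ((size_t)rows * c0)];
            const double g1 = f[(size_t)p + (size_t)P * ((size_t)rows * (c0 + 1))];
            val = g0 + wc * (g1 - g0);
          } else {
            const double vp = sad * z / U;
            const double rf = (vp - v0) / dv;
            if (rf < 0.0 || rf > rows - 1) continue;
            int r0 = (int)rf; if (r0 > rows - 2) r0 = rows - 2;
            const double wr = rf - r0;
            const double g00 = f[(size_t)p + (size_t)P * ((size_t)r0 + (size_t)rows * c0)];
            const double g01 = f[(size_t)p + (size_t)P * ((size_t)r0 + (size_t)rows * (c0 + 1))];
            const double g10 = f[(size_t)p + (size_t)P * ((size_t)(r0 + 1) + (size_t)rows * c0)];
            const double g11 = f[(size_t)p + (size_t)P * ((size_t)(r0 + 1) + (size_t)rows * (c0 + 1))];
            const double ga = g00 + wc * (g01 - g00);
            const double gb = g10 + wc * (g11 - g10);
            val = ga + wr * (gb - ga);
          }
          orow[i] += dbeta * sad * sad / (U * U) * val;
        }
      }
    }
  }
  return out;
}
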