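// Geometry kernels: exact anisotropic Euclidean distance transform,
// vessel-tree rasterization, and resampling used by the augmentation suite.
#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double DT_INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower envelope of parabolas), sample spacing h. Sites with
// f = Inf contribute no parabola; if no finite site exists the line stays Inf.
static void dt1d(const std::vector<double>& f, double h, std::vector<double>& d) {
  const int n = (int)f.size();
  d.assign(n, DT_INF);
  std::vector<int> sites;
  sites.reserve(n);
  for (int q = 0; q < n; ++q)
    if (f[q] < DT_INF) sites.push_back(q);
  if (sites.empty()) return;

  const int m = (int)sites.size();
  std::vector<int> v(m, 0);
  std::vector<double> z(m + 1, 0.0);
  int k = 0;
  v[0] = sites[0];
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int j = 1; j < m; ++j) {
    int q = sites[j];
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (k > 0 && s <= z[k]) { --k; } else { break; }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest background
// voxel center, honouring anisotropic spacing. mask != 0 is foreground.
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? DT_INF : 0.0;

  std::vector<double> f, g;
  // axis 1 (x, stride 1)
  f.resize(d1); g.resize(d1);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y) {
      R_xlen_t base = (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
      for (int x = 0; x < d1; ++x) f[x] = D[base + x];
      dt1d(f, spacing[0], g);
      for (int x = 0; x < d1; ++x) D[base + x] = g[x];
    }
  // axis 2 (y, stride d1)
  f.resize(d2); g.resize(d2);
  for (int z = 0; z < d3; ++z)
    for (int x = 0; x < d1; ++x) {
      R_xlen_t base = x + (R_xlen_t)d1 * d2 * z;
      for (int y = 0; y < d2; ++y) f[y] = D[base + (R_xlen_t)d1 * y];
      dt1d(f, spacing[1], g);
      for (int y = 0; y < d2; ++y) D[base + (R_xlen_t)d1 * y] = g[y];
    }
  // axis 3 (z, stride d1*d2)
  f.resize(d3); g.resize(d3);
  for (int y = 0; y < d2; ++y)
    for (int x = 0; x < d1; ++x) {
      R_xlen_t base = x + (R_xlen_t)d1 * y;
      for (int z = 0; z < d3; ++z) f[z] = D[base + (R_xlen_t)d1 * d2 * z];
      dt1d(f, spacing[2], g);
      for (int z = 0; z < d3; ++z) D[base + (R_xlen_t)d1 * d2 * z] = g[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isinf(D[i]) ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}

// Rasterize tube segments onto a voxel grid. segs: n x 7 matrix
// (x0,y0,z0, x1,y1,z1, radius) in mm; voxel i center at (i - 0.5) * spacing
// in 1-based R indexing. A voxel is foreground iff its center-to-axis
// distance is <= radius, or < half the minimum spacing (thin-vessel
// guarantee, so sub-voxel branches still leave a trace).
// [[Rcpp::export(name = ".rasterize_segments")]]
IntegerVector rasterize_segments(NumericMatrix segs, IntegerVector dims,
                                 NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector out(n);
  const double hmin = 0.5 * std::min({spacing[0], spacing[1], spacing[2]});
  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r = segs(s, 6);
    double reff = std::max(r, hmin);
    // bounding box in voxel indices (0-based)
    int lo[3], hi[3];
    double a3[3] = {ax, ay, az}, b3[3] = {bx, by, bz};
    int dd[3] = {d1, d2, d3};
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(a3[k], b3[k]) - reff, mx = std::max(a3[k], b3[k]) + reff;
      lo[k] = std::max(0, (int)std::floor(mn / spacing[k] - 0.5));
      hi[k] = std::min(dd[k] - 1, (int)std::ceil(mx / spacing[k] - 0.5) + 1);
    }
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double len2 = ux * ux + uy * uy + uz * uz;
    for (int z = lo[2]; z <= hi[2]; ++z) {
      double cz = (z + 0.5) * spacing[2];
      for (int y = lo[1]; y <= hi[1]; ++y) {
        double cy = (y + 0.5) * spacing[1];
        R_xlen_t base = (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
        for (int x = lo[0]; x <= hi[0]; ++x) {
          double cx = (x + 0.5) * spacing[0];
          double t = 0.0;
          if (len2 > 0) {
            t = ((cx - ax) * ux + (cy - ay) * uy + (cz - az) * uz) / len2;
            t = std::min(1.0, std::max(0.0, t));
          }
          double px = ax + t * ux - cx, py = ay + t * uy - cy, pz = az + t * uz - cz;
          double dist = std::sqrt(px * px + py * py + pz * pz);
          if (dist <= r || dist < hmin) out[base + x] = 1;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Backward warp: out(v) = vol(v + disp(v)), displacements in voxel units
// (0-based continuous index space). nearest = TRUE uses nearest-neighbour
// (for label maps), else trilinear. Out-of-bounds samples return `fill`.
// [[Rcpp::export(name = ".warp_volume")]]
NumericVector warp_volume(NumericVector vol, IntegerVector dims,
                          NumericVector dx, NumericVector dy, NumericVector dz,
                          bool nearest, double fill) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  R_xlen_t i = 0;
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x, ++i) {
        double sx = x + dx[i], sy = y + dy[i], sz = z + dz[i];
        if (nearest) {
          int ix = (int)std::lround(sx), iy = (int)std::lround(sy), iz = (int)std::lround(sz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= d1 || iy >= d2 || iz >= d3) {
            out[i] = fill;
          } else {
            out[i] = vol[ix + (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz)];
          }
        } else {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double acc = 0.0;
          for (int cz = 0; cz <= 1; ++cz)
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                int ix = x0 + cx, iy = y0 + cy, iz = z0 + cz;
                double w = (cx ? fx : 1 - fx) * (cy ? fy : 1 - fy) * (cz ? fz : 1 - fz);
                double v;
                if (ix < 0 || iy < 0 || iz < 0 || ix >= d1 || iy >= d2 || iz >= d3)
                  v = fill;
                else
                  v = vol[ix + (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz)];
                acc += w * v;
              }
          out[i] = acc;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Binary dilation by a 3x3x3 box (used for per-bin Dice regioning).
// [[Rcpp::export(name = ".dilate_box3")]]
IntegerVector dilate_box3(IntegerVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  IntegerVector out((R_xlen_t)d1 * d2 * d3);
  R_xlen_t i = 0;
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x, ++i) {
        if (!mask[i]) continue;
        for (int cz = std::max(0, z - 1); cz <= std::min(d3 - 1, z + 1); ++cz)
          for (int cy = std::max(0, y - 1); cy <= std::min(d2 - 1, y + 1); ++cy)
            for (int cx = std::max(0, x - 1); cx <= std::min(d1 - 1, x + 1); ++cx)
              out[cx + (R_xlen_t)d1 * (cy + (R_xlen_t)d2 * cz)] = 1;
      }
  out.attr("dim") = dims;
  return out;
}
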