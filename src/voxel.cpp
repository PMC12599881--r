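#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Arrays are stored in R's column-major order with dim = c(ny, nx, nz)
// (or c(ny, nx) for 2D). Index helpers assume that layout.

static inline R_xlen_t idx3(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
}

// Additively stamp isotropic 2D Gaussian spots onto a matrix.
// ys, xs are 1-based (R convention) spot centres in pixels; amps per spot.
// [[Rcpp::export]]
NumericMatrix cpp_stamp_gaussians(NumericMatrix img, NumericVector ys,
                                  NumericVector xs, NumericVector amps,
                                  double sigma_px) {
  int ny = img.nrow(), nx = img.ncol();
  int rad = (int)std::ceil(4.0 * sigma_px);
  double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  for (R_xlen_t k = 0; k < ys.size(); ++k) {
    double yc = ys[k] - 1.0, xc = xs[k] - 1.0, a = amps[k];
    int y0 = std::max(0, (int)std::floor(yc) - rad);
    int y1 = std::min(ny - 1, (int)std::ceil(yc) + rad);
    int x0 = std::max(0, (int)std::floor(xc) - rad);
    int x1 = std::min(nx - 1, (int)std::ceil(xc) + rad);
    if (y1 < y0 || x1 < x0) continue;
    for (int x = x0; x <= x1; ++x) {
      double dx = x - xc;
      for (int y = y0; y <= y1; ++y) {
        double dy = y - yc;
        img(y, x) += a * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return img;
}

// Fill solid ellipsoids (value = max(current, val)) in a 3D array.
// centres are 1-based voxel coordinates (y, x, z); radii in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_stamp_ellipsoids(NumericVector vol, IntegerVector dim,
                                   NumericMatrix centers, NumericVector ry,
                                   NumericVector rx, NumericVector rz,
                                   NumericVector vals) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  for (int k = 0; k < centers.nrow(); ++k) {
    double yc = centers(k, 0) - 1.0, xc = centers(k, 1) - 1.0,
           zc = centers(k, 2) - 1.0;
    double ay = ry[k], ax = rx[k], az = rz[k], v = vals[k];
    int y0 = std::max(0, (int)std::floor(yc - ay));
    int y1 = std::min(ny - 1, (int)std::ceil(yc + ay));
    int x0 = std::max(0, (int)std::floor(xc - ax));
    int x1 = std::min(nx - 1, (int)std::ceil(xc + ax));
    int z0 = std::max(0, (int)std::floor(zc - az));
    int z1 = std::min(nz - 1, (int)std::ceil(zc + az));
    for (int z = z0; z <= z1; ++z) {
      double fz = (z - zc) / az;
      for (int x = x0; x <= x1; ++x) {
        double fx = (x - xc) / ax;
        for (int y = y0; y <= y1; ++y) {
          double fy = (y - yc) / ay;
          if (fy * fy + fx * fx + fz * fz <= 1.0) {
            R_xlen_t i = idx3(y, x, z, ny, nx);
            if (vol[i] < v) vol[i] = v;
          }
        }
      }
    }
  }
  return vol;
}

// 6-connected 3D connected-component labelling (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front();
      q.pop();
      int y = (int)(i % ny);
      int x = (int)((i / ny) % nx);
      int z = (int)(i / ((R_xlen_t)ny * nx));
      const int dy[6] = {-1, 1, 0, 0, 0, 0};
      const int dx[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int yy = y + dy[d], xx = x + dx[d], zz = z + dz[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = idx3(yy, xx, zz, ny, nx);
        if (mask[j] && !lab[j]) {
          lab[j] = cur;
          q.push(j);
        }
      }
    }
  }
  lab.attr("n_labels") = cur;
  return lab;
}

static LogicalVector morph3d(LogicalVector mask, IntegerVector dim, double ry,
                             double rx, double rz, bool dilate) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  LogicalVector out(n);
  int by = (int)std::floor(ry), bx = (int)std::floor(rx),
      bz = (int)std::floor(rz);
  // precompute structuring-element offsets
  std::vector<int> oy, ox, oz;
  for (int dz = -bz; dz <= bz; ++dz)
    for (int dx = -bx; dx <= bx; ++dx)
      for (int dy = -by; dy <= by; ++dy) {
        double f = 0.0;
        if (ry > 0) f += (dy / ry) * (dy / ry);
        else if (dy != 0) continue;
        if (rx > 0) f += (dx / rx) * (dx / rx);
        else if (dx != 0) continue;
        if (rz > 0) f += (dz / rz) * (dz / rz);
        else if (dz != 0) continue;
        if (f <= 1.0) {
          oy.push_back(dy);
          ox.push_back(dx);
          oz.push_back(dz);
        }
      }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = idx3(y, x, z, ny, nx);
        bool hit = dilate ? false : true;
        for (size_t k = 0; k < oy.size(); ++k) {
          int yy = y + oy[k], xx = x + ox[k], zz = z + oz[k];
          bool inside = yy >= 0 && yy < ny && xx >= 0 && xx < nx && zz >= 0 &&
                        zz < nz;
          bool v = inside ? (bool)mask[idx3(yy, xx, zz, ny, nx)] : false;
          if (dilate && v) {
            hit = true;
            break;
          }
          if (!dilate && !v) {
            hit = false;
            break;
          }
        }
        out[i] = hit;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate3d(LogicalVector mask, IntegerVector dim, double ry,
                           double rx, double rz) {
  return morph3d(mask, dim, ry, rx, rz, true);
}

// [[Rcpp::export]]
LogicalVector cpp_erode3d(LogicalVector mask, IntegerVector dim, double ry,
                          double rx, double rz) {
  return morph3d(mask, dim, ry, rx, rz, false);
}

// Translate a matrix by (dy, dx) pixels with bilinear interpolation,
// zero-filling pixels sampled from outside the field.
// out(y, x) = in(y - dy, x - dx)
// [[Rcpp::export]]
NumericMatrix cpp_shift_bilinear(NumericMatrix img, double dy, double dx) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    double xs = x - dx;
    int x0 = (int)std::floor(xs);
    double fx = xs - x0;
    for (int y = 0; y < ny; ++y) {
      double ys = y - dy;
      int y0 = (int)std::floor(ys);
      double fy = ys - y0;
      double v = 0.0;
      for (int j = 0; j <= 1; ++j)
        for (int i = 0; i <= 1; ++i) {
          int yy = y0 + i, xx = x0 + j;
          double w = (i ? fy : 1 - fy) * (j ? fx : 1 - fx);
          if (w > 0 && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
            v += w * img(yy, xx);
        }
      out(y, x) = v;
    }
  }
  return out;
}

// Separable 3D Gaussian smoothing; sigmas in voxels per axis (0 = skip axis).
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim, double sy,
                           double sx, double sz) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector a = clone(vol), b(n);
  double sig[3] = {sy, sx, sz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sig[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * rad + 1);
    double sum = 0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + rad];
    }
    for (auto &v : k) v /= sum;
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          double acc = 0;
          for (int i = -rad; i <= rad; ++i) {
            int yy = y, xx = x, zz = z;
            if (ax == 0) yy += i;
            if (ax == 1) xx += i;
            if (ax == 2) zz += i;
            if (yy < 0) yy = 0;
            if (yy >= ny) yy = ny - 1;
            if (xx < 0) xx = 0;
            if (xx >= nx) xx = nx - 1;
            if (zz < 0) zz = 0;
            if (zz >= nz) zz = nz - 1;
            acc += k[i + rad] * a[idx3(yy, xx, zz, ny, nx)];
          }
          b[idx3(y, x, z, ny, nx)] = acc;
        }
    std::swap(a, b);
  }
  a.attr("dim") = dim;
  return a;
}

static void boundary_coords(LogicalVector mask, IntegerVector dim,
                            std::vector<double> &py, std::vector<double> &px,
                            std::vector<double> &pz, double sy, double sx,
                            double sz) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        if (!mask[idx3(y, x, z, ny, nx)]) continue;
        bool edge = false;
        const int dy[6] = {-1, 1, 0, 0, 0, 0};
        const int dx[6] = {0, 0, -1, 1, 0, 0};
        const int dz[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6 && !edge; ++d) {
          int yy = y + dy[d], xx = x + dx[d], zz = z + dz[d];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            edge = true;
          else if (!mask[idx3(yy, xx, zz, ny, nx)])
            edge = true;
        }
        if (edge) {
          py.push_back(y * sy);
          px.push_back(x * sx);
          pz.push_back(z * sz);
        }
      }
}

// Minimum Euclidean distance (physical units) between the boundary voxel
// centres of two masks; 0 if the masks overlap or touch (6-neighbourhood).
// [[Rcpp::export]]
double cpp_min_boundary_dist(LogicalVector a, LogicalVector b,
                             IntegerVector dim, double sy, double sx,
                             double sz) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  // overlap or 6-adjacency => distance 0
  for (R_xlen_t i = 0; i < n; ++i)
    if (a[i] && b[i]) return 0.0;
  std::vector<double> ay, axv, az, by, bxv, bz;
  boundary_coords(a, dim, ay, axv, az, sy, sx, sz);
  boundary_coords(b, dim, by, bxv, bz, sy, sx, sz);
  if (ay.empty() || by.empty()) return NA_REAL;
  double best = R_PosInf;
  for (size_t i = 0; i < ay.size(); ++i)
    for (size_t j = 0; j < by.size(); ++j) {
      double d = (ay[i] - by[j]) * (ay[i] - by[j]) +
                 (axv[i] - bxv[j]) * (axv[i] - bxv[j]) +
                 (az[i] - bz[j]) * (az[i] - bz[j]);
      if (d < best) best = d;
    }
  double dmin = std::sqrt(best);
  // voxel-adjacent (touching) components: report 0 rather than one spacing
  double touch = std::sqrt(sy * sy + sx * sx + sz * sz) + 1e-9;
  return dmin <= touch ? 0.0 : dmin;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), anisotropic.
// Parabolas with infinite height (no seed in that column yet) are skipped.
static void edt1d(std::vector<double> &f, double step) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!R_FINITE(f[q])) continue;
    double qq = (double)q * step;
    double s = 0.0;
    while (k >= 0) {
      double vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -R_PosInf : s;
    z[k + 1] = R_PosInf;
  }
  if (k < 0) return; // no finite source in this line
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (physical units) from every voxel to the
// nearest TRUE voxel of the mask.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, double sy,
                         double sx, double sz) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : R_PosInf;
  std::vector<double> buf;
  // along y
  buf.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) buf[y] = d[idx3(y, x, z, ny, nx)];
      edt1d(buf, sy);
      for (int y = 0; y < ny; ++y) d[idx3(y, x, z, ny, nx)] = buf[y];
    }
  // along x
  buf.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) buf[x] = d[idx3(y, x, z, ny, nx)];
      edt1d(buf, sx);
      for (int x = 0; x < nx; ++x) d[idx3(y, x, z, ny, nx)] = buf[x];
    }
  // along z
  if (nz > 1) {
    buf.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) buf[z] = d[idx3(y, x, z, ny, nx)];
        edt1d(buf, sz);
        for (int z = 0; z < nz; ++z) d[idx3(y, x, z, ny, nx)] = buf[z];
      }
  }
  return d;
}
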