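// Low-level 3D image primitives: connected components, Euclidean distance
// transform, local thickness, separable Gaussian smoothing and affine
// resampling. Arrays are column-major [x, y, z] as passed from R.
#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  // connectivity: 6 or 26 (in a single-slice array 26 degenerates to 8, 6 to 4)
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  const int *msk = LOGICAL(mask);
  int *lab = INTEGER(labels);
  std::vector<std::array<int, 3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        nbr.push_back({dx, dy, dz});
      }
  int nn = (int)nbr.size();
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!msk[s] || lab[s] != 0) continue;
    lab[s] = ++cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / nxy);
      int rem = (int)(v - (R_xlen_t)z * nxy);
      int y = rem / nx, x = rem % nx;
      for (int b = 0; b < nn; ++b) {
        int xx = x + nbr[b][0], yy = y + nbr[b][1], zz = z + nbr[b][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
        if (msk[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  labels.attr("dim") = dim;
  labels.attr("n_components") = cur;
  return labels;
}

// "no background seen yet" sentinel: larger than any attainable squared
// distance on realistic grids, but finite so the envelope math stays exact
static const double DT_HUGE = 1e15;

// 1D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (k > 0 && s <= zb[k]) { --k; } else break;
    }
    if (s <= zb[k]) { v[k] = q; zb[k + 1] = INFINITY; }
    else { ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT of foreground to the nearest background voxel centre.
// The volume border is treated as background: distances are capped by the
// distance to the first voxel centre outside the grid.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         bool border_background) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  R_xlen_t n = mask.size();
  NumericVector g(n);
  double *gp = REAL(g);
  const int *msk = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) gp[i] = msk[i] ? DT_HUGE : 0.0;
  int mx = std::max(nx, std::max(ny, nz));
  std::vector<double> f(mx), d(mx);
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double *row = gp + (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
      std::copy(row, row + nx, f.begin());
      dt1d(f, d, nx);
      std::copy(d.begin(), d.begin() + nx, row);
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      double *col = gp + (R_xlen_t)z * nxy + x;
      for (int y = 0; y < ny; ++y) f[y] = col[(R_xlen_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) col[(R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  if (nz > 1)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double *pil = gp + (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = pil[(R_xlen_t)z * nxy];
        dt1d(f, d, nz);
        for (int z = 0; z < nz; ++z) pil[(R_xlen_t)z * nxy] = d[z];
      }
  if (border_background) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
          if (!msk[i]) continue;
          double b = std::min({x + 1, nx - x, y + 1, ny - y});
          if (nz > 1) b = std::min(b, (double)std::min(z + 1, nz - z));
          double b2 = b * b;
          if (b2 < gp[i]) gp[i] = b2;
        }
  }
  g.attr("dim") = dim;
  return g;
}

// Local thickness (Hildebrand-Ruegsegger): thickness at a voxel is the
// diameter of the largest inscribed sphere containing it. Computed as
// EDT -> redundant-sphere pruning -> sphere painting, largest radius first.
// Returns thickness in voxel units.
// [[Rcpp::export(name = ".cpp_local_thickness")]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  if (nz <= 1) stop("local thickness is defined on 3D masks");
  NumericVector r2 = cpp_edt_sq(mask, dim, true);
  R_xlen_t n = mask.size();
  const int *msk = LOGICAL(mask);
  const double *r2p = REAL(r2);
  std::vector<R_xlen_t> centers;
  centers.reserve(n / 4);
  // prune centres whose sphere is contained in a neighbour's sphere:
  // sphere(c) subset of sphere(m) iff r(m) >= r(c) + |c - m|
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        if (!msk[i]) continue;
        double ri = std::sqrt(r2p[i]);
        bool redundant = false;
        for (int dz = -1; dz <= 1 && !redundant; ++dz)
          for (int dy = -1; dy <= 1 && !redundant; ++dy)
            for (int dx = -1; dx <= 1 && !redundant; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz) continue;
              R_xlen_t m = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
              if (!msk[m]) continue;
              double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (std::sqrt(r2p[m]) >= ri + dist - 1e-9) redundant = true;
            }
        if (!redundant) centers.push_back(i);
      }
  std::sort(centers.begin(), centers.end(),
            [&](R_xlen_t a, R_xlen_t b) { return r2p[a] > r2p[b]; });
  NumericVector th(n, 0.0);
  double *thp = REAL(th);
  for (R_xlen_t c : centers) {
    double rc2 = r2p[c];
    double rc = std::sqrt(rc2);
    int z = (int)(c / nxy);
    int rem = (int)(c - (R_xlen_t)z * nxy);
    int y = rem / nx, x = rem % nx;
    int ir = (int)rc;
    double diam = 2.0 * rc;
    for (int dz = -ir; dz <= ir; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -ir; dy <= ir; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        double d2yz = (double)(dy * dy + dz * dz);
        if (d2yz >= rc2) continue;
        R_xlen_t base = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx;
        for (int dx = -ir; dx <= ir; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          double d2 = d2yz + dx * dx;
          if (d2 >= rc2) continue;  // strictly inside the open sphere
          R_xlen_t v = base + xx;
          if (msk[v] && thp[v] < diam) thp[v] = diam;
        }
      }
    }
  }
  th.attr("dim") = dim;
  return th;
}

// Separable Gaussian smoothing with reflective padding; sigma per axis in
// voxels, kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  NumericVector cur = clone(vol);
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[std::min((int)sigma.size() - 1, ax)];
    if (s <= 0 || sizes[ax] == 1) continue;
    int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * hw + 1);
    double ksum = 0;
    for (int i = -hw; i <= hw; ++i) {
      k[i + hw] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + hw];
    }
    for (auto &w : k) w /= ksum;
    NumericVector nxt(cur.size());
    double *curp = REAL(cur), *nxtp = REAL(nxt);
    int sn = sizes[ax];
    R_xlen_t st = strides[ax];
    R_xlen_t nlines = cur.size() / sn;
    std::vector<double> line(sn);
    for (R_xlen_t ln = 0; ln < nlines; ++ln) {
      // base offset of this line
      R_xlen_t base;
      if (ax == 0) base = ln * nx;
      else if (ax == 1) {
        R_xlen_t z = ln / nx, x = ln % nx;
        base = z * (R_xlen_t)nx * ny + x;
      } else {
        base = ln;
      }
      for (int i = 0; i < sn; ++i) line[i] = curp[base + (R_xlen_t)i * st];
      for (int i = 0; i < sn; ++i) {
        double acc = 0;
        for (int j = -hw; j <= hw; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;           // reflect
          if (p >= sn) p = 2 * sn - p - 1;
          acc += k[j + hw] * line[p];
        }
        nxtp[base + (R_xlen_t)i * st] = acc;
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// Rigid resampling: out(x) = in(R^T (x - c_out) + c_in), trilinear or nearest.
// R maps input coordinates to output coordinates (both 0-based voxel coords).
// [[Rcpp::export(name = ".cpp_resample_rigid")]]
NumericVector cpp_resample_rigid(NumericVector vol, IntegerVector dim_in,
                                 IntegerVector dim_out, NumericMatrix rot,
                                 NumericVector center_in,
                                 NumericVector center_out, bool nearest,
                                 double fill) {
  int nxi = dim_in[0], nyi = dim_in[1], nzi = dim_in[2];
  int nxo = dim_out[0], nyo = dim_out[1], nzo = dim_out[2];
  NumericVector out((R_xlen_t)nxo * nyo * nzo, fill);
  double *outp = REAL(out);
  const double *volp = REAL(vol);
  double RT[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) RT[i][j] = rot(j, i);  // transpose
  for (int z = 0; z < nzo; ++z)
    for (int y = 0; y < nyo; ++y)
      for (int x = 0; x < nxo; ++x) {
        double px = x - center_out[0], py = y - center_out[1],
               pz = z - center_out[2];
        double sx = RT[0][0] * px + RT[0][1] * py + RT[0][2] * pz + center_in[0];
        double sy = RT[1][0] * px + RT[1][1] * py + RT[1][2] * pz + center_in[1];
        double sz = RT[2][0] * px + RT[2][1] * py + RT[2][2] * pz + center_in[2];
        R_xlen_t o = idx3(x, y, z, nxo, nyo);
        if (nearest) {
          int ix = (int)std::lround(sx), iy = (int)std::lround(sy),
              iz = (int)std::lround(sz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nxi || iy >= nyi ||
              iz >= nzi) continue;
          outp[o] = volp[idx3(ix, iy, iz, nxi, nyi)];
        } else {
          if (sx < 0 || sy < 0 || sz < 0 || sx > nxi - 1 || sy > nyi - 1 ||
              sz > nzi - 1) continue;
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
          int x1 = std::min(x0 + 1, nxi - 1), y1 = std::min(y0 + 1, nyi - 1),
              z1 = std::min(z0 + 1, nzi - 1);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double c00 = volp[idx3(x0, y0, z0, nxi, nyi)] * (1 - fx) +
                       volp[idx3(x1, y0, z0, nxi, nyi)] * fx;
          double c10 = volp[idx3(x0, y1, z0, nxi, nyi)] * (1 - fx) +
                       volp[idx3(x1, y1, z0, nxi, nyi)] * fx;
          double c01 = volp[idx3(x0, y0, z1, nxi, nyi)] * (1 - fx) +
                       volp[idx3(x1, y0, z1, nxi, nyi)] * fx;
          double c11 = volp[idx3(x0, y1, z1, nxi, nyi)] * (1 - fx) +
                       volp[idx3(x1, y1, z1, nxi, nyi)] * fx;
          outp[o] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                    (c01 * (1 - fy) + c11 * fy) * fz;
        }
      }
  out.attr("dim") = dim_out;
  return out;
}

// Bilinear resize of a 2D matrix to out_w x out_h. Output pixel centres map
// to input coordinates via (i + 0.5) * scale - 0.5 (edge-clamped).
// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_w, int out_h) {
  int in_w = img.nrow(), in_h = img.ncol();
  NumericMatrix out(out_w, out_h);
  double sx = (double)in_w / out_w, sy = (double)in_h / out_h;
  for (int j = 0; j < out_h; ++j) {
    double v = (j + 0.5) * sy - 0.5;
    if (v < 0) v = 0;
    if (v > in_h - 1) v = in_h - 1;
    int y0 = (int)std::floor(v), y1 = std::min(y0 + 1, in_h - 1);
    double fy = v - y0;
    for (int i = 0; i < out_w; ++i) {
      double u = (i + 0.5) * sx - 0.5;
      if (u < 0) u = 0;
      if (u > in_w - 1) u = in_w - 1;
      int x0 = (int)std::floor(u), x1 = std::min(x0 + 1, in_w - 1);
      double fx = u - x0;
      out(i, j) = img(x0, y0) * (1 - fx) * (1 - fy) +
                  img(x1, y0) * fx * (1 - fy) +
                  img(x0, y1) * (1 - fx) * fy + img(x1, y1) * fx * fy;
    }
  }
  return out;
}
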