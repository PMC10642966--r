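// Low-level numerical kernels: red-black SOR Laplace solver, N-D linear /
// nearest interpolation with clamped (no-wrap) sampling, separable Gaussian
// smoothing, exact Euclidean distance transform, streamline thickness
// tracing, scattered-to-grid interpolation, and connected components.
// All arrays are passed flat in R (column-major) with an explicit dims vector.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

// ---------------------------------------------------------------------------
// Red-black successive over-relaxation for the masked discrete Laplace
// equation. 6-neighbour stencil; walls (neighbours outside domain|fixed) are
// zero-flux via stencil renormalisation. 'fixed' cells hold Dirichlet values.
// [[Rcpp::export]]
List cpp_solve_laplace(LogicalVector domain, LogicalVector fixed,
                       NumericVector init, IntegerVector dims,
                       double omega, double tol, int max_iter) {
  const int* d = INTEGER(dims);
  NumericVector x = clone(init);
  // collect domain voxel coordinates, split by parity
  std::vector<int> vox[2];
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int id = idx3(i, j, k, d);
        if (domain[id] && !fixed[id]) vox[(i + j + k) & 1].push_back(id);
      }
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  double maxdelta = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    maxdelta = 0.0;
    for (int par = 0; par < 2; ++par) {
      for (size_t q = 0; q < vox[par].size(); ++q) {
        int id = vox[par][q];
        int k = id / (d[0] * d[1]);
        int r = id - k * d[0] * d[1];
        int j = r / d[0];
        int i = r - j * d[0];
        double s = 0.0; int n = 0;
        for (int m = 0; m < 6; ++m) {
          int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
            continue;
          int nid = idx3(ii, jj, kk, d);
          if (domain[nid] || fixed[nid]) { s += x[nid]; ++n; }
        }
        if (n == 0) continue;
        double target = s / n;
        double nv = (1.0 - omega) * x[id] + omega * target;
        double delta = std::fabs(nv - x[id]);
        if (delta > maxdelta) maxdelta = delta;
        x[id] = nv;
      }
    }
    if (maxdelta < tol) { ++it; break; }
  }
  // residual: max |x - mean(neighbours)| over interior
  double resid = 0.0;
  for (int par = 0; par < 2; ++par)
    for (size_t q = 0; q < vox[par].size(); ++q) {
      int id = vox[par][q];
      int k = id / (d[0] * d[1]);
      int r = id - k * d[0] * d[1];
      int j = r / d[0];
      int i = r - j * d[0];
      double s = 0.0; int n = 0;
      for (int m = 0; m < 6; ++m) {
        int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
          continue;
        int nid = idx3(ii, jj, kk, d);
        if (domain[nid] || fixed[nid]) { s += x[nid]; ++n; }
      }
      if (n == 0) continue;
      double rr = std::fabs(x[id] - s / n);
      if (rr > resid) resid = rr;
    }
  return List::create(_["field"] = x, _["iterations"] = it,
                      _["residual"] = resid,
                      _["converged"] = (maxdelta < tol));
}

// ---------------------------------------------------------------------------
// Connected components. dims length 2 or 3. connectivity: 4/8 in 2D, 6/26 in 3D.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  int n = d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (nd == 2 && dk != 0) continue;
        bool keep;
        if (nd == 2) keep = (connectivity == 8) ? true : (manh == 1);
        else keep = (connectivity == 26) ? true : (manh == 1);
        if (keep) offs.push_back({di, dj, dk});
      }
  int cur = 0;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++cur;
    stack.push_back(start);
    lab[start] = cur;
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      int k = id / (d[0] * d[1]);
      int r = id - k * d[0] * d[1];
      int j = r / d[0];
      int i = r - j * d[0];
      for (size_t m = 0; m < offs.size(); ++m) {
        int ii = i + offs[m][0], jj = j + offs[m][1], kk = k + offs[m][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
          continue;
        int nid = idx3(ii, jj, kk, d);
        if (mask[nid] && !lab[nid]) { lab[nid] = cur; stack.push_back(nid); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Linear interpolation with clamped sampling (no wrap). pts: n x D, 0-based
// continuous voxel coordinates. dims length D in {2,3}.
// [[Rcpp::export]]
NumericVector cpp_interp_linear(NumericVector img, IntegerVector dims,
                                NumericMatrix pts) {
  int nd = dims.size();
  int n = pts.nrow();
  NumericVector out(n);
  if (nd == 2) {
    int nx = dims[0], ny = dims[1];
    for (int p = 0; p < n; ++p) {
      double x = pts(p, 0), y = pts(p, 1);
      if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
      if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
      int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
      int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
      double fx = x - x0, fy = y - y0;
      double v00 = img[x0 + nx * y0],     v10 = img[x0 + 1 + nx * y0];
      double v01 = img[x0 + nx * (y0+1)], v11 = img[x0 + 1 + nx * (y0+1)];
      out[p] = (1-fx)*(1-fy)*v00 + fx*(1-fy)*v10 + (1-fx)*fy*v01 + fx*fy*v11;
    }
  } else {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    for (int p = 0; p < n; ++p) {
      double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
      if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
      if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
      if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
      int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
      int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
      int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      double acc = 0.0;
      for (int c = 0; c < 8; ++c) {
        int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
        double w = (dx ? fx : 1-fx) * (dy ? fy : 1-fy) * (dz ? fz : 1-fz);
        acc += w * img[(x0+dx) + nx * ((y0+dy) + ny * (z0+dz))];
      }
      out[p] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp_nearest(NumericVector img, IntegerVector dims,
                                 NumericMatrix pts) {
  int nd = dims.size();
  int n = pts.nrow();
  NumericVector out(n);
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  for (int p = 0; p < n; ++p) {
    int c[3] = {0, 0, 0};
    for (int a = 0; a < nd; ++a) {
      double v = pts(p, a);
      int iv = (int)std::lround(v);
      if (iv < 0) iv = 0;
      if (iv > d[a] - 1) iv = d[a] - 1;
      c[a] = iv;
    }
    out[p] = img[c[0] + d[0] * (c[1] + d[1] * c[2])];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, replicate boundary. sigma in pixels per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector img, IntegerVector dims,
                               NumericVector sigma) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  int n = d[0] * d[1] * d[2];
  NumericVector cur = clone(img);
  NumericVector tmp(n);
  int stride[3] = {1, d[0], d[0] * d[1]};
  for (int ax = 0; ax < nd; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * rad + 1);
    double tot = 0;
    for (int m = -rad; m <= rad; ++m) {
      w[m + rad] = std::exp(-0.5 * m * m / (s * s));
      tot += w[m + rad];
    }
    for (size_t m = 0; m < w.size(); ++m) w[m] /= tot;
    int len = d[ax];
    // iterate over all lines along axis ax
    int oth[2], no = 0;
    for (int a = 0; a < 3; ++a) if (a != ax) oth[no++] = a;
    for (int b = 0; b < d[oth[1]]; ++b)
      for (int a = 0; a < d[oth[0]]; ++a) {
        int base = a * stride[oth[0]] + b * stride[oth[1]];
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int m = -rad; m <= rad; ++m) {
            int ii = i + m;
            if (ii < 0) ii = 0;
            if (ii > len - 1) ii = len - 1;
            acc += w[m + rad] * cur[base + ii * stride[ax]];
          }
          tmp[base + i * stride[ax]] = acc;
        }
      }
    std::copy(tmp.begin(), tmp.end(), cur.begin());
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), with
// anisotropic spacing; distance in the same units as 'spacing' from the
// nearest TRUE site. Returns +Inf where no site exists.
static void edt1d(std::vector<double>& f, std::vector<double>& out, int n,
                  double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int first = -1;
  for (int q = 0; q < n; ++q) if (f[q] != INF) { first = q; break; }
  if (first < 0) {
    for (int q = 0; q < n; ++q) out[q] = INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    while (true) {
      int p = v[k];
      // intersection abscissa in physical units (z is compared to h*q)
      double s = ((f[q] + h*h*q*q) - (f[p] + h*h*p*p)) /
                 (2.0*h*(q - p));
      if (s <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; break; }
      } else {
        ++k; v[k] = q; z[k] = s; z[k+1] = INF; break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < h * q) ++k;
    int p = v[k];
    double dq = h * (q - p);
    out[q] = dq * dq + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector sites, IntegerVector dims,
                      NumericVector spacing) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  double sp[3] = {spacing[0], nd > 1 ? spacing[1] : 1.0, nd > 2 ? spacing[2] : 1.0};
  int n = d[0] * d[1] * d[2];
  std::vector<double> dist(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) dist[i] = sites[i] ? 0.0 : INF;
  int stride[3] = {1, d[0], d[0] * d[1]};
  for (int ax = 0; ax < (nd > 2 ? 3 : 2); ++ax) {
    int len = d[ax];
    std::vector<double> f(len), out(len);
    int oth[2], no = 0;
    for (int a = 0; a < 3; ++a) if (a != ax) oth[no++] = a;
    for (int b = 0; b < d[oth[1]]; ++b)
      for (int a = 0; a < d[oth[0]]; ++a) {
        int base = a * stride[oth[0]] + b * stride[oth[1]];
        for (int i = 0; i < len; ++i) f[i] = dist[base + i * stride[ax]];
        edt1d(f, out, len, sp[ax]);
        for (int i = 0; i < len; ++i) dist[base + i * stride[ax]] = out[i];
      }
  }
  NumericVector res(n);
  for (int i = 0; i < n; ++i)
    res[i] = dist[i] == INF ? R_PosInf : std::sqrt(dist[i]);
  return res;
}

// ---------------------------------------------------------------------------
// For every zero pixel of a 2D label image, the label of the nearest nonzero
// pixel (Euclidean with spacing); exact ring search; ties broken by the
// smaller label id. Nonzero pixels keep their label.
// [[Rcpp::export]]
IntegerVector cpp_impute_nearest(IntegerVector labels, IntegerVector dims,
                                 NumericVector spacing) {
  int nx = dims[0], ny = dims[1];
  double sx = spacing[0], sy = spacing[1];
  IntegerVector out = clone(labels);
  double maxsp = std::max(sx, sy), minsp = std::min(sx, sy);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (labels[i + nx * j] != 0) continue;
      double best = std::numeric_limits<double>::infinity();
      int bestlab = 0;
      int maxr = std::max(nx, ny);
      for (int r = 1; r <= maxr; ++r) {
        // once a candidate is found, search up to the ring that could still
        // contain something closer
        if (best < std::numeric_limits<double>::infinity() &&
            (r - 1) * minsp > best) break;
        for (int dj = -r; dj <= r; ++dj) {
          for (int di = -r; di <= r; ++di) {
            if (std::max(std::abs(di), std::abs(dj)) != r) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
            int lab = labels[ii + nx * jj];
            if (lab == 0) continue;
            double dd = std::sqrt(di*sx*di*sx + dj*sy*dj*sy);
            if (dd < best - 1e-12 ||
                (std::fabs(dd - best) <= 1e-12 && lab < bestlab)) {
              best = dd; bestlab = lab;
            }
          }
        }
      }
      out[i + nx * j] = bestlab;
    }
  (void)maxsp;
  return out;
}

// ---------------------------------------------------------------------------
// Streamline thickness: trace along +/- grad(io) from seed points (0-based
// voxel coords) until io <= lo or >= hi; RK4; returns arc length in mm.
// grad arrays are d(io)/d(index). spacing converts index steps to mm.
static inline double interp3(const double* img, const int* d, double x,
                             double y, double z) {
  if (x < 0) x = 0; if (x > d[0]-1) x = d[0]-1;
  if (y < 0) y = 0; if (y > d[1]-1) y = d[1]-1;
  if (z < 0) z = 0; if (z > d[2]-1) z = d[2]-1;
  int x0 = (int)std::floor(x); if (x0 > d[0]-2) x0 = d[0]-2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > d[1]-2) y0 = d[1]-2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > d[2]-2) z0 = d[2]-2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0;
  for (int c = 0; c < 8; ++c) {
    int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
    double w = (dx ? fx : 1-fx) * (dy ? fy : 1-fy) * (dz ? fz : 1-fz);
    acc += w * img[(x0+dx) + d[0] * ((y0+dy) + d[1] * (z0+dz))];
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_trace_thickness(NumericVector io, NumericVector gx,
                                  NumericVector gy, NumericVector gz,
                                  IntegerVector dims, NumericVector spacing,
                                  NumericMatrix seeds, double step_mm,
                                  double lo, double hi, double max_mm) {
  const int* d = INTEGER(dims);
  const double* pio = REAL(io);
  const double* pgx = REAL(gx);
  const double* pgy = REAL(gy);
  const double* pgz = REAL(gz);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  int n = seeds.nrow();
  NumericVector out(n);
  int maxsteps = (int)std::ceil(max_mm / step_mm);
  for (int p = 0; p < n; ++p) {
    double total = 0.0;
    bool bad = false;
    if (ISNA(seeds(p, 0)) || ISNAN(seeds(p, 0))) { out[p] = NA_REAL; continue; }
    for (int dir = -1; dir <= 1; dir += 2) {
      double x = seeds(p, 0), y = seeds(p, 1), z = seeds(p, 2);
      int steps = 0;
      while (steps < maxsteps) {
        double v = interp3(pio, d, x, y, z);
        if ((dir < 0 && v <= lo) || (dir > 0 && v >= hi)) break;
        // direction in world coords from index-space gradient
        auto dirat = [&](double xx, double yy, double zz, double* w) {
          double gxi = interp3(pgx, d, xx, yy, zz);
          double gyi = interp3(pgy, d, xx, yy, zz);
          double gzi = interp3(pgz, d, xx, yy, zz);
          double wx = gxi / sx, wy = gyi / sy, wz = gzi / sz; // world gradient
          double nrm = std::sqrt(wx*wx + wy*wy + wz*wz);
          if (nrm < 1e-12) { w[0] = w[1] = w[2] = 0; return false; }
          w[0] = dir * wx / nrm; w[1] = dir * wy / nrm; w[2] = dir * wz / nrm;
          return true;
        };
        double k1[3], k2[3], k3[3], k4[3];
        if (!dirat(x, y, z, k1)) { bad = true; break; }
        double h = step_mm;
        if (!dirat(x + 0.5*h*k1[0]/sx, y + 0.5*h*k1[1]/sy, z + 0.5*h*k1[2]/sz, k2)) { bad = true; break; }
        if (!dirat(x + 0.5*h*k2[0]/sx, y + 0.5*h*k2[1]/sy, z + 0.5*h*k2[2]/sz, k3)) { bad = true; break; }
        if (!dirat(x + h*k3[0]/sx, y + h*k3[1]/sy, z + h*k3[2]/sz, k4)) { bad = true; break; }
        double wx = (k1[0] + 2*k2[0] + 2*k3[0] + k4[0]) / 6.0;
        double wy = (k1[1] + 2*k2[1] + 2*k3[1] + k4[1]) / 6.0;
        double wz = (k1[2] + 2*k2[2] + 2*k3[2] + k4[2]) / 6.0;
        x += h * wx / sx; y += h * wy / sy; z += h * wz / sz;
        total += h;
        ++steps;
        if (x < 0 || y < 0 || z < 0 || x > d[0]-1 || y > d[1]-1 || z > d[2]-1)
          break;
      }
      if (steps >= maxsteps) bad = true;
      if (bad) break;
    }
    out[p] = bad ? NA_REAL : total;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Scattered-to-grid inverse-distance interpolation. uv: n x 2 in [0,1]^2;
// vals: n x m; grid nodes at ((i+0.5)/nr, (j+0.5)/nc). k nearest-ish points
// gathered by expanding cell rings. Returns values (nr*nc x m) and the
// nearest-point distance per node (for the validity mask).
// [[Rcpp::export]]
List cpp_idw_grid(NumericMatrix uv, NumericMatrix vals, int nr, int nc,
                  int k) {
  int n = uv.nrow(), m = vals.ncol();
  // bin points into grid cells
  std::vector<std::vector<int>> bins(nr * nc);
  for (int p = 0; p < n; ++p) {
    int i = (int)std::floor(uv(p, 0) * nr); if (i < 0) i = 0; if (i > nr-1) i = nr-1;
    int j = (int)std::floor(uv(p, 1) * nc); if (j < 0) j = 0; if (j > nc-1) j = nc-1;
    bins[i + nr * j].push_back(p);
  }
  NumericMatrix out(nr * nc, m);
  NumericVector ndist(nr * nc);
  double cw_u = 1.0 / nr, cw_v = 1.0 / nc;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double u0 = (i + 0.5) / nr, v0 = (j + 0.5) / nc;
      std::vector<int> cand;
      int maxr = std::max(nr, nc);
      int found_r = -1;
      for (int r = 0; r <= maxr; ++r) {
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            if (std::max(std::abs(di), std::abs(dj)) != r) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            const std::vector<int>& b = bins[ii + nr * jj];
            cand.insert(cand.end(), b.begin(), b.end());
          }
        if ((int)cand.size() >= k && found_r < 0) found_r = r;
        if (found_r >= 0 && r >= found_r + 1) break; // one safety ring
      }
      // take k closest among candidates
      std::vector<std::pair<double,int>> ds;
      ds.reserve(cand.size());
      for (size_t q = 0; q < cand.size(); ++q) {
        int p = cand[q];
        double du = uv(p, 0) - u0, dv = uv(p, 1) - v0;
        ds.push_back({du*du + dv*dv, p});
      }
      std::sort(ds.begin(), ds.end());
      int kk = std::min((int)ds.size(), k);
      double eps = 1e-6 * (cw_u * cw_u + cw_v * cw_v);
      double wsum = 0;
      std::vector<double> acc(m, 0.0);
      for (int q = 0; q < kk; ++q) {
        double w = 1.0 / (ds[q].first + eps);
        wsum += w;
        int p = ds[q].second;
        for (int c = 0; c < m; ++c) acc[c] += w * vals(p, c);
      }
      int node = i + nr * j;
      if (kk == 0 || wsum <= 0) {
        for (int c = 0; c < m; ++c) out(node, c) = NA_REAL;
        ndist[node] = R_PosInf;
      } else {
        for (int c = 0; c < m; ++c) out(node, c) = acc[c] / wsum;
        ndist[node] = std::sqrt(ds[0].first);
      }
    }
  return List::create(_["values"] = out, _["nearest_dist"] = ndist);
}

// ---------------------------------------------------------------------------
// Fast approximate Gaussian via three box passes per axis (standard
// regularization smoothing for demons-style registration). Replicate
// boundary; preserves the mean.
static void box1d(std::vector<double>& line, std::vector<double>& tmp,
                  int n, int r) {
  if (r <= 0) { return; }
  double norm = 1.0 / (2 * r + 1);
  double acc = 0.0;
  for (int i = -r; i <= r; ++i) {
    int ii = i < 0 ? 0 : (i > n - 1 ? n - 1 : i);
    acc += line[ii];
  }
  for (int i = 0; i < n; ++i) {
    tmp[i] = acc * norm;
    int add = i + r + 1; if (add > n - 1) add = n - 1;
    int rem = i - r; if (rem < 0) rem = 0;
    acc += line[add] - line[rem];
  }
  std::copy(tmp.begin(), tmp.begin() + n, line.begin());
}

// [[Rcpp::export]]
NumericVector cpp_box_smooth(NumericVector img, IntegerVector dims,
                             NumericVector sigma) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  NumericVector cur = clone(img);
  int stride[3] = {1, d[0], d[0] * d[1]};
  for (int ax = 0; ax < nd; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    // three equal boxes approximating a Gaussian of width s
    int r = (int)std::floor(std::sqrt(s * s + 1.0 / 12.0));
    if (r < 1) r = 1;
    int len = d[ax];
    std::vector<double> line(len), tmp(len);
    int oth[2], no = 0;
    for (int a = 0; a < 3; ++a) if (a != ax) oth[no++] = a;
    for (int b = 0; b < d[oth[1]]; ++b)
      for (int a = 0; a < d[oth[0]]; ++a) {
        int base = a * stride[oth[0]] + b * stride[oth[1]];
        for (int i = 0; i < len; ++i) line[i] = cur[base + i * stride[ax]];
        box1d(line, tmp, len, r);
        box1d(line, tmp, len, r);
        box1d(line, tmp, len, r);
        for (int i = 0; i < len; ++i) cur[base + i * stride[ax]] = line[i];
      }
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Displacement-field primitives, fully in C++ to avoid per-call R overhead.
static inline double sampleLin(const double* img, const int* d, int nd,
                               const double* p) {
  if (nd == 2) {
    double x = p[0], y = p[1];
    if (x < 0) x = 0;
    if (x > d[0]-1) x = d[0]-1;
    if (y < 0) y = 0;
    if (y > d[1]-1) y = d[1]-1;
    int x0 = (int)std::floor(x); if (x0 > d[0]-2) x0 = d[0]-2; if (x0 < 0) x0 = 0;
    int y0 = (int)std::floor(y); if (y0 > d[1]-2) y0 = d[1]-2; if (y0 < 0) y0 = 0;
    double fx = x - x0, fy = y - y0;
    return (1-fx)*(1-fy)*img[x0 + d[0]*y0] + fx*(1-fy)*img[x0+1 + d[0]*y0] +
           (1-fx)*fy*img[x0 + d[0]*(y0+1)] + fx*fy*img[x0+1 + d[0]*(y0+1)];
  }
  return interp3(img, d, p[0], p[1], p[2]);
}

// compose: uc = ua + ub(x + ua(x))
// [[Rcpp::export]]
List cpp_compose_disp(List ua, List ub, IntegerVector dims) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  int n = d[0] * d[1] * d[2];
  std::vector<const double*> pa(nd), pb(nd);
  for (int c = 0; c < nd; ++c) {
    pa[c] = REAL((SEXP)ua[c]);
    pb[c] = REAL((SEXP)ub[c]);
  }
  List out(nd);
  std::vector<double*> po(nd);
  for (int c = 0; c < nd; ++c) {
    NumericVector v(n);
    out[c] = v;
    po[c] = REAL((SEXP)out[c]);
  }
  double p[3];
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int id = i + d[0] * (j + d[1] * k);
        p[0] = i + pa[0][id];
        p[1] = j + pa[1][id];
        if (nd == 3) p[2] = k + pa[2][id];
        for (int c = 0; c < nd; ++c)
          po[c][id] = pa[c][id] + sampleLin(pb[c], d, nd, p);
      }
  return out;
}

// scaling and squaring: disp = exp(vel)
// [[Rcpp::export]]
List cpp_exp_velocity(List vel, IntegerVector dims, double target) {
  int nd = dims.size();
  int n = 1;
  for (int a = 0; a < nd; ++a) n *= dims[a];
  double mx = 0;
  for (int id = 0; id < n; ++id) {
    double s = 0;
    for (int c = 0; c < nd; ++c) {
      double v = REAL((SEXP)vel[c])[id];
      s += v * v;
    }
    if (s > mx) mx = s;
  }
  mx = std::sqrt(mx);
  List u(nd);
  if (mx < 1e-12) {
    for (int c = 0; c < nd; ++c) u[c] = NumericVector(n);
    return u;
  }
  int nsq = 0;
  while (mx / std::pow(2.0, nsq) > target) ++nsq;
  double scale = 1.0 / std::pow(2.0, nsq);
  for (int c = 0; c < nd; ++c) {
    NumericVector v(n);
    const double* pv = REAL((SEXP)vel[c]);
    for (int id = 0; id < n; ++id) v[id] = pv[id] * scale;
    u[c] = v;
  }
  for (int s = 0; s < nsq; ++s) u = cpp_compose_disp(u, u, dims);
  return u;
}

// warp image through displacement: out(x) = img(x + u(x)); order 0 or 1
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, IntegerVector dims, List u,
                       int order) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  int n = d[0] * d[1] * d[2];
  std::vector<const double*> pu(nd);
  for (int c = 0; c < nd; ++c) pu[c] = REAL((SEXP)u[c]);
  const double* pi = REAL(img);
  NumericVector out(n);
  double p[3];
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int id = i + d[0] * (j + d[1] * k);
        p[0] = i + pu[0][id];
        p[1] = j + pu[1][id];
        if (nd == 3) p[2] = k + pu[2][id];
        if (order == 1) out[id] = sampleLin(pi, d, nd, p);
        else {
          int c0[3] = {0, 0, 0};
          for (int a = 0; a < nd; ++a) {
            int iv = (int)std::lround(p[a]);
            if (iv < 0) iv = 0;
            if (iv > d[a]-1) iv = d[a]-1;
            c0[a] = iv;
          }
          out[id] = pi[c0[0] + d[0] * (c0[1] + d[1] * c0[2])];
        }
      }
  return out;
}

// fixed-point inversion of a displacement field
// [[Rcpp::export]]
List cpp_invert_disp(List u, IntegerVector dims, int iters) {
  int nd = dims.size();
  int d[3] = {dims[0], nd > 1 ? dims[1] : 1, nd > 2 ? dims[2] : 1};
  int n = d[0] * d[1] * d[2];
  std::vector<const double*> pu(nd);
  for (int c = 0; c < nd; ++c) pu[c] = REAL((SEXP)u[c]);
  List inv(nd);
  std::vector<double*> pv(nd);
  for (int c = 0; c < nd; ++c) {
    NumericVector v(n);
    inv[c] = v;
    pv[c] = REAL((SEXP)inv[c]);
  }
  double p[3];
  for (int it = 0; it < iters; ++it) {
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int id = i + d[0] * (j + d[1] * k);
          p[0] = i + pv[0][id];
          p[1] = j + pv[1][id];
          if (nd == 3) p[2] = k + pv[2][id];
          for (int c = 0; c < nd; ++c)
            pv[c][id] = -sampleLin(pu[c], d, nd, p);
        }
  }
  return inv;
}
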