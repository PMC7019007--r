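#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Column-major linear index for a 3D array, 0-based.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Neighbour offset table: 6- or 26-connectivity.
static void neigh_offsets(int connectivity, std::vector<int>& dx,
                          std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (connectivity == 6) {
    const int ox[6] = {1,-1,0,0,0,0}, oy[6] = {0,0,1,-1,0,0}, oz[6] = {0,0,0,0,1,-1};
    for (int t = 0; t < 6; ++t) { dx.push_back(ox[t]); dy.push_back(oy[t]); dz.push_back(oz[t]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = mask.size();
  std::vector<char> m(nvox);
  const int* mp = LOGICAL(mask);
  for (R_xlen_t t = 0; t < nvox; ++t) m[t] = (char)(mp[t] == 1);
  IntegerVector labels(nvox, 0);
  int* lab = INTEGER(labels);
  std::vector<int> dx, dy, dz;
  neigh_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  int current = 0;
  std::queue<R_xlen_t> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = lin(i, j, k, nx, ny);
        if (!m[p] || lab[p] != 0) continue;
        ++current;
        lab[p] = current;
        q.push(p);
        while (!q.empty()) {
          R_xlen_t c = q.front(); q.pop();
          int ci = (int)(c % nx);
          int cj = (int)((c / nx) % ny);
          int ck = (int)(c / ((R_xlen_t)nx * ny));
          for (int t = 0; t < nn; ++t) {
            int ii = ci + dx[t], jj = cj + dy[t], kk = ck + dz[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t pp = lin(ii, jj, kk, nx, ny);
            if (m[pp] && lab[pp] == 0) { lab[pp] = current; q.push(pp); }
          }
        }
      }
  return labels;
}

// Flood fill of `open` voxels from a seed (0-based i,j,k).
// [[Rcpp::export]]
LogicalVector cpp_flood_region(LogicalVector open, IntegerVector dims,
                               IntegerVector seed, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = open.size();
  std::vector<char> op(nvox);
  const int* opp = LOGICAL(open);
  for (R_xlen_t t = 0; t < nvox; ++t) op[t] = (char)(opp[t] == 1);
  LogicalVector out(nvox, false);
  int* ob = LOGICAL(out);
  std::vector<int> dx, dy, dz;
  neigh_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  R_xlen_t s = lin(seed[0], seed[1], seed[2], nx, ny);
  if (!op[s]) stop("seed voxel is not in the fillable region");
  std::queue<R_xlen_t> q;
  ob[s] = 1; q.push(s);
  while (!q.empty()) {
    R_xlen_t c = q.front(); q.pop();
    int ci = (int)(c % nx);
    int cj = (int)((c / nx) % ny);
    int ck = (int)(c / ((R_xlen_t)nx * ny));
    for (int t = 0; t < nn; ++t) {
      int ii = ci + dx[t], jj = cj + dy[t], kk = ck + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t pp = lin(ii, jj, kk, nx, ny);
      if (op[pp] && !ob[pp]) { ob[pp] = 1; q.push(pp); }
    }
  }
  return out;
}

// Discrete Euclidean ball structuring element, dilation/erosion.
// Outside the grid counts as background for dilation; for erosion the
// out-of-grid value is `border` (0 = background so edges erode, 1 =
// foreground so the grid border acts as padding).
// [[Rcpp::export]]
LogicalVector cpp_ball_morph(LogicalVector mask, IntegerVector dims,
                             int radius, bool dilate, int border = 0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (radius == 0) return clone(mask);
  std::vector<int> bx, by, bz;
  const int r2 = radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c)
        if (a * a + b * b + c * c <= r2) { bx.push_back(a); by.push_back(b); bz.push_back(c); }
  const int nb = (int)bx.size();
  const R_xlen_t nvox = mask.size();
  std::vector<char> m(nvox);
  const int* mp = LOGICAL(mask);
  for (R_xlen_t t = 0; t < nvox; ++t) m[t] = (char)(mp[t] == 1);
  LogicalVector out(nvox, dilate ? false : true);
  int* ob = LOGICAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = lin(i, j, k, nx, ny);
        if (dilate) {
          if (!m[p]) continue;
          for (int t = 0; t < nb; ++t) {
            int ii = i + bx[t], jj = j + by[t], kk = k + bz[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            ob[lin(ii, jj, kk, nx, ny)] = 1;
          }
        } else {
          bool keep = true;
          for (int t = 0; t < nb; ++t) {
            int ii = i + bx[t], jj = j + by[t], kk = k + bz[t];
            bool outside = (ii < 0 || jj < 0 || kk < 0 || ii >= nx ||
                            jj >= ny || kk >= nz);
            bool val = outside ? (border != 0) : (m[lin(ii, jj, kk, nx, ny)] != 0);
            if (!val) { keep = false; break; }
          }
          ob[p] = keep ? 1 : 0;
        }
      }
  return out;
}

// Per-slice 2D hole filling along `axis` (1, 2 or 3, R convention):
// background 4-connected (in-slice) regions not reachable from the slice
// border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dims,
                                    int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out = clone(mask);
  // In-slice axes u, v; slice axis w.
  int nu, nv, nw;
  if (axis == 3)      { nu = nx; nv = ny; nw = nz; }
  else if (axis == 2) { nu = nx; nv = nz; nw = ny; }
  else                { nu = ny; nv = nz; nw = nx; }
  std::vector<char> reach((size_t)nu * nv);
  const int du[4] = {1,-1,0,0}, dv[4] = {0,0,1,-1};
  for (int w = 0; w < nw; ++w) {
    std::fill(reach.begin(), reach.end(), 0);
    std::queue<int> q;
    auto idx3 = [&](int u, int v) -> R_xlen_t {
      if (axis == 3)      return lin(u, v, w, nx, ny);
      else if (axis == 2) return lin(u, w, v, nx, ny);
      else                return lin(w, u, v, nx, ny);
    };
    // seed background flood from the slice border
    for (int u = 0; u < nu; ++u)
      for (int v = 0; v < nv; ++v) {
        if (u != 0 && u != nu - 1 && v != 0 && v != nv - 1) continue;
        if (!mask[idx3(u, v)] && !reach[(size_t)u + (size_t)nu * v]) {
          reach[(size_t)u + (size_t)nu * v] = 1;
          q.push(u + nu * v);
        }
      }
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cu = c % nu, cv = c / nu;
      for (int t = 0; t < 4; ++t) {
        int uu = cu + du[t], vv = cv + dv[t];
        if (uu < 0 || vv < 0 || uu >= nu || vv >= nv) continue;
        size_t rp = (size_t)uu + (size_t)nu * vv;
        if (!reach[rp] && !mask[idx3(uu, vv)]) { reach[rp] = 1; q.push(uu + nu * vv); }
      }
    }
    for (int u = 0; u < nu; ++u)
      for (int v = 0; v < nv; ++v)
        if (!mask[idx3(u, v)] && !reach[(size_t)u + (size_t)nu * v])
          out[idx3(u, v)] = true;
  }
  return out;
}

// Trilinear sampling at continuous 0-based voxel coordinates (N x 3).
// Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = pts(t, 0), y = pts(t, 1), z = pts(t, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) { out[t] = fill; continue; }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = vol[lin(i0, j0, k0, nx, ny)], c100 = vol[lin(i1, j0, k0, nx, ny)];
    double c010 = vol[lin(i0, j1, k0, nx, ny)], c110 = vol[lin(i1, j1, k0, nx, ny)];
    double c001 = vol[lin(i0, j0, k1, nx, ny)], c101 = vol[lin(i1, j0, k1, nx, ny)];
    double c011 = vol[lin(i0, j1, k1, nx, ny)], c111 = vol[lin(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[t] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_nearest_sample(NumericVector vol, IntegerVector dims,
                                 NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = pts(t, 0), y = pts(t, 1), z = pts(t, 2);
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) { out[t] = fill; continue; }
    out[t] = vol[lin(i, j, k, nx, ny)];
  }
  return out;
}

// Cubic B-spline kernel (support |t| < 2), the Parzen window used on the
// moving-intensity axis of the Mattes joint histogram.
static inline double bspline3(double t) {
  t = std::fabs(t);
  if (t >= 2.0) return 0.0;
  if (t >= 1.0) { double u = 2.0 - t; return u * u * u / 6.0; }
  return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
}

// Mattes mutual information from paired samples.
// f: fixed-image samples; m: moving-image samples (NA = mapped outside the
// moving grid). Intensities are min-max normalized with the supplied image
// ranges: fixed to zero-order bins [0, nbins-1], moving to a continuous
// position in [1.5, nbins-2.5] so the cubic Parzen support stays in range.
// Returns negative MI in bits, and the number of in-overlap samples.
// [[Rcpp::export]]
List cpp_mattes_mi(NumericVector f, NumericVector m,
                   double fmin, double fmax, double mmin, double mmax,
                   int nbins) {
  const R_xlen_t n = f.size();
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  const double fscale = (fmax > fmin) ? (nbins - 1.0) / (fmax - fmin) : 0.0;
  const double mspan = (mmax > mmin) ? (mmax - mmin) : 1.0;
  R_xlen_t used = 0;
  for (R_xlen_t t = 0; t < n; ++t) {
    if (NumericVector::is_na(m[t])) continue;
    double fb = (f[t] - fmin) * fscale;
    int fi = (int)std::lround(fb);
    if (fi < 0) fi = 0;
    if (fi > nbins - 1) fi = nbins - 1;
    double mb = 1.5 + (m[t] - mmin) / mspan * (nbins - 4.0);
    if (mb < 1.5) mb = 1.5;
    if (mb > nbins - 2.5) mb = nbins - 2.5;
    int m0 = (int)std::floor(mb);
    for (int d = -1; d <= 2; ++d) {
      int mi_ = m0 + d;
      if (mi_ < 0 || mi_ > nbins - 1) continue;
      joint[(size_t)fi + (size_t)nbins * mi_] += bspline3(mb - mi_);
    }
    ++used;
  }
  if (used == 0) return List::create(_["neg_mi"] = NA_REAL, _["n_used"] = 0);
  double total = 0.0;
  for (double v : joint) total += v;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double p = joint[(size_t)a + (size_t)nbins * b] / total;
      pf[a] += p; pm[b] += p;
    }
  double mi = 0.0;
  const double log2_ = std::log(2.0);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double p = joint[(size_t)a + (size_t)nbins * b] / total;
      if (p > 0.0 && pf[a] > 0.0 && pm[b] > 0.0)
        mi += p * std::log(p / (pf[a] * pm[b])) / log2_;
    }
  return List::create(_["neg_mi"] = -mi, _["n_used"] = (double)used);
}

// Project every voxel of a grid onto a centerline polyline with attached
// orthonormal frames. Returns, per voxel: distance to the curve, in-plane
// frame coordinates (u along the normal, v along the binormal), and the
// arc-length parameter s. Voxels farther than maxr from every considered
// sample get dist = Inf. Candidate samples are pruned by axial (z) distance,
// valid for curves whose long axis is z.
// [[Rcpp::export]]
List cpp_project_to_curve(IntegerVector dims, NumericVector spacing,
                          NumericVector origin, NumericMatrix pts,
                          NumericMatrix nrm, NumericMatrix bin,
                          NumericVector arclen, double maxr) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ns = pts.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dist(nvox, R_PosInf), U(nvox, NA_REAL), V(nvox, NA_REAL),
      S(nvox, NA_REAL);
  // median axial step for the pruning slack
  double zmin_c = pts(0, 2), zmax_c = pts(0, 2);
  for (int s = 0; s < ns; ++s) {
    zmin_c = std::min(zmin_c, pts(s, 2));
    zmax_c = std::max(zmax_c, pts(s, 2));
  }
  double slack = maxr + 4.0 * (arclen[ns - 1] / std::max(1, ns - 1));
  for (int k = 0; k < nz; ++k) {
    double wz = origin[2] + k * spacing[2];
    if (wz < zmin_c - slack || wz > zmax_c + slack) continue;
    for (int j = 0; j < ny; ++j) {
      double wy = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i) {
        double wx = origin[0] + i * spacing[0];
        // nearest sample
        int best = -1; double bd2 = maxr * maxr;
        for (int s = 0; s < ns; ++s) {
          double dz = wz - pts(s, 2);
          if (std::fabs(dz) > slack) continue;
          double dx = wx - pts(s, 0), dy = wy - pts(s, 1);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= bd2) { bd2 = d2; best = s; }
        }
        if (best < 0) continue;
        // exact projection onto the two adjacent segments
        double bs = arclen[best];
        double cx = pts(best, 0), cy = pts(best, 1), cz = pts(best, 2);
        int fa = best, fb = best; double ft = 0.0; // frame interp endpoints
        double bestd2 = (wx - cx) * (wx - cx) + (wy - cy) * (wy - cy) +
                        (wz - cz) * (wz - cz);
        for (int seg = -1; seg <= 0; ++seg) {
          int a = best + seg, b = best + seg + 1;
          if (a < 0 || b > ns - 1) continue;
          double ex = pts(b, 0) - pts(a, 0), ey = pts(b, 1) - pts(a, 1),
                 ez = pts(b, 2) - pts(a, 2);
          double L2 = ex * ex + ey * ey + ez * ez;
          if (L2 <= 0.0) continue;
          double tt = ((wx - pts(a, 0)) * ex + (wy - pts(a, 1)) * ey +
                       (wz - pts(a, 2)) * ez) / L2;
          if (tt < 0.0) tt = 0.0;
          if (tt > 1.0) tt = 1.0;
          double qx = pts(a, 0) + tt * ex, qy = pts(a, 1) + tt * ey,
                 qz = pts(a, 2) + tt * ez;
          double d2 = (wx - qx) * (wx - qx) + (wy - qy) * (wy - qy) +
                      (wz - qz) * (wz - qz);
          if (d2 < bestd2 - 1e-12) {
            bestd2 = d2; cx = qx; cy = qy; cz = qz;
            bs = arclen[a] + tt * (arclen[b] - arclen[a]);
            fa = a; fb = b; ft = tt;
          }
        }
        if (bestd2 > maxr * maxr) continue;
        // frame at the projection: linear interpolation, then renormalize
        double nxv = nrm(fa, 0) + ft * (nrm(fb, 0) - nrm(fa, 0));
        double nyv = nrm(fa, 1) + ft * (nrm(fb, 1) - nrm(fa, 1));
        double nzv = nrm(fa, 2) + ft * (nrm(fb, 2) - nrm(fa, 2));
        double bxv = bin(fa, 0) + ft * (bin(fb, 0) - bin(fa, 0));
        double byv = bin(fa, 1) + ft * (bin(fb, 1) - bin(fa, 1));
        double bzv = bin(fa, 2) + ft * (bin(fb, 2) - bin(fa, 2));
        double nl = std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
        double bl = std::sqrt(bxv * bxv + byv * byv + bzv * bzv);
        if (nl > 0) { nxv /= nl; nyv /= nl; nzv /= nl; }
        if (bl > 0) { bxv /= bl; byv /= bl; bzv /= bl; }
        double rx = wx - cx, ry = wy - cy, rz = wz - cz;
        R_xlen_t p = lin(i, j, k, nx, ny);
        dist[p] = std::sqrt(bestd2);
        U[p] = rx * nxv + ry * nyv + rz * nzv;
        V[p] = rx * bxv + ry * byv + rz * bzv;
        S[p] = bs;
      }
    }
  }
  return List::create(_["dist"] = dist, _["u"] = U, _["v"] = V, _["s"] = S);
}
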