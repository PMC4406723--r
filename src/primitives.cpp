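#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---- 6-connected component labelling -------------------------------------

// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
      R_xlen_t nb[6]; int ok[6];
      nb[0] = v - sx; ok[0] = x > 0;
      nb[1] = v + sx; ok[1] = x < nx - 1;
      nb[2] = v - sy; ok[2] = y > 0;
      nb[3] = v + sy; ok[3] = y < ny - 1;
      nb[4] = v - sz; ok[4] = z > 0;
      nb[5] = v + sz; ok[5] = z < nz - 1;
      for (int k = 0; k < 6; ++k) {
        if (ok[k] && mask[nb[k]] && lab[nb[k]] == 0) {
          lab[nb[k]] = cur;
          stack.push_back(nb[k]);
        }
      }
    }
  }
  return lab;
}

// ---- Felzenszwalb squared Euclidean distance transform -------------------

static void dt1d(const double* f, double* d, int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
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
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Squared EDT (mm^2) to the set of TRUE voxels of a 3D mask (use nz = 1 for 2D).
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> g(f.size());
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)y * nx + (R_xlen_t)z * sz;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f.data(), g.data(), nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)z * sz;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)y * nx];
      dt1d(f.data(), g.data(), ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = g[y];
    }
  // z pass
  if (nz > 1)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)x + (R_xlen_t)y * nx;
        for (int z = 0; z < nz; ++z) f[z] = d[base + (R_xlen_t)z * sz];
        dt1d(f.data(), g.data(), nz, spacing[2] * spacing[2]);
        for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * sz] = g[z];
      }
  return d;
}

// ---- affine resampling ----------------------------------------------------

// mat: 3x4 row-major mapping output-voxel world coords -> source world coords.
// Out-of-field samples are NA.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericVector sspacing, NumericVector sorigin,
                                  IntegerVector odim, NumericVector ospacing,
                                  NumericVector oorigin, NumericVector mat,
                                  bool nearest) {
  const int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  const int onx = odim[0], ony = odim[1], onz = odim[2];
  const R_xlen_t ssz = (R_xlen_t)snx * sny;
  NumericVector out((R_xlen_t)onx * ony * onz);
  R_xlen_t idx = 0;
  for (int z = 0; z < onz; ++z) {
    double wz = oorigin[2] + z * ospacing[2];
    for (int y = 0; y < ony; ++y) {
      double wy = oorigin[1] + y * ospacing[1];
      for (int x = 0; x < onx; ++x, ++idx) {
        double wx = oorigin[0] + x * ospacing[0];
        double px = mat[0] * wx + mat[1] * wy + mat[2] * wz + mat[3];
        double py = mat[4] * wx + mat[5] * wy + mat[6] * wz + mat[7];
        double pz = mat[8] * wx + mat[9] * wy + mat[10] * wz + mat[11];
        double cx = (px - sorigin[0]) / sspacing[0];
        double cy = (py - sorigin[1]) / sspacing[1];
        double cz = (pz - sorigin[2]) / sspacing[2];
        if (nearest) {
          int ix = (int)std::lround(cx), iy = (int)std::lround(cy),
              iz = (int)std::lround(cz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= snx || iy >= sny || iz >= snz) {
            out[idx] = NA_REAL;
          } else {
            out[idx] = src[(R_xlen_t)ix + (R_xlen_t)iy * snx + (R_xlen_t)iz * ssz];
          }
        } else {
          if (cx < 0 || cy < 0 || cz < 0 || cx > snx - 1 || cy > sny - 1 ||
              cz > snz - 1) {
            out[idx] = NA_REAL;
            continue;
          }
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
          if (x0 == snx - 1) --x0;
          if (y0 == sny - 1) --y0;
          if (z0 == snz - 1) --z0;
          if (snx == 1) x0 = 0;
          if (sny == 1) y0 = 0;
          if (snz == 1) z0 = 0;
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          int x1 = std::min(x0 + 1, snx - 1), y1 = std::min(y0 + 1, sny - 1),
              z1 = std::min(z0 + 1, snz - 1);
          double v000 = src[(R_xlen_t)x0 + (R_xlen_t)y0 * snx + (R_xlen_t)z0 * ssz];
          double v100 = src[(R_xlen_t)x1 + (R_xlen_t)y0 * snx + (R_xlen_t)z0 * ssz];
          double v010 = src[(R_xlen_t)x0 + (R_xlen_t)y1 * snx + (R_xlen_t)z0 * ssz];
          double v110 = src[(R_xlen_t)x1 + (R_xlen_t)y1 * snx + (R_xlen_t)z0 * ssz];
          double v001 = src[(R_xlen_t)x0 + (R_xlen_t)y0 * snx + (R_xlen_t)z1 * ssz];
          double v101 = src[(R_xlen_t)x1 + (R_xlen_t)y0 * snx + (R_xlen_t)z1 * ssz];
          double v011 = src[(R_xlen_t)x0 + (R_xlen_t)y1 * snx + (R_xlen_t)z1 * ssz];
          double v111 = src[(R_xlen_t)x1 + (R_xlen_t)y1 * snx + (R_xlen_t)z1 * ssz];
          double c00 = v000 * (1 - fx) + v100 * fx;
          double c10 = v010 * (1 - fx) + v110 * fx;
          double c01 = v001 * (1 - fx) + v101 * fx;
          double c11 = v011 * (1 - fx) + v111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[idx] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  return out;
}

// ---- IC(0)-preconditioned conjugate gradients ------------------------------

// K given in CSC (dgCMatrix slots, 0-based, full symmetric pattern).
// Returns list(x, iterations, residual). Incomplete Cholesky with diagonal
// shifting on breakdown; falls back to larger shifts until the
// factorization succeeds.
// [[Rcpp::export(name = ".pcg_ic0")]]
List pcg_ic0(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
             NumericVector b, double tol, int maxit) {
  const int n = b.size();
  const int* ap = INTEGER(Ap);
  const int* ai = INTEGER(Ai);
  const double* ax = REAL(Ax);

  // extract lower-triangular pattern (i >= j) for IC(0)
  std::vector<int> Lp(n + 1, 0), Li;
  std::vector<double> Lx0;
  for (int j = 0; j < n; ++j) {
    for (int k = ap[j]; k < ap[j + 1]; ++k)
      if (ai[k] >= j) ++Lp[j + 1];
  }
  for (int j = 0; j < n; ++j) Lp[j + 1] += Lp[j];
  Li.resize(Lp[n]);
  Lx0.resize(Lp[n]);
  {
    std::vector<int> pos(n);
    for (int j = 0; j < n; ++j) pos[j] = Lp[j];
    for (int j = 0; j < n; ++j)
      for (int k = ap[j]; k < ap[j + 1]; ++k)
        if (ai[k] >= j) { Li[pos[j]] = ai[k]; Lx0[pos[j]] = ax[k]; ++pos[j]; }
  }
  // rows are sorted within columns because dgCMatrix stores sorted indices

  std::vector<double> Lx;
  double shift = 0.0;
  bool ok = false;
  for (int attempt = 0; attempt < 6 && !ok; ++attempt) {
    Lx = Lx0;
    if (shift > 0)
      for (int j = 0; j < n; ++j) Lx[Lp[j]] += shift * Lx0[Lp[j]];
    ok = true;
    // column-wise IC(0): for each column j, d = sqrt(a_jj - sum l_jk^2)
    // using only the retained pattern
    std::vector<std::vector<std::pair<int, double> > > rows(n);
    for (int j = 0; j < n && ok; ++j) {
      double djj = Lx[Lp[j]];
      for (size_t t = 0; t < rows[j].size(); ++t) {
        double l = rows[j][t].second;
        djj -= l * l;
      }
      if (djj <= 0) { ok = false; break; }
      djj = std::sqrt(djj);
      Lx[Lp[j]] = djj;
      for (int k = Lp[j] + 1; k < Lp[j + 1]; ++k) {
        int i = Li[k];
        double v = Lx[k];
        // v -= sum_{m<j, pattern} L(i,m) * L(j,m)
        size_t ta = 0, tb = 0;
        const std::vector<std::pair<int, double> >& ri = rows[i];
        const std::vector<std::pair<int, double> >& rj = rows[j];
        while (ta < ri.size() && tb < rj.size()) {
          if (ri[ta].first < rj[tb].first) ++ta;
          else if (ri[ta].first > rj[tb].first) ++tb;
          else { v -= ri[ta].second * rj[tb].second; ++ta; ++tb; }
        }
        v /= djj;
        Lx[k] = v;
        rows[i].push_back(std::make_pair(j, v));
      }
      rows[j].push_back(std::make_pair(j, djj));
    }
    if (!ok) shift = (shift == 0) ? 1e-3 : shift * 10;
  }

  std::vector<double> x(n, 0.0), r(b.begin(), b.end()), z(n), p(n), Kp(n);
  double nb = 0;
  for (int i = 0; i < n; ++i) nb += b[i] * b[i];
  nb = std::sqrt(nb);
  if (nb == 0)
    return List::create(Named("x") = NumericVector(n),
                        Named("iterations") = 0,
                        Named("residual") = 0.0);
  // diag for Jacobi fallback
  std::vector<double> dinv(n);
  for (int j = 0; j < n; ++j) dinv[j] = 1.0 / Lx0[Lp[j]];

  auto precond = [&](const std::vector<double>& rr, std::vector<double>& zz) {
    if (!ok) {
      for (int i = 0; i < n; ++i) zz[i] = rr[i] * dinv[i];
      return;
    }
    // solve L y = r (forward), then L' z = y (backward)
    static std::vector<double> y;
    y.assign(rr.begin(), rr.end());
    for (int j = 0; j < n; ++j) {
      y[j] /= Lx[Lp[j]];
      double yj = y[j];
      for (int k = Lp[j] + 1; k < Lp[j + 1]; ++k) y[Li[k]] -= Lx[k] * yj;
    }
    zz.assign(y.begin(), y.end());
    for (int j = n - 1; j >= 0; --j) {
      double s = zz[j];
      for (int k = Lp[j] + 1; k < Lp[j + 1]; ++k) s -= Lx[k] * zz[Li[k]];
      zz[j] = s / Lx[Lp[j]];
    }
  };
  auto matvec = [&](const std::vector<double>& v, std::vector<double>& out) {
    std::fill(out.begin(), out.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double vj = v[j];
      for (int k = ap[j]; k < ap[j + 1]; ++k) out[ai[k]] += ax[k] * vj;
    }
  };
  precond(r, z);
  p = z;
  double rz = 0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];
  int it = 0;
  double res = 1.0;
  while (it < maxit) {
    ++it;
    matvec(p, Kp);
    double pKp = 0;
    for (int i = 0; i < n; ++i) pKp += p[i] * Kp[i];
    double alpha = rz / pKp;
    double rn = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Kp[i];
      rn += r[i] * r[i];
    }
    res = std::sqrt(rn) / nb;
    if (res < tol) break;
    precond(r, z);
    double rz2 = 0;
    for (int i = 0; i < n; ++i) rz2 += r[i] * z[i];
    double beta = rz2 / rz;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    rz = rz2;
  }
  // true residual
  matvec(x, Kp);
  double rn = 0;
  for (int i = 0; i < n; ++i) {
    double d = Kp[i] - b[i];
    rn += d * d;
  }
  res = std::sqrt(rn) / nb;
  return List::create(Named("x") = NumericVector(x.begin(), x.end()),
                      Named("iterations") = it,
                      Named("residual") = res);
}

// ---- fused NMI objective --------------------------------------------------

// Warp the moving image onto the fixed grid (trilinear, mat maps fixed world
// -> moving world), bin against precomputed fixed-image bin indices
// (1..bins, 0 = invalid) and return Studholme NMI (H(A)+H(B))/H(A,B) over
// the valid overlap. Returns -1 when the overlap is below min_overlap.
// [[Rcpp::export(name = ".nmi_warped")]]
double nmi_warped(NumericVector src, IntegerVector sdim,
                  NumericVector sspacing, NumericVector sorigin,
                  IntegerVector odim, NumericVector ospacing,
                  NumericVector oorigin, NumericVector mat,
                  IntegerVector fixed_bins, int bins,
                  double lo, double step, int min_overlap, int stride) {
  const int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  const int onx = odim[0], ony = odim[1], onz = odim[2];
  const R_xlen_t ssz = (R_xlen_t)snx * sny;
  std::vector<double> joint((size_t)bins * bins, 0.0);
  const double* S = REAL(src);
  const int* FB = INTEGER(fixed_bins);
  long nok = 0;
  const R_xlen_t sy_o = onx, sz_o = (R_xlen_t)onx * ony;
  for (int z = 0; z < onz; z += stride) {
    double wz = oorigin[2] + z * ospacing[2];
    for (int y = 0; y < ony; y += stride) {
      double wy = oorigin[1] + y * ospacing[1];
      R_xlen_t row = (R_xlen_t)y * sy_o + (R_xlen_t)z * sz_o;
      for (int x = 0; x < onx; x += stride) {
        R_xlen_t idx = row + x;
        int fb = FB[idx];
        if (fb == 0) continue;
        double wx = oorigin[0] + x * ospacing[0];
        double px = mat[0] * wx + mat[1] * wy + mat[2] * wz + mat[3];
        double py = mat[4] * wx + mat[5] * wy + mat[6] * wz + mat[7];
        double pz = mat[8] * wx + mat[9] * wy + mat[10] * wz + mat[11];
        double cx = (px - sorigin[0]) / sspacing[0];
        double cy = (py - sorigin[1]) / sspacing[1];
        double cz = (pz - sorigin[2]) / sspacing[2];
        if (cx < 0 || cy < 0 || cz < 0 || cx > snx - 1 || cy > sny - 1 ||
            cz > snz - 1) continue;
        int x0 = std::min((int)cx, snx - 2); if (snx == 1) x0 = 0;
        int y0 = std::min((int)cy, sny - 2); if (sny == 1) y0 = 0;
        int z0 = std::min((int)cz, snz - 2); if (snz == 1) z0 = 0;
        double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        int x1 = std::min(x0 + 1, snx - 1), y1 = std::min(y0 + 1, sny - 1),
            z1 = std::min(z0 + 1, snz - 1);
        double v000 = S[(R_xlen_t)x0 + (R_xlen_t)y0 * snx + (R_xlen_t)z0 * ssz];
        double v100 = S[(R_xlen_t)x1 + (R_xlen_t)y0 * snx + (R_xlen_t)z0 * ssz];
        double v010 = S[(R_xlen_t)x0 + (R_xlen_t)y1 * snx + (R_xlen_t)z0 * ssz];
        double v110 = S[(R_xlen_t)x1 + (R_xlen_t)y1 * snx + (R_xlen_t)z0 * ssz];
        double v001 = S[(R_xlen_t)x0 + (R_xlen_t)y0 * snx + (R_xlen_t)z1 * ssz];
        double v101 = S[(R_xlen_t)x1 + (R_xlen_t)y0 * snx + (R_xlen_t)z1 * ssz];
        double v011 = S[(R_xlen_t)x0 + (R_xlen_t)y1 * snx + (R_xlen_t)z1 * ssz];
        double v111 = S[(R_xlen_t)x1 + (R_xlen_t)y1 * snx + (R_xlen_t)z1 * ssz];
        double c00 = v000 * (1 - fx) + v100 * fx;
        double c10 = v010 * (1 - fx) + v110 * fx;
        double c01 = v001 * (1 - fx) + v101 * fx;
        double c11 = v011 * (1 - fx) + v111 * fx;
        double val = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                     (c01 * (1 - fy) + c11 * fy) * fz;
        int ab = (int)((val - lo) / step);
        if (ab < 0) ab = 0;
        if (ab >= bins) ab = bins - 1;
        joint[(size_t)ab + (size_t)bins * (fb - 1)] += 1.0;
        ++nok;
      }
    }
  }
  if (nok < min_overlap) return -1.0;
  std::vector<double> ma(bins, 0.0), mb(bins, 0.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      double c = joint[(size_t)i + (size_t)bins * j];
      ma[i] += c; mb[j] += c;
    }
  double ha = 0, hb = 0, hab = 0;
  const double N = (double)nok;
  for (int i = 0; i < bins; ++i) {
    if (ma[i] > 0) { double p = ma[i] / N; ha -= p * std::log(p); }
    if (mb[i] > 0) { double p = mb[i] / N; hb -= p * std::log(p); }
  }
  for (size_t k = 0; k < joint.size(); ++k)
    if (joint[k] > 0) { double p = joint[k] / N; hab -= p * std::log(p); }
  if (hab <= 0) return 2.0;
  return (ha + hb) / hab;
}

// ---- triangle-triangle intersection (Moller interval test) ---------------

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double* a, const double* b, double* c) {
  c[0] = a[0] - b[0]; c[1] = a[1] - b[1]; c[2] = a[2] - b[2];
}

static const double TT_EPS = 1e-10;

// 2D coplanar overlap via separating axis on projected triangles
static bool coplanar_overlap(const double V[3][3], const double U[3][3],
                             const double* n) {
  int i0, i1;
  double an[3] = {std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2])};
  if (an[0] >= an[1] && an[0] >= an[2]) { i0 = 1; i1 = 2; }
  else if (an[1] >= an[2]) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  double a[3][2], b[3][2];
  for (int k = 0; k < 3; ++k) {
    a[k][0] = V[k][i0]; a[k][1] = V[k][i1];
    b[k][0] = U[k][i0]; b[k][1] = U[k][i1];
  }
  // SAT over edges of both triangles; touching (overlap <= eps) not counted
  for (int t = 0; t < 2; ++t) {
    double (*P)[2] = t == 0 ? a : b;
    for (int e = 0; e < 3; ++e) {
      double ex = P[(e + 1) % 3][0] - P[e][0];
      double ey = P[(e + 1) % 3][1] - P[e][1];
      double nx = -ey, ny = ex;
      double amin = 1e300, amax = -1e300, bmin = 1e300, bmax = -1e300;
      for (int k = 0; k < 3; ++k) {
        double pa = nx * a[k][0] + ny * a[k][1];
        double pb = nx * b[k][0] + ny * b[k][1];
        amin = std::min(amin, pa); amax = std::max(amax, pa);
        bmin = std::min(bmin, pb); bmax = std::max(bmax, pb);
      }
      double scale = std::max(amax - amin, bmax - bmin) + TT_EPS;
      if (amax <= bmin + TT_EPS * scale || bmax <= amin + TT_EPS * scale)
        return false;
    }
  }
  return true;
}

static void isect_interval(double vp0, double vp1, double vp2, double d0,
                           double d1, double d2, double* t0, double* t1) {
  // d0*d1 > 0 handled by caller ordering: here d0,d1 same side, d2 other
  *t0 = vp0 + (vp2 - vp0) * d0 / (d0 - d2);
  *t1 = vp1 + (vp2 - vp1) * d1 / (d1 - d2);
}

static bool tri_tri_intersect(const double V[3][3], const double U[3][3]) {
  double e1[3], e2[3], n1[3], n2[3], d[3];
  sub3(V[1], V[0], e1); sub3(V[2], V[0], e2); cross3(e1, e2, n1);
  double d1 = -dot3(n1, V[0]);
  double du[3];
  for (int k = 0; k < 3; ++k) du[k] = dot3(n1, U[k]) + d1;
  double nlen1 = std::sqrt(dot3(n1, n1));
  double eps1 = TT_EPS * nlen1;
  for (int k = 0; k < 3; ++k) if (std::fabs(du[k]) < eps1) du[k] = 0.0;
  if ((du[0] > 0 && du[1] > 0 && du[2] > 0) ||
      (du[0] < 0 && du[1] < 0 && du[2] < 0)) return false;

  sub3(U[1], U[0], e1); sub3(U[2], U[0], e2); cross3(e1, e2, n2);
  double d2c = -dot3(n2, U[0]);
  double dv[3];
  for (int k = 0; k < 3; ++k) dv[k] = dot3(n2, V[k]) + d2c;
  double nlen2 = std::sqrt(dot3(n2, n2));
  double eps2 = TT_EPS * nlen2;
  for (int k = 0; k < 3; ++k) if (std::fabs(dv[k]) < eps2) dv[k] = 0.0;
  if ((dv[0] > 0 && dv[1] > 0 && dv[2] > 0) ||
      (dv[0] < 0 && dv[1] < 0 && dv[2] < 0)) return false;

  if (du[0] == 0 && du[1] == 0 && du[2] == 0)
    return coplanar_overlap(V, U, n1);

  double dir[3];
  cross3(n1, n2, dir);
  // project onto largest component of dir
  int idx = 0;
  double m = std::fabs(dir[0]);
  if (std::fabs(dir[1]) > m) { m = std::fabs(dir[1]); idx = 1; }
  if (std::fabs(dir[2]) > m) { idx = 2; }
  double vp[3], up[3];
  for (int k = 0; k < 3; ++k) { vp[k] = V[k][idx]; up[k] = U[k][idx]; }

  auto order = [](double* dd, double* pp) {
    // permute so that index 2 is alone on its side
    double d0 = dd[0], d1 = dd[1], d2 = dd[2];
    int lone;
    if (d0 * d1 >= 0 && (d0 * d2 < 0 || d1 * d2 < 0 || (d0 == 0 && d1 == 0)))
      lone = 2;
    else if (d0 * d2 >= 0) lone = 1;
    else lone = 0;
    if (lone != 2) {
      std::swap(dd[lone], dd[2]);
      std::swap(pp[lone], pp[2]);
    }
  };
  order(dv, vp);
  order(du, up);
  if (dv[0] - dv[2] == 0 || dv[1] - dv[2] == 0 ||
      du[0] - du[2] == 0 || du[1] - du[2] == 0) {
    // a vertex exactly on the other plane with its partners: treat as touch
    return false;
  }
  double a0, a1, b0, b1;
  isect_interval(vp[0], vp[1], vp[2], dv[0], dv[1], dv[2], &a0, &a1);
  isect_interval(up[0], up[1], up[2], du[0], du[1], du[2], &b0, &b1);
  if (a0 > a1) std::swap(a0, a1);
  if (b0 > b1) std::swap(b0, b1);
  double scale = std::max(a1 - a0, b1 - b0) + TT_EPS;
  return !(a1 <= b0 + TT_EPS * scale || b1 <= a0 + TT_EPS * scale);
}

// verts: N x 3 matrix; tris: M x 3 (1-based); pairs: K x 2 (1-based tri ids).
// Returns logical vector: pair properly intersects.
// [[Rcpp::export(name = ".tri_pairs_intersect")]]
LogicalVector tri_pairs_intersect(NumericMatrix verts, IntegerMatrix tris,
                                  IntegerMatrix pairs) {
  const int K = pairs.nrow();
  LogicalVector out(K);
  for (int k = 0; k < K; ++k) {
    int t1 = pairs(k, 0) - 1, t2 = pairs(k, 1) - 1;
    double V[3][3], U[3][3];
    for (int j = 0; j < 3; ++j) {
      int a = tris(t1, j) - 1, b = tris(t2, j) - 1;
      for (int c = 0; c < 3; ++c) {
        V[j][c] = verts(a, c);
        U[j][c] = verts(b, c);
      }
    }
    out[k] = tri_tri_intersect(V, U);
  }
  return out;
}
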