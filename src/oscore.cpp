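// Compiled kernels for the heavy per-voxel loops: phantom distance fields,
// directional derivatives of orientation scores (trilinear sampling along
// rotated axes with periodic wrap), gauge-frame eigenfitting, explicit
// diffusion stepping, and the tubularity sweep.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Trilinear sample of channel `ch` of a 4D array (nx,ny,nz,nc) at (x,y,z)
// with periodic wrap.  Coordinates are 0-based voxel units.
static inline double tri_periodic(const double* W, int nx, int ny, int nz,
                                  std::size_t choff, double x, double y,
                                  double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = wrap(x0 + 1, nx), y1 = wrap(y0 + 1, ny), z1 = wrap(z0 + 1, nz);
  x0 = wrap(x0, nx); y0 = wrap(y0, ny); z0 = wrap(z0, nz);
  std::size_t sxy = (std::size_t)nx * ny;
  const double* B = W + choff;
  double c00 = B[x0 + nx * y0 + sxy * z0] * (1 - fx) + B[x1 + nx * y0 + sxy * z0] * fx;
  double c10 = B[x0 + nx * y1 + sxy * z0] * (1 - fx) + B[x1 + nx * y1 + sxy * z0] * fx;
  double c01 = B[x0 + nx * y0 + sxy * z1] * (1 - fx) + B[x1 + nx * y0 + sxy * z1] * fx;
  double c11 = B[x0 + nx * y1 + sxy * z1] * (1 - fx) + B[x1 + nx * y1 + sxy * z1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Trilinear sample with zero padding outside the volume (3D, one channel).
static inline double tri_zero(const double* B, int nx, int ny, int nz,
                              double x, double y, double z, bool* outside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    if (outside) *outside = true;
    return 0.0;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  std::size_t sxy = (std::size_t)nx * ny;
  double c00 = B[x0 + nx * y0 + sxy * z0] * (1 - fx) + B[x1 + nx * y0 + sxy * z0] * fx;
  double c10 = B[x0 + nx * y1 + sxy * z0] * (1 - fx) + B[x1 + nx * y1 + sxy * z0] * fx;
  double c01 = B[x0 + nx * y0 + sxy * z1] * (1 - fx) + B[x1 + nx * y0 + sxy * z1] * fx;
  double c11 = B[x0 + nx * y1 + sxy * z1] * (1 - fx) + B[x1 + nx * y1 + sxy * z1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// ---------------------------------------------------------------- phantoms

// Distance from every voxel to a densely sampled centerline, plus the
// radius at the nearest centerline sample.  pts is M x 3 (0-based voxel
// coordinates), sig length M.
// [[Rcpp::export]]
List cpp_nearest_centerline(IntegerVector dims, NumericMatrix pts,
                            NumericVector sig) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  NumericVector dist(nvox), sigma(nvox);
  int M = pts.nrow();
  std::vector<double> px(M), py(M), pz(M);
  for (int m = 0; m < M; ++m) {
    px[m] = pts(m, 0); py[m] = pts(m, 1); pz[m] = pts(m, 2);
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double best = 1e300; int barg = 0;
        for (int m = 0; m < M; ++m) {
          double dx = x - px[m], dy = y - py[m], dz = z - pz[m];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) { best = d2; barg = m; }
        }
        std::size_t id = x + (std::size_t)nx * y + (std::size_t)nx * ny * z;
        dist[id] = std::sqrt(best);
        sigma[id] = sig[barg];
      }
  dist.attr("dim") = dims;
  sigma.attr("dim") = dims;
  return List::create(_["dist"] = dist, _["sigma"] = sigma);
}

// Signed distance to a union of balls: min_i(||x - c_i|| - r_i).
// centers M x 3 (0-based), radii length M.
// [[Rcpp::export]]
NumericVector cpp_ball_union_dist(IntegerVector dims, NumericMatrix centers,
                                  NumericVector radii) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  NumericVector out(nvox);
  int M = centers.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double best = 1e300;
        for (int m = 0; m < M; ++m) {
          double dx = x - centers(m, 0), dy = y - centers(m, 1),
                 dz = z - centers(m, 2);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[m];
          if (d < best) best = d;
        }
        out[x + (std::size_t)nx * y + (std::size_t)nx * ny * z] = best;
      }
  out.attr("dim") = dims;
  return out;
}

// Trilinear samples of a 3D volume at given points (0-based), zero outside.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int M = pts.nrow();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    out[m] = tri_zero(REAL(vol), nx, ny, nz, pts(m, 0), pts(m, 1), pts(m, 2),
                      nullptr);
  }
  return out;
}

// ------------------------------------------------- left-invariant derivatives

// First/second directional derivative of each orientation channel along a
// per-channel constant spatial direction (central differences, step h,
// periodic wrap).  W is (nx,ny,nz,nc); dirs is nc x 3.
// [[Rcpp::export]]
NumericVector cpp_dirderiv_const(NumericVector W, IntegerVector dims4,
                                 NumericMatrix dirs, double h, int order) {
  int nx = dims4[0], ny = dims4[1], nz = dims4[2], nc = dims4[3];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  NumericVector out((std::size_t)nvox * nc);
  const double* Wp = REAL(W);
  for (int c = 0; c < nc; ++c) {
    std::size_t off = nvox * (std::size_t)c;
    double dx = dirs(c, 0) * h, dy = dirs(c, 1) * h, dz = dirs(c, 2) * h;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          std::size_t id = off + x + (std::size_t)nx * y + (std::size_t)nx * ny * z;
          double fp = tri_periodic(Wp, nx, ny, nz, off, x + dx, y + dy, z + dz);
          double fm = tri_periodic(Wp, nx, ny, nz, off, x - dx, y - dy, z - dz);
          if (order == 1) out[id] = (fp - fm) / (2 * h);
          else out[id] = (fp - 2 * Wp[id] + fm) / (h * h);
        }
  }
  out.attr("dim") = dims4;
  return out;
}

// Deterministic orthonormal completion of a unit vector v: e1 proportional
// to v x ez unless degenerate (then ex), e2 = v x e1.
static inline void complete_frame(const double v[3], double e1[3], double e2[3]) {
  double cx = v[1], cy = -v[0], cz = 0.0;  // v x ez
  double n = std::sqrt(cx * cx + cy * cy + cz * cz);
  if (n < 1e-6) { cx = 1; cy = 0; cz = 0; n = 1; }
  e1[0] = cx / n; e1[1] = cy / n; e1[2] = cz / n;
  e2[0] = v[1] * e1[2] - v[2] * e1[1];
  e2[1] = v[2] * e1[0] - v[0] * e1[2];
  e2[2] = v[0] * e1[1] - v[1] * e1[0];
}

// Gauge-frame derivative fields: for each (voxel, channel) computes the
// second derivatives along B1, B2 (spatial plane perpendicular to the
// fitted tangent v), the second derivative along B3 = v, and the first
// derivative along B3 (central differences with trilinear sampling, h = 1,
// periodic).  v* are (nx,ny,nz,nc) component arrays.
// [[Rcpp::export]]
List cpp_gauge_derivs(NumericVector W, IntegerVector dims4,
                      NumericVector vx, NumericVector vy, NumericVector vz) {
  int nx = dims4[0], ny = dims4[1], nz = dims4[2], nc = dims4[3];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  std::size_t ntot = nvox * (std::size_t)nc;
  NumericVector d2perp(ntot), d2b3(ntot), db3(ntot);
  const double* Wp = REAL(W);
  const double* pvx = REAL(vx); const double* pvy = REAL(vy);
  const double* pvz = REAL(vz);
  double h = 1.0;
  for (int c = 0; c < nc; ++c) {
    std::size_t off = nvox * (std::size_t)c;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          std::size_t id = off + x + (std::size_t)nx * y + (std::size_t)nx * ny * z;
          double v[3] = { pvx[id], pvy[id], pvz[id] };
          double e1[3], e2[3];
          complete_frame(v, e1, e2);
          double w0 = Wp[id];
          double fp, fm, acc = 0;
          fp = tri_periodic(Wp, nx, ny, nz, off, x + e1[0], y + e1[1], z + e1[2]);
          fm = tri_periodic(Wp, nx, ny, nz, off, x - e1[0], y - e1[1], z - e1[2]);
          acc += fp - 2 * w0 + fm;
          fp = tri_periodic(Wp, nx, ny, nz, off, x + e2[0], y + e2[1], z + e2[2]);
          fm = tri_periodic(Wp, nx, ny, nz, off, x - e2[0], y - e2[1], z - e2[2]);
          acc += fp - 2 * w0 + fm;
          d2perp[id] = acc / (h * h);
          fp = tri_periodic(Wp, nx, ny, nz, off, x + v[0], y + v[1], z + v[2]);
          fm = tri_periodic(Wp, nx, ny, nz, off, x - v[0], y - v[1], z - v[2]);
          d2b3[id] = (fp - 2 * w0 + fm) / (h * h);
          db3[id] = (fp - fm) / (2 * h);
        }
  }
  d2perp.attr("dim") = dims4; d2b3.attr("dim") = dims4; db3.attr("dim") = dims4;
  return List::create(_["d2perp"] = d2perp, _["d2b3"] = d2b3, _["db3"] = db3);
}

// Smallest-eigenvector of the 3x3 symmetric structure tensor per node by
// Jacobi rotations.  Inputs are the six unique components; outputs the
// eigenvector (sign fixed to a positive dot product with the per-channel
// reference direction, i.e. the orientation n_i), plus the relative
// eigenvalue gap (l_max - l_min)/l_max used for the degeneracy fallback.
// [[Rcpp::export]]
List cpp_smallest_eigvec(NumericVector jxx, NumericVector jxy, NumericVector jxz,
                         NumericVector jyy, NumericVector jyz, NumericVector jzz,
                         IntegerVector dims4, NumericMatrix refdir) {
  int nx = dims4[0], ny = dims4[1], nz = dims4[2], nc = dims4[3];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  std::size_t ntot = nvox * (std::size_t)nc;
  NumericVector vx(ntot), vy(ntot), vz(ntot), gap(ntot);
  for (std::size_t id = 0; id < ntot; ++id) {
    double A[3][3] = { { jxx[id], jxy[id], jxz[id] },
                       { jxy[id], jyy[id], jyz[id] },
                       { jxz[id], jyz[id], jzz[id] } };
    double V[3][3] = { {1,0,0},{0,1,0},{0,0,1} };
    for (int sweep = 0; sweep < 12; ++sweep) {
      double offd = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
      if (offd < 1e-15) break;
      for (int p = 0; p < 2; ++p)
        for (int q = p + 1; q < 3; ++q) {
          if (std::fabs(A[p][q]) < 1e-18) continue;
          double theta = (A[q][q] - A[p][p]) / (2 * A[p][q]);
          double t = (theta >= 0 ? 1.0 : -1.0) /
                     (std::fabs(theta) + std::sqrt(theta * theta + 1));
          double cth = 1.0 / std::sqrt(t * t + 1), sth = t * cth;
          for (int k = 0; k < 3; ++k) {
            double akp = A[k][p], akq = A[k][q];
            A[k][p] = cth * akp - sth * akq;
            A[k][q] = sth * akp + cth * akq;
          }
          for (int k = 0; k < 3; ++k) {
            double apk = A[p][k], aqk = A[q][k];
            A[p][k] = cth * apk - sth * aqk;
            A[q][k] = sth * apk + cth * aqk;
            double vkp = V[k][p], vkq = V[k][q];
            V[k][p] = cth * vkp - sth * vkq;
            V[k][q] = sth * vkp + cth * vkq;
          }
        }
    }
    double ev[3] = { A[0][0], A[1][1], A[2][2] };
    int imin = 0, imax = 0;
    for (int k = 1; k < 3; ++k) {
      if (ev[k] < ev[imin]) imin = k;
      if (ev[k] > ev[imax]) imax = k;
    }
    double lmax = ev[imax], lmin = ev[imin];
    gap[id] = lmax > 1e-300 ? (lmax - lmin) / lmax : 0.0;
    double v[3] = { V[0][imin], V[1][imin], V[2][imin] };
    int c = (int)(id / nvox);
    double dot = v[0] * refdir(c, 0) + v[1] * refdir(c, 1) + v[2] * refdir(c, 2);
    double s = (dot < 0) ? -1.0 : 1.0;
    if (std::fabs(dot) < 1e-12) s = (v[2] != 0 ? (v[2] > 0 ? 1 : -1)
                                               : (v[0] >= 0 ? 1 : -1));
    vx[id] = s * v[0]; vy[id] = s * v[1]; vz[id] = s * v[2];
  }
  vx.attr("dim") = dims4; vy.attr("dim") = dims4; vz.attr("dim") = dims4;
  gap.attr("dim") = dims4;
  return List::create(_["vx"] = vx, _["vy"] = vy, _["vz"] = vz, _["gap"] = gap);
}

// Explicit Euler evolution of the diffusion
//   dW/dt = D11 (B1^2 + B2^2) W + D33 B3^2 W + D44 Lap_S2 W,
// with per-(voxel,channel) tangent fields v (B3) and diffusivities, and the
// angular Laplacian given in CSC form (Lp, Li, Lxv; N_c x N_c).
// [[Rcpp::export]]
NumericVector cpp_evolve(NumericVector W0, IntegerVector dims4,
                         NumericVector vx, NumericVector vy, NumericVector vz,
                         NumericVector D11, NumericVector D33, double D44,
                         IntegerVector Lp, IntegerVector Li, NumericVector Lxv,
                         NumericVector dts) {
  int nx = dims4[0], ny = dims4[1], nz = dims4[2], nc = dims4[3];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  std::size_t ntot = nvox * (std::size_t)nc;
  NumericVector Wa(clone(W0));
  std::vector<double> rhs(ntot);
  const double* pvx = REAL(vx); const double* pvy = REAL(vy);
  const double* pvz = REAL(vz);
  const double* p11 = REAL(D11); const double* p33 = REAL(D33);
  for (int step = 0; step < dts.size(); ++step) {
    double dt = dts[step];
    const double* Wp = REAL(Wa);
    // spatial part: D11 (B1^2+B2^2) + D33 B3^2 is rewritten as
    // m Lap + (D11-m)(B1^2+B2^2) + (D33-m) B3^2 with m = min(D11, D33) --
    // the same operator, but the isotropic share runs on the exact 7-point
    // Laplacian (no interpolation diffusion) and all stencil weights stay
    // nonnegative (max principle for frozen coefficients).
    for (int c = 0; c < nc; ++c) {
      std::size_t off = nvox * (std::size_t)c;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            std::size_t id = off + x + (std::size_t)nx * y + (std::size_t)nx * ny * z;
            double d11 = p11[id], d33 = p33[id];
            double m = d11 < d33 ? d11 : d33;
            double w0 = Wp[id];
            double acc = 0;
            if (m != 0) {
              std::size_t sxy = (std::size_t)nx * ny;
              const double* B = Wp + off;
              double lap =
                B[wrap(x + 1, nx) + nx * y + sxy * z] +
                B[wrap(x - 1, nx) + nx * y + sxy * z] +
                B[x + nx * wrap(y + 1, ny) + sxy * z] +
                B[x + nx * wrap(y - 1, ny) + sxy * z] +
                B[x + nx * y + sxy * wrap(z + 1, nz)] +
                B[x + nx * y + sxy * wrap(z - 1, nz)] - 6 * w0;
              acc += m * lap;
            }
            double v[3] = { pvx[id], pvy[id], pvz[id] };
            double fp, fm;
            if (d11 - m > 1e-12) {
              double e1[3], e2[3];
              complete_frame(v, e1, e2);
              double perp = 0;
              fp = tri_periodic(Wp, nx, ny, nz, off, x + e1[0], y + e1[1], z + e1[2]);
              fm = tri_periodic(Wp, nx, ny, nz, off, x - e1[0], y - e1[1], z - e1[2]);
              perp += fp - 2 * w0 + fm;
              fp = tri_periodic(Wp, nx, ny, nz, off, x + e2[0], y + e2[1], z + e2[2]);
              fm = tri_periodic(Wp, nx, ny, nz, off, x - e2[0], y - e2[1], z - e2[2]);
              perp += fp - 2 * w0 + fm;
              acc += (d11 - m) * perp;
            }
            if (d33 - m > 1e-12) {
              fp = tri_periodic(Wp, nx, ny, nz, off, x + v[0], y + v[1], z + v[2]);
              fm = tri_periodic(Wp, nx, ny, nz, off, x - v[0], y - v[1], z - v[2]);
              acc += (d33 - m) * (fp - 2 * w0 + fm);
            }
            rhs[id] = acc;
          }
    }
    // angular part: for each voxel row, W_ang = Lap * w  (column c of W)
    if (D44 != 0) {
      for (int c = 0; c < nc; ++c) {
        for (int k = Lp[c]; k < Lp[c + 1]; ++k) {
          int r = Li[k];
          double lw = Lxv[k];
          // contribution of channel c to Laplacian at channel r: L[r,c]*W[.,c]
          std::size_t offc = nvox * (std::size_t)c;
          std::size_t offr = nvox * (std::size_t)r;
          for (std::size_t vv = 0; vv < nvox; ++vv) {
            rhs[offr + vv] += D44 * lw * Wp[offc + vv];
          }
        }
      }
    }
    double* Wm = REAL(Wa);
    for (std::size_t id = 0; id < ntot; ++id) Wm[id] += dt * rhs[id];
  }
  Wa.attr("dim") = dims4;
  return Wa;
}

// ------------------------------------------------------------- tubularity

// Tubularity sweep.  ImW: positive-clipped-later imaginary part channels
// (nx,ny,nz,nc).  For orientation i and in-plane angle j the perpendicular
// direction d_ij (ndir = nc * ntheta rows, 3 cols) carries
// orientation-interpolation weights for +d (idxP/wP, 3 per direction) and
// -d (idxN/wN).  radii: nr values.  Ksm: ntheta x ntheta smoothing matrix
// (rows: output angle, cols: input angle, rows sum to 1).  Returns the
// max-over-(i, r) of min-over-theta smoothed edge products, with argmax
// orientation index and radius, and the count of out-of-volume samples.
// [[Rcpp::export]]
List cpp_tubularity(NumericVector ImW, IntegerVector dims4,
                    NumericMatrix dirs, IntegerMatrix idxP, NumericMatrix wP,
                    IntegerMatrix idxN, NumericMatrix wN,
                    NumericVector radii, NumericMatrix Ksm,
                    LogicalVector mask) {
  int nx = dims4[0], ny = dims4[1], nz = dims4[2], nc = dims4[3];
  std::size_t nvox = (std::size_t)nx * ny * nz;
  int ntheta = Ksm.nrow();
  int nr = radii.size();
  NumericVector st(nvox);
  IntegerVector ni(nvox);
  NumericVector rs(nvox);
  for (std::size_t id = 0; id < nvox; ++id) { ni[id] = 1; rs[id] = radii[0]; }
  const double* Wp = REAL(ImW);
  std::vector<double> chP((std::size_t)nvox * ntheta),
      chN((std::size_t)nvox * ntheta);
  std::vector<double> Eprod((std::size_t)nvox * ntheta);
  long long n_outside = 0;
  for (int i = 0; i < nc; ++i) {
    // interpolated (in orientation) edge channels for each theta
    for (int j = 0; j < ntheta; ++j) {
      int d = i * ntheta + j;
      for (std::size_t vv = 0; vv < nvox; ++vv) {
        double aP = 0, aN = 0;
        for (int k = 0; k < 3; ++k) {
          aP += wP(d, k) * Wp[vv + nvox * (std::size_t)idxP(d, k)];
          aN += wN(d, k) * Wp[vv + nvox * (std::size_t)idxN(d, k)];
        }
        chP[vv + nvox * (std::size_t)j] = aP > 0 ? aP : 0;
        chN[vv + nvox * (std::size_t)j] = aN > 0 ? aN : 0;
      }
    }
    for (int ir = 0; ir < nr; ++ir) {
      double r = radii[ir];
      for (int j = 0; j < ntheta; ++j) {
        int d = i * ntheta + j;
        double ox = r * dirs(d, 0), oy = r * dirs(d, 1), oz = r * dirs(d, 2);
        const double* BP = chP.data() + nvox * (std::size_t)j;
        const double* BN = chN.data() + nvox * (std::size_t)j;
        double* E = Eprod.data() + nvox * (std::size_t)j;
        for (int z = 0; z < nz; ++z)
          for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
              std::size_t vv = x + (std::size_t)nx * y + (std::size_t)nx * ny * z;
              if (mask.size() > 1 && !mask[vv]) { E[vv] = 0; continue; }
              bool outP = false, outN = false;
              double eP = tri_zero(BP, nx, ny, nz, x + ox, y + oy, z + oz, &outP);
              double eN = tri_zero(BN, nx, ny, nz, x - ox, y - oy, z - oz, &outN);
              if (outP || outN) ++n_outside;
              E[vv] = (eP > 0 && eN > 0) ? eP * eN : 0.0;
            }
      }
      // V = min over theta of the angularly smoothed edge product
      for (std::size_t vv = 0; vv < nvox; ++vv) {
        if (mask.size() > 1 && !mask[vv]) continue;
        double vmin = 1e300;
        for (int j = 0; j < ntheta; ++j) {
          double acc = 0;
          for (int jj = 0; jj < ntheta; ++jj) {
            acc += Ksm(j, jj) * Eprod[vv + nvox * (std::size_t)jj];
          }
          if (acc < vmin) vmin = acc;
        }
        if (vmin > st[vv]) {
          st[vv] = vmin;
          ni[vv] = i + 1;
          rs[vv] = r;
        }
      }
    }
  }
  IntegerVector d3(3); d3[0] = nx; d3[1] = ny; d3[2] = nz;
  st.attr("dim") = d3; ni.attr("dim") = d3; rs.attr("dim") = d3;
  return List::create(_["s_t"] = st, _["n_index"] = ni, _["r_star"] = rs,
                      _["n_outside"] = n_outside);
}
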