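// Compiled kernels for Fourier-slice extraction/insertion, pose-grid
// likelihood evaluation, rigid resampling and the exact Euclidean
// distance transform. All Fourier arrays use a centred frequency grid:
// 0-based array index i corresponds to frequency k = i - D/2, so the
// zero frequency sits at index D/2 in every dimension. Real-space
// volumes use the same centre convention for rotations.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925287;

// Trilinear sample of a complex volume at continuous centred coords.
// Caller guarantees |x|,|y|,|z| <= D/2 - 2 so all 8 corners are in range.
static inline void csample(const Rcomplex* v, int D, double x, double y, double z,
                           double& re, double& im) {
  const int h = D / 2;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const double gx = 1.0 - fx, gy = 1.0 - fy, gz = 1.0 - fz;
  const int64_t D2 = (int64_t)D * D;
  const int64_t base = (int64_t)(x0 + h) + (int64_t)D * (y0 + h) + D2 * (z0 + h);
  const double w000 = gx * gy * gz, w100 = fx * gy * gz;
  const double w010 = gx * fy * gz, w110 = fx * fy * gz;
  const double w001 = gx * gy * fz, w101 = fx * gy * fz;
  const double w011 = gx * fy * fz, w111 = fx * fy * fz;
  const Rcomplex* p = v + base;
  re = w000 * p[0].r + w100 * p[1].r + w010 * p[D].r + w110 * p[D + 1].r
     + w001 * p[D2].r + w101 * p[D2 + 1].r + w011 * p[D2 + D].r + w111 * p[D2 + D + 1].r;
  im = w000 * p[0].i + w100 * p[1].i + w010 * p[D].i + w110 * p[D + 1].i
     + w001 * p[D2].i + w101 * p[D2 + 1].i + w011 * p[D2 + D].i + w111 * p[D2 + D + 1].i;
}

// Log-likelihood of one subtracted image against projections of one body
// volume over a grid of poses. Poses factorise as nr rotations x nt
// in-plane shifts; returns an nr x nt matrix of
//   -0.5 * sum_k w(k) |S(k) - CTF(k) P_R V(k) e^{-2pi i k.t/D}|^2
// over the Fourier disc of radius rmax, exploiting Hermitian symmetry
// (half-plane pixels counted twice; the DC term is excluded).
// wshell is indexed by integer shell (0..D/2).
// [[Rcpp::export]]
NumericMatrix cpp_pose_loglik(ComplexVector vol, int D,
                              NumericMatrix rotmats, NumericMatrix shifts,
                              ComplexVector simg, NumericVector ctf,
                              NumericVector wshell, int rmax) {
  const int nr = rotmats.nrow(), nt = shifts.nrow(), h = D / 2;
  const Rcomplex* vp = COMPLEX(vol);
  const Rcomplex* sp = COMPLEX(simg);
  const double* cp = REAL(ctf);
  const int nshell = wshell.size();

  std::vector<int> pkx, pky;
  std::vector<double> pw, pc, psr, psi;
  for (int iy = 0; iy < D; ++iy) {
    const int ky = iy - h;
    for (int ix = h; ix < D; ++ix) {
      const int kx = ix - h;
      if (kx == 0 && ky <= 0) continue;          // keep one of each conjugate pair
      const int sh = (int)std::lround(std::sqrt((double)(kx * kx + ky * ky)));
      if (sh > rmax || sh >= nshell) continue;
      const double w = wshell[sh];
      if (w <= 0) continue;
      const int pix = ix + D * iy;
      pkx.push_back(kx); pky.push_back(ky);
      pw.push_back(2.0 * w); pc.push_back(cp[pix]);
      psr.push_back(sp[pix].r); psi.push_back(sp[pix].i);
    }
  }
  const int npix = (int)pkx.size();
  NumericMatrix out(nr, nt);
  if (npix == 0) return out;

  double A = 0.0;
  for (int j = 0; j < npix; ++j)
    A += pw[j] * (psr[j] * psr[j] + psi[j] * psi[j]);

  // phase tables exp(+2 pi i k t / D) per axis
  std::vector<double> exr((size_t)nt * D), exi((size_t)nt * D);
  std::vector<double> eyr((size_t)nt * D), eyi((size_t)nt * D);
  for (int t = 0; t < nt; ++t) {
    const double tx = shifts(t, 0), ty = shifts(t, 1);
    for (int k = -h; k < h; ++k) {
      const double ax = TWOPI * k * tx / D, ay = TWOPI * k * ty / D;
      exr[(size_t)t * D + (k + h)] = std::cos(ax);
      exi[(size_t)t * D + (k + h)] = std::sin(ax);
      eyr[(size_t)t * D + (k + h)] = std::cos(ay);
      eyi[(size_t)t * D + (k + h)] = std::sin(ay);
    }
  }

  std::vector<double> Wr(npix), Wi(npix);
  for (int r = 0; r < nr; ++r) {
    const double r00 = rotmats(r, 0), r10 = rotmats(r, 1), r20 = rotmats(r, 2);
    const double r01 = rotmats(r, 3), r11 = rotmats(r, 4), r21 = rotmats(r, 5);
    const double r02 = rotmats(r, 6), r12 = rotmats(r, 7), r22 = rotmats(r, 8);
    double B = 0.0;
    for (int j = 0; j < npix; ++j) {
      const double kx = pkx[j], ky = pky[j];
      // R^T (kx, ky, 0)
      const double x = r00 * kx + r10 * ky;
      const double y = r01 * kx + r11 * ky;
      const double z = r02 * kx + r12 * ky;
      double vr, vi;
      csample(vp, D, x, y, z, vr, vi);
      const double c = pc[j], w = pw[j];
      B += w * c * c * (vr * vr + vi * vi);
      // W = w * S * conj(c * v)
      Wr[j] = w * c * (psr[j] * vr + psi[j] * vi);
      Wi[j] = w * c * (psi[j] * vr - psr[j] * vi);
    }
    for (int t = 0; t < nt; ++t) {
      const double* txr = &exr[(size_t)t * D]; const double* txi = &exi[(size_t)t * D];
      const double* tyr = &eyr[(size_t)t * D]; const double* tyi = &eyi[(size_t)t * D];
      double cross = 0.0;
      for (int j = 0; j < npix; ++j) {
        const int ax = pkx[j] + h, ay = pky[j] + h;
        const double er = txr[ax] * tyr[ay] - txi[ax] * tyi[ay];
        const double ei = txr[ax] * tyi[ay] + txi[ax] * tyr[ay];
        cross += Wr[j] * er - Wi[j] * ei;
      }
      out(r, t) = -0.5 * (A - 2.0 * cross + B);
    }
  }
  return out;
}

// Central-section slice through a Fourier volume at rotation R, then a
// phase shift corresponding to translating the projection by (tx, ty).
// Pixels outside the disc of radius rmax are zero. The output grid has
// side Dout (the image box); `scale` maps output frequencies onto the
// (possibly zero-padded) volume grid, so scale = Dvol / Dout.
// [[Rcpp::export]]
ComplexMatrix cpp_extract_slice(ComplexVector vol, int Dvol, NumericVector rotmat,
                                double tx, double ty, int rmax,
                                int Dout, double scale) {
  const int D = Dout;
  const int h = D / 2;
  const Rcomplex* vp = COMPLEX(vol);
  ComplexMatrix out(D, D);
  const double r00 = rotmat[0], r10 = rotmat[1], r20 = rotmat[2];
  const double r01 = rotmat[3], r11 = rotmat[4], r21 = rotmat[5];
  const double r02 = rotmat[6], r12 = rotmat[7], r22 = rotmat[8];
  for (int iy = 0; iy < D; ++iy) {
    const int ky = iy - h;
    for (int ix = 0; ix < D; ++ix) {
      const int kx = ix - h;
      const int sh = (int)std::lround(std::sqrt((double)(kx * kx + ky * ky)));
      if (sh > rmax) continue;
      const double x = scale * (r00 * kx + r10 * ky);
      const double y = scale * (r01 * kx + r11 * ky);
      const double z = scale * (r02 * kx + r12 * ky);
      double vr, vi;
      csample(vp, Dvol, x, y, z, vr, vi);
      const double ph = -TWOPI * (kx * tx + ky * ty) / D;
      const double er = std::cos(ph), ei = std::sin(ph);
      Rcomplex o; o.r = vr * er - vi * ei; o.i = vr * ei + vi * er;
      out(ix, iy) = o;
    }
  }
  return out;
}

// Adjoint of slice extraction: spread gamma-weighted image data onto the
// 3D numerator/denominator accumulators (modified in place).
//   num += gamma * w * CTF * S * e^{+2pi i k.t/D}  (trilinearly spread)
//   den += gamma * w * CTF^2                       (same spreading weights)
// [[Rcpp::export]]
void cpp_insert_slice(NumericVector numre, NumericVector numim, NumericVector den,
                      int D, NumericVector rotmat, double tx, double ty,
                      ComplexVector simg, NumericVector ctf, NumericVector wshell,
                      double gamma, int rmax) {
  const int h = D / 2;
  double* nr_ = REAL(numre); double* ni_ = REAL(numim); double* dn_ = REAL(den);
  const Rcomplex* sp = COMPLEX(simg);
  const double* cp = REAL(ctf);
  const int nshell = wshell.size();
  const int64_t D2 = (int64_t)D * D;
  const double r00 = rotmat[0], r10 = rotmat[1], r20 = rotmat[2];
  const double r01 = rotmat[3], r11 = rotmat[4], r21 = rotmat[5];
  const double r02 = rotmat[6], r12 = rotmat[7], r22 = rotmat[8];
  for (int iy = 0; iy < D; ++iy) {
    const int ky = iy - h;
    for (int ix = 0; ix < D; ++ix) {
      const int kx = ix - h;
      const int sh = (int)std::lround(std::sqrt((double)(kx * kx + ky * ky)));
      if (sh > rmax || sh >= nshell) continue;
      const double w = wshell[sh];
      if (w <= 0) continue;
      const int pix = ix + D * iy;
      const double c = cp[pix];
      const double ph = TWOPI * (kx * tx + ky * ty) / D;
      const double er = std::cos(ph), ei = std::sin(ph);
      const double sr = sp[pix].r, si = sp[pix].i;
      const double vr = gamma * w * c * (sr * er - si * ei);
      const double vi = gamma * w * c * (sr * ei + si * er);
      const double dv = gamma * w * c * c;
      const double x = r00 * kx + r10 * ky;
      const double y = r01 * kx + r11 * ky;
      const double z = r02 * kx + r12 * ky;
      const int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
      const double fx = x - x0, fy = y - y0, fz = z - z0;
      const double gx = 1.0 - fx, gy = 1.0 - fy, gz = 1.0 - fz;
      const int64_t base = (int64_t)(x0 + h) + (int64_t)D * (y0 + h) + D2 * (z0 + h);
      const double ww[8] = { gx * gy * gz, fx * gy * gz, gx * fy * gz, fx * fy * gz,
                             gx * gy * fz, fx * gy * fz, gx * fy * fz, fx * fy * fz };
      const int64_t off[8] = { 0, 1, D, D + 1, D2, D2 + 1, D2 + D, D2 + D + 1 };
      for (int q = 0; q < 8; ++q) {
        nr_[base + off[q]] += ww[q] * vr;
        ni_[base + off[q]] += ww[q] * vi;
        dn_[base + off[q]] += ww[q] * dv;
      }
    }
  }
}

// Rigid resampling of a real volume: out(x) = in(R^T (x - c - t) + c),
// i.e. the input rotated by R about centre c then translated by t.
// Trilinear interpolation, zero outside the box.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector vol, int D, NumericVector rotmat,
                                 NumericVector centre, NumericVector shift3) {
  const int h = D / 2;
  const double* vp = REAL(vol);
  NumericVector out((int64_t)D * D * D);
  double* op = REAL(out);
  const int64_t D2 = (int64_t)D * D;
  const double r00 = rotmat[0], r10 = rotmat[1], r20 = rotmat[2];
  const double r01 = rotmat[3], r11 = rotmat[4], r21 = rotmat[5];
  const double r02 = rotmat[6], r12 = rotmat[7], r22 = rotmat[8];
  const double cx = centre[0], cy = centre[1], cz = centre[2];
  const double tx = shift3[0], ty = shift3[1], tz = shift3[2];
  for (int iz = 0; iz < D; ++iz) {
    const double z = iz - h - cz - tz;
    for (int iy = 0; iy < D; ++iy) {
      const double y = iy - h - cy - ty;
      for (int ix = 0; ix < D; ++ix) {
        const double x = ix - h - cx - tx;
        // R^T (x,y,z) + c, back to 0-based indices
        const double sx = r00 * x + r10 * y + r20 * z + cx + h;
        const double sy = r01 * x + r11 * y + r21 * z + cy + h;
        const double sz = r02 * x + r12 * y + r22 * z + cz + h;
        const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= D - 1 || y0 >= D - 1 || z0 >= D - 1)
          continue;
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        const double gx = 1.0 - fx, gy = 1.0 - fy, gz = 1.0 - fz;
        const double* p = vp + (int64_t)x0 + (int64_t)D * y0 + D2 * z0;
        op[(int64_t)ix + (int64_t)D * iy + D2 * iz] =
            gx * gy * gz * p[0] + fx * gy * gz * p[1]
          + gx * fy * gz * p[D] + fx * fy * gz * p[D + 1]
          + gx * gy * fz * p[D2] + fx * gy * fz * p[D2 + 1]
          + gx * fy * fz * p[D2 + D] + fx * fy * fz * p[D2 + D + 1];
      }
    }
  }
  return out;
}

// ---- exact Euclidean distance transform (separable squared-distance) ----

static void dt1d(const double* f, int n, double* d, int* v, double* z) {
  int k = 0;
  v[0] = 0; z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k]))
               / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k]))
          / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxels) from every voxel to the nearest voxel with mask > 0.5.
// [[Rcpp::export]]
NumericVector cpp_edt(NumericVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  std::vector<double> g(n);
  for (int64_t i = 0; i < n; ++i) g[i] = mask[i] > 0.5 ? 0.0 : 1e20;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      double* row = &g[(int64_t)nx * (iy + (int64_t)ny * iz)];
      for (int i = 0; i < nx; ++i) f[i] = row[i];
      dt1d(f.data(), nx, d.data(), v.data(), z.data());
      for (int i = 0; i < nx; ++i) row[i] = d[i];
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int i = 0; i < ny; ++i) f[i] = g[ix + (int64_t)nx * (i + (int64_t)ny * iz)];
      dt1d(f.data(), ny, d.data(), v.data(), z.data());
      for (int i = 0; i < ny; ++i) g[ix + (int64_t)nx * (i + (int64_t)ny * iz)] = d[i];
    }
  // z pass
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int i = 0; i < nz; ++i) f[i] = g[ix + (int64_t)nx * (iy + (int64_t)ny * i)];
      dt1d(f.data(), nz, d.data(), v.data(), z.data());
      for (int i = 0; i < nz; ++i) g[ix + (int64_t)nx * (iy + (int64_t)ny * i)] = d[i];
    }
  NumericVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
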