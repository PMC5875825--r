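#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Normalized mutual information between a fixed image and a moving image
// sampled (trilinear) at affine-mapped fixed-voxel-center positions.
// A is 3x4, mapping fixed-world -> moving-world. fbin holds precomputed
// 0-based histogram bin indices of the fixed image (pose-independent);
// moving intensities are binned equal-width over [mlo,mhi]. maskIdx: 0-based
// linear indices of fixed voxels to use (empty = all). Fixed voxels mapping
// outside the moving field of view are skipped, so the histogram covers the
// overlap only. Returns NMI = 2*I(A;B) / (H_A + H_B) and the overlap count.
// The hot path of the registration optimizer: the mapped continuous moving
// index is advanced incrementally along the fixed i-axis, no divisions.
// [[Rcpp::export]]
List cpp_nmi_affine(IntegerVector fbin, IntegerVector fdims,
                    NumericVector fspacing, NumericVector forigin,
                    NumericVector mvox, IntegerVector mdims,
                    NumericVector mspacing, NumericVector morigin,
                    NumericMatrix A, int nbins,
                    double mlo, double mhi,
                    IntegerVector maskIdx) {
  int fx = fdims[0], fy = fdims[1], fz = fdims[2];
  int mx = mdims[0], my = mdims[1], mz = mdims[2];
  const int* fb = INTEGER(fbin);
  const double* mv = REAL(mvox);
  double imsx = 1.0 / mspacing[0], imsy = 1.0 / mspacing[1], imsz = 1.0 / mspacing[2];
  // continuous moving index = Mcol_i * i + Mcol_j * j + Mcol_k * k + c0
  double Mix = A(0,0) * fspacing[0] * imsx;
  double Miy = A(1,0) * fspacing[0] * imsy;
  double Miz = A(2,0) * fspacing[0] * imsz;
  double Mjx = A(0,1) * fspacing[1] * imsx;
  double Mjy = A(1,1) * fspacing[1] * imsy;
  double Mjz = A(2,1) * fspacing[1] * imsz;
  double Mkx = A(0,2) * fspacing[2] * imsx;
  double Mky = A(1,2) * fspacing[2] * imsy;
  double Mkz = A(2,2) * fspacing[2] * imsz;
  double c0x = (A(0,0) * forigin[0] + A(0,1) * forigin[1] + A(0,2) * forigin[2] + A(0,3) - morigin[0]) * imsx;
  double c0y = (A(1,0) * forigin[0] + A(1,1) * forigin[1] + A(1,2) * forigin[2] + A(1,3) - morigin[1]) * imsy;
  double c0z = (A(2,0) * forigin[0] + A(2,1) * forigin[1] + A(2,2) * forigin[2] + A(2,3) - morigin[2]) * imsz;

  double mscale = nbins / std::max(mhi - mlo, 1e-12);
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  long long n = 0;
  size_t s2 = (size_t)mx, s3 = (size_t)mx * (size_t)my;

  auto accum = [&](double ux, double uy, double uz, int bf) {
    if (ux < 0 || uy < 0 || uz < 0 ||
        ux > mx - 1 || uy > my - 1 || uz > mz - 1) return;
    int i0 = (int)ux; if (i0 == mx - 1) i0--;
    int j0 = (int)uy; if (j0 == my - 1) j0--;
    int k0 = (int)uz; if (k0 == mz - 1) k0--;
    double gx = ux - i0, gy = uy - j0, gz = uz - k0;
    const double* p = mv + (size_t)i0 + s2 * (size_t)j0 + s3 * (size_t)k0;
    double c00 = p[0] + (p[1] - p[0]) * gx;
    double c10 = p[s2] + (p[s2 + 1] - p[s2]) * gx;
    double c01 = p[s3] + (p[s3 + 1] - p[s3]) * gx;
    double c11 = p[s2 + s3] + (p[s2 + s3 + 1] - p[s2 + s3]) * gx;
    double c0 = c00 + (c10 - c00) * gy;
    double c1 = c01 + (c11 - c01) * gy;
    double mval = c0 + (c1 - c0) * gz;
    int bm = (int)((mval - mlo) * mscale);
    if (bm < 0) bm = 0; if (bm >= nbins) bm = nbins - 1;
    joint[(size_t)bf + (size_t)nbins * (size_t)bm] += 1.0;
    ++n;
  };

  if (maskIdx.size() > 0) {
    size_t sxy = (size_t)fx * (size_t)fy;
    for (R_xlen_t t = 0; t < maskIdx.size(); ++t) {
      size_t q = (size_t)maskIdx[t];
      size_t k = q / sxy, r = q - k * sxy;
      size_t j = r / (size_t)fx, i = r - j * (size_t)fx;
      accum(Mix * i + Mjx * j + Mkx * k + c0x,
            Miy * i + Mjy * j + Mky * k + c0y,
            Miz * i + Mjz * j + Mkz * k + c0z, fb[q]);
    }
  } else {
    size_t q = 0;
    for (int k = 0; k < fz; ++k)
      for (int j = 0; j < fy; ++j) {
        double ux = Mjx * j + Mkx * k + c0x;
        double uy = Mjy * j + Mky * k + c0y;
        double uz = Mjz * j + Mkz * k + c0z;
        for (int i = 0; i < fx; ++i, ++q) {
          accum(ux, uy, uz, fb[q]);
          ux += Mix; uy += Miy; uz += Miz;
        }
      }
  }
  if (n < 2) return List::create(_["nmi"] = NA_REAL, _["n_overlap"] = (double)n);

  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  double inv = 1.0 / (double)n;
  double hj = 0.0;
  for (int b = 0; b < nbins; ++b)
    for (int c = 0; c < nbins; ++c) {
      double p = joint[(size_t)b + (size_t)nbins * (size_t)c] * inv;
      if (p > 0) { hj -= p * std::log(p); pf[b] += p; pm[c] += p; }
    }
  double hf = 0.0, hm = 0.0;
  for (int b = 0; b < nbins; ++b) {
    if (pf[b] > 0) hf -= pf[b] * std::log(pf[b]);
    if (pm[b] > 0) hm -= pm[b] * std::log(pm[b]);
  }
  double nmi;
  if (hf <= 0 || hm <= 0) {
    nmi = NA_REAL;  // constant image in overlap: zero entropy, undefined
  } else {
    nmi = 2.0 * (hf + hm - hj) / (hf + hm);
  }
  return List::create(_["nmi"] = nmi, _["n_overlap"] = (double)n,
                      _["h_fixed"] = hf, _["h_moving"] = hm, _["h_joint"] = hj);
}
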