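#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Continuous 0-based index of world coordinate w along one axis.
// Values within 1e-7 voxel of a lattice point are snapped so that
// identity resampling onto the same grid is exactly lossless.
static inline double cont_index(double w, double origin, double spacing) {
  double u = (w - origin) / spacing;
  double r = std::round(u);
  if (std::fabs(u - r) < 1e-7) u = r;
  return u;
}

// Trilinear / nearest sample of vox (dims nx,ny,nz, column-major, x fastest)
// at continuous 0-based index (ux,uy,uz). Returns false when out of the
// voxel-center hull.
static inline bool sample_at(const double* vox, int nx, int ny, int nz,
                             double ux, double uy, double uz,
                             bool nearest, double& out) {
  if (nearest) {
    int i = (int)std::lround(ux), j = (int)std::lround(uy), k = (int)std::lround(uz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    out = vox[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
    return true;
  }
  if (ux < 0 || uy < 0 || uz < 0 || ux > nx - 1 || uy > ny - 1 || uz > nz - 1)
    return false;
  int i0 = (int)std::floor(ux); if (i0 == nx - 1) i0--;
  int j0 = (int)std::floor(uy); if (j0 == ny - 1) j0--;
  int k0 = (int)std::floor(uz); if (k0 == nz - 1) k0--;
  double fx = ux - i0, fy = uy - j0, fz = uz - k0;
  size_t base = (size_t)i0 + (size_t)nx * ((size_t)j0 + (size_t)ny * (size_t)k0);
  size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * (size_t)ny;
  double c000 = vox[base],            c100 = vox[base + sx];
  double c010 = vox[base + sy],       c110 = vox[base + sx + sy];
  double c001 = vox[base + sz],       c101 = vox[base + sx + sz];
  double c011 = vox[base + sy + sz],  c111 = vox[base + sx + sy + sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  out = c0 * (1 - fz) + c1 * fz;
  return true;
}

// [[Rcpp::export]]
List cpp_sample_points(NumericVector vox, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       NumericMatrix pts, bool nearest, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector values(n);
  LogicalVector infield(n);
  const double* v = REAL(vox);
  for (R_xlen_t q = 0; q < n; ++q) {
    double ux = cont_index(pts(q, 0), origin[0], spacing[0]);
    double uy = cont_index(pts(q, 1), origin[1], spacing[1]);
    double uz = cont_index(pts(q, 2), origin[2], spacing[2]);
    double out;
    bool ok = sample_at(v, nx, ny, nz, ux, uy, uz, nearest, out);
    values[q] = ok ? out : fill;
    infield[q] = ok;
  }
  return List::create(_["values"] = values, _["infield"] = infield);
}

// Resample src onto an output lattice. A is a 3x4 affine [R|t] mapping each
// output voxel-center world position into the source image's world frame.
// [[Rcpp::export]]
List cpp_resample_affine(NumericVector src, IntegerVector sdims,
                         NumericVector sspacing, NumericVector sorigin,
                         IntegerVector odims, NumericVector ospacing,
                         NumericVector oorigin, NumericMatrix A,
                         bool nearest, double fill) {
  int nx = sdims[0], ny = sdims[1], nz = sdims[2];
  int ox = odims[0], oy = odims[1], oz = odims[2];
  size_t n = (size_t)ox * (size_t)oy * (size_t)oz;
  NumericVector values((R_xlen_t)n);
  LogicalVector infield((R_xlen_t)n);
  const double* v = REAL(src);
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2), a03 = A(0,3);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2), a13 = A(1,3);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2), a23 = A(2,3);
  size_t q = 0;
  for (int k = 0; k < oz; ++k) {
    double wz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      double wy = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i, ++q) {
        double wx = oorigin[0] + i * ospacing[0];
        double px = a00 * wx + a01 * wy + a02 * wz + a03;
        double py = a10 * wx + a11 * wy + a12 * wz + a13;
        double pz = a20 * wx + a21 * wy + a22 * wz + a23;
        double ux = cont_index(px, sorigin[0], sspacing[0]);
        double uy = cont_index(py, sorigin[1], sspacing[1]);
        double uz = cont_index(pz, sorigin[2], sspacing[2]);
        double out;
        bool ok = sample_at(v, nx, ny, nz, ux, uy, uz, nearest, out);
        values[q] = ok ? out : fill;
        infield[q] = ok;
      }
    }
  }
  return List::create(_["values"] = values, _["infield"] = infield);
}
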