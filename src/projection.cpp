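// Real-space volume projection and central-slice Fourier insertion.
// Conventions: cubic D^3 volume, geometric centre at voxel index D/2
// (0-based), matching the FFT origin used on the R side so that the
// projection operator and the Fourier-slice reconstruction agree.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double trilinear(const double* v, int D, double x, double y,
                               double z) {
  // zero outside the grid
  if (x < 0 || y < 0 || z < 0 || x > D - 1 || y > D - 1 || z > D - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, D - 1), y1 = std::min(y0 + 1, D - 1),
      z1 = std::min(z0 + 1, D - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double* p = v;
  auto at = [&](int i, int j, int k) {
    return p[i + (size_t)D * (j + (size_t)D * k)];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Project a volume along +z after rotating coordinates by t(R):
// I(i,j) = sum_z v( c + R^T (p - relative coords) ), line-integral sum with
// unit step. Output pixel (i,j) is centred on the volume centre.
// [[Rcpp::export(name = ".project_volume_cpp")]]
NumericMatrix project_volume_cpp(NumericVector vol, int D, NumericMatrix R,
                                 int out_size) {
  NumericMatrix img(out_size, out_size);
  const double* v = vol.begin();
  double c = D / 2;          // integer division intended: FFT-style centre
  double co = out_size / 2;
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  for (int j = 0; j < out_size; ++j) {
    double py = j - co;
    for (int i = 0; i < out_size; ++i) {
      double px = i - co;
      double acc = 0.0;
      // base point at z=0 plane relative coord pz = -c
      for (int k = 0; k < D; ++k) {
        double pz = k - c;
        // q = R^T p  (R^T rows are R columns)
        double qx = r00 * px + r10 * py + r20 * pz;
        double qy = r01 * px + r11 * py + r21 * pz;
        double qz = r02 * px + r12 * py + r22 * pz;
        acc += trilinear(v, D, qx + c, qy + c, qz + c);
      }
      img(i, j) = acc;
    }
  }
  return img;
}

// Insert centred 2D DFT slices into a 3D Fourier accumulator with trilinear
// gridding. fstack: P x P x n complex array (origin at index P/2 in both
// dims); rots: 3 x 3 x n rotation matrices. A Fourier sample at in-plane
// frequency (fx, fy) lands at 3D frequency R^T (fx, fy, 0).
// [[Rcpp::export(name = ".insert_slices_cpp")]]
List insert_slices_cpp(ComplexVector fstack, IntegerVector dims,
                       NumericVector rots) {
  int P = dims[0], n = dims[2];
  size_t vox = (size_t)P * P * P;
  arma::cx_vec acc(vox, arma::fill::zeros);
  arma::vec wt(vox, arma::fill::zeros);
  int c = P / 2;
  const Rcomplex* fs = fstack.begin();
  for (int m = 0; m < n; ++m) {
    const double* Rm = rots.begin() + (size_t)9 * m;
    // column-major 3x3: Rm[r + 3*c]
    double r00 = Rm[0], r10 = Rm[1], r20 = Rm[2];
    double r01 = Rm[3], r11 = Rm[4], r21 = Rm[5];
    double r02 = Rm[6], r12 = Rm[7], r22 = Rm[8];
    const Rcomplex* F = fs + (size_t)P * P * m;
    for (int j = 0; j < P; ++j) {
      double fy = j - c;
      for (int i = 0; i < P; ++i) {
        double fx = i - c;
        // g = R^T (fx, fy, 0)
        double gx = r00 * fx + r10 * fy;
        double gy = r01 * fx + r11 * fy;
        double gz = r02 * fx + r12 * fy;
        double X = gx + c, Y = gy + c, Z = gz + c;
        if (X < 0 || Y < 0 || Z < 0 || X > P - 1 || Y > P - 1 || Z > P - 1)
          continue;
        int x0 = (int)std::floor(X), y0 = (int)std::floor(Y),
            z0 = (int)std::floor(Z);
        double fx1 = X - x0, fy1 = Y - y0, fz1 = Z - z0;
        Rcomplex val = F[i + (size_t)P * j];
        std::complex<double> cv(val.r, val.i);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
              if (xx > P - 1 || yy > P - 1 || zz > P - 1) continue;
              double w = (dx ? fx1 : 1 - fx1) * (dy ? fy1 : 1 - fy1) *
                         (dz ? fz1 : 1 - fz1);
              if (w <= 0) continue;
              size_t idx = xx + (size_t)P * (yy + (size_t)P * zz);
              acc(idx) += w * cv;
              wt(idx) += w;
            }
      }
    }
  }
  ComplexVector accR(vox);
  NumericVector wtR(vox);
  for (size_t q = 0; q < vox; ++q) {
    accR[q].r = acc(q).real();
    accR[q].i = acc(q).imag();
    wtR[q] = wt(q);
  }
  accR.attr("dim") = IntegerVector::create(P, P, P);
  wtR.attr("dim") = IntegerVector::create(P, P, P);
  return List::create(_["acc"] = accR, _["wt"] = wtR);
}
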