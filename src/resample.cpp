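// Affine resampling of 3D volumes: nearest-neighbour (order 0), trilinear
// (order 1) and cubic-convolution spline interpolation (order 3, Keys
// kernel a = -1/2, which interpolates the samples exactly).  The mapping A
// is a 3x4 matrix sending 0-based target voxel indices to 0-based source
// voxel coordinates; out-of-field voxels are set to 0.
#include <Rcpp.h>
using namespace Rcpp;

static inline double keys(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t < 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0) return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

// [[Rcpp::export(name = ".affineResample")]]
NumericVector affine_resample(const NumericVector& x, IntegerVector dims,
                              const NumericMatrix& A, IntegerVector odims,
                              int order) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int OX = odims[0], OY = odims[1], OZ = odims[2];
  NumericVector out(static_cast<R_xlen_t>(OX) * OY * OZ);
  const double* xp = x.begin();
  auto at = [&](int i, int j, int l) -> double {
    return xp[i + static_cast<size_t>(X) * (j + static_cast<size_t>(Y) * l)];
  };
  R_xlen_t o = 0;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox, ++o) {
        const double sx = A(0,0)*ox + A(0,1)*oy + A(0,2)*oz + A(0,3);
        const double sy = A(1,0)*ox + A(1,1)*oy + A(1,2)*oz + A(1,3);
        const double sz = A(2,0)*ox + A(2,1)*oy + A(2,2)*oz + A(2,3);
        if (order == 0) {
          const int i = static_cast<int>(std::lround(sx));
          const int j = static_cast<int>(std::lround(sy));
          const int l = static_cast<int>(std::lround(sz));
          out[o] = (i >= 0 && i < X && j >= 0 && j < Y && l >= 0 && l < Z)
            ? at(i, j, l) : 0.0;
        } else if (order == 1) {
          const int i0 = static_cast<int>(std::floor(sx));
          const int j0 = static_cast<int>(std::floor(sy));
          const int l0 = static_cast<int>(std::floor(sz));
          const double fx = sx - i0, fy = sy - j0, fz = sz - l0;
          double acc = 0.0;
          for (int dl = 0; dl <= 1; ++dl)
            for (int dj = 0; dj <= 1; ++dj)
              for (int di = 0; di <= 1; ++di) {
                const int i = i0 + di, j = j0 + dj, l = l0 + dl;
                if (i < 0 || i >= X || j < 0 || j >= Y || l < 0 || l >= Z)
                  continue;
                const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                                 (dl ? fz : 1 - fz);
                acc += w * at(i, j, l);
              }
          out[o] = acc;
        } else {
          const int i0 = static_cast<int>(std::floor(sx));
          const int j0 = static_cast<int>(std::floor(sy));
          const int l0 = static_cast<int>(std::floor(sz));
          double wx[4], wy[4], wz[4];
          for (int d = -1; d <= 2; ++d) {
            wx[d + 1] = keys(sx - (i0 + d));
            wy[d + 1] = keys(sy - (j0 + d));
            wz[d + 1] = keys(sz - (l0 + d));
          }
          double acc = 0.0;
          for (int dl = -1; dl <= 2; ++dl) {
            const int l = l0 + dl;
            if (l < 0 || l >= Z || wz[dl + 1] == 0.0) continue;
            for (int dj = -1; dj <= 2; ++dj) {
              const int j = j0 + dj;
              if (j < 0 || j >= Y || wy[dj + 1] == 0.0) continue;
              const double wyz = wy[dj + 1] * wz[dl + 1];
              for (int di = -1; di <= 2; ++di) {
                const int i = i0 + di;
                if (i < 0 || i >= X) continue;
                acc += wx[di + 1] * wyz * at(i, j, l);
              }
            }
          }
          out[o] = acc;
        }
      }
    }
  }
  return out;
}
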