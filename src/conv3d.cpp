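// 3D convolution primitives for the translation network.
// Layout convention: feature maps are column-major R arrays with dim
// (X, Y, Z, C), spatial fastest, channels last, viewed as N x C matrices
// with N = X*Y*Z.  The unfolded patch matrix M is N_out x (k^3*C) with
// column index (kx + k*(ky + k*kz)) + k^3*c, and weights are (k^3*C) x F
// matrices in the same row ordering, so y = M %*% W + b.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold x into an N_out x (k^3*C) matrix of receptive-field values.
// [[Rcpp::export(name = ".im2col3d")]]
arma::mat im2col3d(const arma::vec& x, IntegerVector dims,
                   int k, int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const size_t Nout = static_cast<size_t>(OX) * OY * OZ;
  const size_t plane = static_cast<size_t>(X) * Y;
  const size_t chan = plane * Z;
  arma::mat M(Nout, static_cast<size_t>(k) * k * k * C, arma::fill::zeros);
  const double* xp = x.memptr();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + chan * c;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          double* mcol = M.colptr(kx + static_cast<size_t>(k) *
                                  (ky + static_cast<size_t>(k) * kz) +
                                  static_cast<size_t>(k) * k * k * c);
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * stride - pad + kz;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= Y) continue;
              // run over ox; source index ix = ox*stride - pad + kx
              int ox0 = 0, ox1 = OX - 1;  // clamp to valid ix range
              while (ox0 <= ox1 && ox0 * stride - pad + kx < 0) ++ox0;
              while (ox1 >= ox0 && ox1 * stride - pad + kx >= X) --ox1;
              if (ox0 > ox1) continue;
              double* dst = mcol + ox0 + static_cast<size_t>(OX) *
                (oy + static_cast<size_t>(OY) * oz);
              const double* src = xc + (ox0 * stride - pad + kx) +
                static_cast<size_t>(X) * iy + plane * iz;
              const int len = ox1 - ox0 + 1;
              if (stride == 1) {
                std::memcpy(dst, src, len * sizeof(double));
              } else {
                for (int i = 0; i < len; ++i) dst[i] = src[i * stride];
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col3d: scatter-add columns back onto the input grid.
// [[Rcpp::export(name = ".col2im3d")]]
arma::vec col2im3d(const arma::mat& M, IntegerVector dims,
                   int k, int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const size_t plane = static_cast<size_t>(X) * Y;
  const size_t chan = plane * Z;
  arma::vec x(chan * C, arma::fill::zeros);
  double* xp = x.memptr();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + chan * c;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const double* mcol = M.colptr(kx + static_cast<size_t>(k) *
                                        (ky + static_cast<size_t>(k) * kz) +
                                        static_cast<size_t>(k) * k * k * c);
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * stride - pad + kz;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= Y) continue;
              int ox0 = 0, ox1 = OX - 1;
              while (ox0 <= ox1 && ox0 * stride - pad + kx < 0) ++ox0;
              while (ox1 >= ox0 && ox1 * stride - pad + kx >= X) --ox1;
              if (ox0 > ox1) continue;
              const double* src = mcol + ox0 + static_cast<size_t>(OX) *
                (oy + static_cast<size_t>(OY) * oz);
              double* dst = xc + (ox0 * stride - pad + kx) +
                static_cast<size_t>(X) * iy + plane * iz;
              const int len = ox1 - ox0 + 1;
              for (int i = 0; i < len; ++i) dst[i * stride] += src[i];
            }
          }
        }
      }
    }
  }
  return x;
}

// y = im2col(x) %*% W + b.
// [[Rcpp::export(name = ".conv3dForward")]]
List conv3d_forward(const arma::vec& x, IntegerVector dims,
                    const arma::mat& W, const arma::vec& b,
                    int k, int stride, int pad) {
  arma::mat M = im2col3d(x, dims, k, stride, pad);
  arma::mat Y = M * W;
  Y.each_row() += b.t();
  IntegerVector odims = IntegerVector::create(
    out_extent(dims[0], k, stride, pad), out_extent(dims[1], k, stride, pad),
    out_extent(dims[2], k, stride, pad), W.n_cols);
  return List::create(_["y"] = NumericVector(Y.begin(), Y.end()),
                      _["dims"] = odims);
}

// Gradients of the convolution given upstream dY (same layout as y). The
// patch matrix is recomputed from the cached input x, which is cheaper
// than round-tripping it through R.
// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3d_backward(const arma::vec& dy, IntegerVector odims,
                     const arma::mat& W, const arma::vec& x,
                     IntegerVector xdims, int k, int stride, int pad,
                     bool need_dx) {
  const int F = odims[3];
  const size_t N = static_cast<size_t>(odims[0]) * odims[1] * odims[2];
  arma::mat dY(const_cast<double*>(dy.memptr()), N, F, false, true);
  arma::mat M = im2col3d(x, xdims, k, stride, pad);
  arma::mat dW = M.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  List out = List::create(_["dW"] = dW, _["db"] = db);
  if (need_dx) {
    arma::mat dcols = dY * W.t();
    out["dx"] = col2im3d(dcols, xdims, k, stride, pad);
  }
  return out;
}
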