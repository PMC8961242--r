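// Separable Gaussian blur and 3D connected-component labelling.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Blur one axis at a time with a truncated (3 sigma) normalized kernel and
// reflected boundaries.
// [[Rcpp::export(name = ".gaussianBlur3d")]]
NumericVector gaussian_blur3d(const NumericVector& x, IntegerVector dims,
                              double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int d = -r; d <= r; ++d) {
    ker[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += ker[d + r];
  }
  for (double& w : ker) w /= s;
  NumericVector a = clone(x), b(x.size());
  const int ext[3] = {X, Y, Z};
  const size_t strd[3] = {1, static_cast<size_t>(X),
                          static_cast<size_t>(X) * Y};
  auto reflect = [](int i, int n) {
    if (n == 1) return 0;
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int ax = 0; ax < 3; ++ax) {
    const int n = ext[ax];
    const size_t st = strd[ax];
    for (int iz = 0; iz < (ax == 2 ? 1 : Z); ++iz) {
      for (int iy = 0; iy < (ax == 1 ? 1 : Y); ++iy) {
        for (int ix = 0; ix < (ax == 0 ? 1 : X); ++ix) {
          const size_t base = ix + static_cast<size_t>(X) *
            (iy + static_cast<size_t>(Y) * iz);
          for (int i = 0; i < n; ++i) {
            double acc = 0.0;
            for (int d = -r; d <= r; ++d)
              acc += ker[d + r] * a[base + st * reflect(i + d, n)];
            b[base + st * i] = acc;
          }
        }
      }
    }
    std::swap(a, b);
  }
  return a;
}

// 26-connected component labelling of a logical/0-1 volume.
// [[Rcpp::export(name = ".labelComponents3d")]]
IntegerVector label_components3d(const LogicalVector& mask,
                                 IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<size_t> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t v = stack.back(); stack.pop_back();
      const int ix = v % X, iy = (v / X) % Y, iz = v / (static_cast<size_t>(X) * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int i = ix + dx, j = iy + dy, l = iz + dz;
            if (i < 0 || i >= X || j < 0 || j >= Y || l < 0 || l >= Z) continue;
            const size_t w = i + static_cast<size_t>(X) *
              (j + static_cast<size_t>(Y) * l);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  lab.attr("n") = next;
  return lab;
}
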