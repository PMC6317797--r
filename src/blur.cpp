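#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur, truncated at 3 sigma, renormalised at the image
// faces (no halo darkening).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int half = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * half + 1);
  for (int t = -half; t <= half; ++t)
    k[t + half] = std::exp(-0.5 * t * t / (sigma * sigma));
  std::vector<double> a(vol.begin(), vol.end()), b(nvox);
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int len = n[ax];
    size_t st = stride[ax];
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj)
        for (int ii = 0; ii < nx; ++ii) {
          int pos = ax == 0 ? ii : (ax == 1 ? jj : kk);
          size_t id = ii + (size_t)nx * (jj + (size_t)ny * kk);
          double acc = 0.0, wsum = 0.0;
          int lo = std::max(-half, -pos), hi = std::min(half, len - 1 - pos);
          for (int t = lo; t <= hi; ++t) {
            acc += k[t + half] * a[(size_t)((long long)id + (long long)t * (long long)st)];
            wsum += k[t + half];
          }
          b[id] = acc / wsum;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
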