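#include <Rcpp.h>
using namespace Rcpp;

// Trilinear basis triplets (voxel row, node column, weight) for a node grid of
// spacing ns (voxels) over an image of the given dimensions. 8 entries per
// voxel; 1-based indices, ready for Matrix::sparseMatrix.
// [[Rcpp::export]]
List cpp_trilinear_basis(IntegerVector dim, IntegerVector n_node, double ns,
                         NumericVector pad) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ax = n_node[0], ay = n_node[1], az = n_node[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector ri(nvox * 8), ci(nvox * 8);
  NumericVector w(nvox * 8);
  size_t e = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = (i + pad[0]) / ns, gy = (j + pad[1]) / ns,
               gz = (k + pad[2]) / ns;
        int cx = std::min((int)std::floor(gx), ax - 2);
        int cy = std::min((int)std::floor(gy), ay - 2);
        int cz = std::min((int)std::floor(gz), az - 2);
        double tx = gx - cx, ty = gy - cy, tz = gz - cz;
        size_t row = i + (size_t)nx * (j + (size_t)ny * k);
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              size_t nidx = (cx + a) + (size_t)ax * ((cy + b) + (size_t)ay * (cz + c));
              ri[e] = (int)row + 1;
              ci[e] = (int)nidx + 1;
              w[e] = (a ? tx : 1 - tx) * (b ? ty : 1 - ty) * (c ? tz : 1 - tz);
              ++e;
            }
      }
  return List::create(_["i"] = ri, _["j"] = ci, _["x"] = w);
}
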