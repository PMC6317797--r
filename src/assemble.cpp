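#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct assembly of the Gauss-Newton normal equations of the linearised
// intensity-matching system. Unknown ordering: 4 blocks of nn values
// (du_x, du_y, du_z, dc). For each voxel the residual model is
//   r(x) ~ sum_nodes phi_n(x) * (g . du_n + dc_n),  g = image gradient.
// Node pairs interacting through a voxel differ by at most one grid step per
// axis, so the Gram blocks have a 27-point stencil: accumulate into a dense
// (node x 27-offset x 10-symmetric-pair) array, then emit triplets.
// Returns list(i, j, x, rhs) with 1-based indices for Matrix::sparseMatrix.
// [[Rcpp::export]]
List cpp_assemble_system(IntegerVector dim, IntegerVector n_node, double ns,
                         NumericVector pad, NumericVector gx, NumericVector gy,
                         NumericVector gz, NumericVector r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ax = n_node[0], ay = n_node[1], az = n_node[2];
  size_t nn = (size_t)ax * ay * az;
  std::vector<double> acc(nn * 27 * 10, 0.0);
  std::vector<double> rhs(4 * nn, 0.0);
  int nid[8], lx[8], ly[8], lz[8];
  double w[8];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t v = i + (size_t)nx * (j + (size_t)ny * k);
        double gxx = (i + pad[0]) / ns, gyy = (j + pad[1]) / ns,
               gzz = (k + pad[2]) / ns;
        int cx = std::min((int)std::floor(gxx), ax - 2);
        int cy = std::min((int)std::floor(gyy), ay - 2);
        int cz = std::min((int)std::floor(gzz), az - 2);
        double tx = gxx - cx, ty = gyy - cy, tz = gzz - cz;
        int e = 0;
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              nid[e] = (cx + a) + ax * ((cy + b) + ay * (cz + c));
              lx[e] = a; ly[e] = b; lz[e] = c;
              w[e] = (a ? tx : 1 - tx) * (b ? ty : 1 - ty) * (c ? tz : 1 - tz);
              ++e;
            }
        double g4[4] = {gx[v], gy[v], gz[v], 1.0};
        double rv = r[v];
        for (int a = 0; a < 8; ++a) {
          double wa = w[a];
          if (wa == 0.0) continue;
          for (int p = 0; p < 4; ++p)
            rhs[(size_t)p * nn + nid[a]] += wa * g4[p] * rv;
          for (int b = 0; b < 8; ++b) {
            double wab = wa * w[b];
            if (wab == 0.0) continue;
            int off = (lx[b] - lx[a] + 1) + 3 * (ly[b] - ly[a] + 1) +
                      9 * (lz[b] - lz[a] + 1);
            double* slot = &acc[((size_t)nid[a] * 27 + off) * 10];
            int s = 0;
            for (int p = 0; p < 4; ++p)
              for (int q = p; q < 4; ++q)
                slot[s++] += wab * g4[p] * g4[q];
          }
        }
      }
  // emit triplets
  std::vector<int> ti, tj;
  std::vector<double> tx_;
  ti.reserve(nn * 27 * 4); tj.reserve(nn * 27 * 4); tx_.reserve(nn * 27 * 4);
  for (size_t na = 0; na < nn; ++na) {
    int ia = na % ax, ja = (na / ax) % ay, ka = na / ((size_t)ax * ay);
    for (int off = 0; off < 27; ++off) {
      int dx = off % 3 - 1, dy = (off / 3) % 3 - 1, dz = off / 9 - 1;
      int ib = ia + dx, jb = ja + dy, kb = ka + dz;
      if (ib < 0 || jb < 0 || kb < 0 || ib >= ax || jb >= ay || kb >= az)
        continue;
      size_t nb = ib + (size_t)ax * (jb + (size_t)ay * kb);
      const double* slot = &acc[(na * 27 + off) * 10];
      int s = 0;
      for (int p = 0; p < 4; ++p)
        for (int q = p; q < 4; ++q) {
          double val = slot[s++];
          if (val == 0.0) continue;
          ti.push_back((int)(p * nn + na) + 1);
          tj.push_back((int)(q * nn + nb) + 1);
          tx_.push_back(val);
          if (p != q) {
            ti.push_back((int)(q * nn + na) + 1);
            tj.push_back((int)(p * nn + nb) + 1);
            tx_.push_back(val);
          }
        }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx_), _["rhs"] = wrap(rhs));
}
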