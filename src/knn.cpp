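#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal 3-d k-d tree for nearest-neighbour distances between point sets
// (the inner loop of the Hausdorff-type metrics).

namespace {

struct KDTree {
  const NumericMatrix& pts;
  std::vector<int> order;        // point indices, partitioned in place
  explicit KDTree(const NumericMatrix& p) : pts(p), order(p.nrow()) {
    for (int i = 0; i < p.nrow(); ++i) order[i] = i;
    build(0, p.nrow(), 0);
  }
  void build(int lo, int hi, int axis) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    std::nth_element(order.begin() + lo, order.begin() + mid, order.begin() + hi,
                     [&](int a, int b) { return pts(a, axis) < pts(b, axis); });
    build(lo, mid, (axis + 1) % 3);
    build(mid + 1, hi, (axis + 1) % 3);
  }
  void query(double x, double y, double z, int lo, int hi, int axis,
             double& best2) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = order[mid];
    double dx = x - pts(p, 0), dy = y - pts(p, 1), dz = z - pts(p, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best2) best2 = d2;
    double q = axis == 0 ? x : (axis == 1 ? y : z);
    double split = pts(p, axis);
    double diff = q - split;
    int naxis = (axis + 1) % 3;
    if (diff < 0) {
      query(x, y, z, lo, mid, naxis, best2);
      if (diff * diff < best2) query(x, y, z, mid + 1, hi, naxis, best2);
    } else {
      query(x, y, z, mid + 1, hi, naxis, best2);
      if (diff * diff < best2) query(x, y, z, lo, mid, naxis, best2);
    }
  }
};

} // namespace

// For each row of A, the Euclidean distance to its nearest neighbour in B.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  KDTree tree(B);
  int n = A.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best2 = R_PosInf;
    tree.query(A(i,0), A(i,1), A(i,2), 0, B.nrow(), 0, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}
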