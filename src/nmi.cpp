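#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double entropy_from_counts(const std::vector<double>& p, double n) {
  double h = 0.0;
  for (double c : p)
    if (c > 0.0) { double q = c / n; h -= q * std::log(q); }
  return h;
}

// Normalised mutual information (Studholme): (H(A)+H(B)) / H(A,B),
// joint histogram with `bins` bins per image over fixed ranges.
// [[Rcpp::export]]
double cpp_nmi(NumericVector a, NumericVector b, int bins,
               double amin, double amax, double bmin, double bmax) {
  int n = a.size();
  double ra = amax - amin, rb = bmax - bmin;
  if (ra <= 0) ra = 1.0;
  if (rb <= 0) rb = 1.0;
  std::vector<double> ha(bins, 0.0), hb(bins, 0.0), hab((size_t)bins * bins, 0.0);
  double cnt = 0.0;
  for (int s = 0; s < n; ++s) {
    int ia = (int)((a[s] - amin) / ra * bins);
    int ib = (int)((b[s] - bmin) / rb * bins);
    if (ia < 0) ia = 0; if (ia >= bins) ia = bins - 1;
    if (ib < 0) ib = 0; if (ib >= bins) ib = bins - 1;
    ha[ia] += 1.0; hb[ib] += 1.0; hab[ia + (size_t)bins * ib] += 1.0;
    cnt += 1.0;
  }
  if (cnt < 2) return 1.0;
  double Ha = entropy_from_counts(ha, cnt);
  double Hb = entropy_from_counts(hb, cnt);
  double Hab = entropy_from_counts(hab, cnt);
  if (Hab <= 0.0) return 2.0;  // both images constant on the overlap
  return (Ha + Hb) / Hab;
}

// NMI between fixed-image samples and a rigidly mapped moving image, evaluated
// at given fixed-lattice voxel indices (0-based rows of `idx`). The moving
// image is sampled trilinearly at A %*% idx + b; samples falling outside the
// moving extent are dropped. Returns c(nmi, overlap_fraction).
// [[Rcpp::export]]
NumericVector cpp_nmi_rigid(NumericVector moving, IntegerVector mdim,
                            NumericVector fixed_vals, NumericMatrix idx,
                            NumericMatrix A, NumericVector b, int bins,
                            double fmin, double fmax, double mmin, double mmax) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int n = idx.nrow();
  const double* v = moving.begin();
  double rf = fmax - fmin, rm = mmax - mmin;
  if (rf <= 0) rf = 1.0;
  if (rm <= 0) rm = 1.0;
  std::vector<double> hf(bins, 0.0), hm(bins, 0.0), hj((size_t)bins * bins, 0.0);
  double cnt = 0.0;
  for (int s = 0; s < n; ++s) {
    double i = idx(s,0), j = idx(s,1), k = idx(s,2);
    double x = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
    double y = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
    double z = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
    if (x < 0 || y < 0 || z < 0 || x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
      continue;
    int ix = std::min((int)std::floor(x), nx - 2);
    int iy = std::min((int)std::floor(y), ny - 2);
    int iz = std::min((int)std::floor(z), nz - 2);
    double tx = x - ix, ty = y - iy, tz = z - iz;
    double mv = 0.0;
    for (int c = 0; c < 2; ++c)
      for (int bb = 0; bb < 2; ++bb)
        for (int a = 0; a < 2; ++a) {
          double w = (a ? tx : 1 - tx) * (bb ? ty : 1 - ty) * (c ? tz : 1 - tz);
          if (w == 0.0) continue;
          mv += w * v[(ix + a) + (size_t)nx * ((iy + bb) + (size_t)ny * (iz + c))];
        }
    int bi = (int)((fixed_vals[s] - fmin) / rf * bins);
    int bj = (int)((mv - mmin) / rm * bins);
    if (bi < 0) bi = 0; if (bi >= bins) bi = bins - 1;
    if (bj < 0) bj = 0; if (bj >= bins) bj = bins - 1;
    hf[bi] += 1.0; hm[bj] += 1.0; hj[bi + (size_t)bins * bj] += 1.0;
    cnt += 1.0;
  }
  NumericVector out(2);
  out[1] = n > 0 ? cnt / n : 0.0;
  if (cnt < 2) { out[0] = 0.0; return out; }
  double Hf = entropy_from_counts(hf, cnt);
  double Hm = entropy_from_counts(hm, cnt);
  double Hj = entropy_from_counts(hj, cnt);
  out[0] = Hj > 0.0 ? (Hf + Hm) / Hj : 2.0;
  return out;
}
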