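#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 6- or 26-connected labelling; returns the mask restricted to its largest
// connected component.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim,
                                    int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<int> label(nvox, 0);
  int next = 0;
  size_t best_size = 0;
  int best_label = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || label[s]) continue;
    ++next;
    size_t sz = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      ++sz;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && manh != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[nb] && !label[nb]) {
              label[nb] = next;
              stack.push_back(nb);
            }
          }
    }
    if (sz > best_size) { best_size = sz; best_label = next; }
  }
  LogicalVector out(nvox);
  for (size_t s = 0; s < nvox; ++s) out[s] = (label[s] == best_label && best_label > 0);
  out.attr("dim") = dim;
  return out;
}

// Count of 6-connected components (for phantom contract checks).
// [[Rcpp::export]]
int cpp_n_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<char> seen(nvox, 0);
  int n = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || seen[s]) continue;
    ++n;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && manh != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[nb] && !seen[nb]) { seen[nb] = 1; stack.push_back(nb); }
          }
    }
  }
  return n;
}

// One erosion pass with a face-adjacent (6) or full (26) structuring element;
// voxels outside the image count as background.
static void erode_once(const std::vector<char>& in, std::vector<char>& out,
                       int nx, int ny, int nz, int connectivity) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + (size_t)nx * (j + (size_t)ny * k);
        char keep = in[id];
        if (keep)
          for (int dk = -1; dk <= 1 && keep; ++dk)
            for (int dj = -1; dj <= 1 && keep; ++dj)
              for (int di = -1; di <= 1 && keep; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (connectivity == 6 && manh != 1) continue;
                int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
                  keep = 0; break;
                }
                if (!in[ii + (size_t)nx * (jj + (size_t)ny * kk)]) { keep = 0; break; }
              }
        out[id] = keep;
      }
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, int radius,
                        int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<char> a(nvox), b(nvox);
  for (size_t s = 0; s < nvox; ++s) a[s] = mask[s] ? 1 : 0;
  for (int r = 0; r < radius; ++r) {
    erode_once(a, b, nx, ny, nz, connectivity);
    std::swap(a, b);
  }
  LogicalVector out(nvox);
  for (size_t s = 0; s < nvox; ++s) out[s] = a[s] != 0;
  out.attr("dim") = dim;
  return out;
}
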