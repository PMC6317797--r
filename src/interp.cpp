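#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays (column-major), dim = (nx, ny, nz).
// All coordinates here are 0-based voxel-centre coordinates ("voxel units").

static inline double sinc(double x) {
  if (std::fabs(x) < 1e-12) return 1.0;
  double px = M_PI * x;
  return std::sin(px) / px;
}

// Lanczos window a = 3
static inline double lanczos3(double x) {
  double ax = std::fabs(x);
  if (ax >= 3.0) return 0.0;
  return sinc(x) * sinc(x / 3.0);
}

static inline double sample_lanczos3(const double* v, int nx, int ny, int nz,
                                     double x, double y, double z) {
  // far outside: nothing to sum
  if (x <= -3.0 || y <= -3.0 || z <= -3.0 ||
      x >= nx + 2.0 || y >= ny + 2.0 || z >= nz + 2.0) return 0.0;
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  double wx[6], wy[6], wz[6];
  double sx = 0.0, sy = 0.0, sz = 0.0;
  for (int t = 0; t < 6; ++t) {
    wx[t] = lanczos3(x - (ix - 2 + t));
    wy[t] = lanczos3(y - (iy - 2 + t));
    wz[t] = lanczos3(z - (iz - 2 + t));
    sx += wx[t]; sy += wy[t]; sz += wz[t];
  }
  // normalise the separable kernel so that constants are reproduced exactly
  // in the interior; out-of-extent taps contribute value 0 but keep their
  // weight in the denominator, so intensities fade to background at edges
  double denom = sx * sy * sz;
  if (std::fabs(denom) < 1e-12) return 0.0;
  double acc = 0.0;
  for (int c = 0; c < 6; ++c) {
    int zz = iz - 2 + c;
    if (zz < 0 || zz >= nz || wz[c] == 0.0) continue;
    double accy = 0.0;
    for (int b = 0; b < 6; ++b) {
      int yy = iy - 2 + b;
      if (yy < 0 || yy >= ny || wy[b] == 0.0) continue;
      double accx = 0.0;
      const double* col = v + (size_t)nx * (yy + (size_t)ny * zz);
      for (int a = 0; a < 6; ++a) {
        int xx = ix - 2 + a;
        if (xx < 0 || xx >= nx) continue;
        accx += wx[a] * col[xx];
      }
      accy += wy[b] * accx;
    }
    acc += wz[c] * accy;
  }
  double out = acc / denom;
  return out < 0.0 ? 0.0 : out;   // clamp interpolation undershoot
}

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z, bool* inside) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
    if (inside) *inside = false;
    return 0.0;
  }
  if (inside) *inside = true;
  int ix = std::min((int)std::floor(x), nx - 2);
  int iy = std::min((int)std::floor(y), ny - 2);
  int iz = std::min((int)std::floor(z), nz - 2);
  if (nx == 1) ix = 0;
  if (ny == 1) iy = 0;
  if (nz == 1) iz = 0;
  double tx = x - ix, ty = y - iy, tz = z - iz;
  double acc = 0.0;
  for (int c = 0; c < 2; ++c) {
    int zz = std::min(iz + c, nz - 1);
    double wz = c ? tz : 1.0 - tz;
    if (wz == 0.0) continue;
    for (int b = 0; b < 2; ++b) {
      int yy = std::min(iy + b, ny - 1);
      double wy = b ? ty : 1.0 - ty;
      if (wy == 0.0) continue;
      for (int a = 0; a < 2; ++a) {
        int xx = std::min(ix + a, nx - 1);
        double wx = a ? tx : 1.0 - tx;
        if (wx == 0.0) continue;
        acc += wx * wy * wz * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_resample_affine_lanczos(NumericVector vol, IntegerVector src_dim,
                                          IntegerVector dst_dim, NumericMatrix A,
                                          NumericVector b) {
  int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  int dx = dst_dim[0], dy = dst_dim[1], dz = dst_dim[2];
  NumericVector out((size_t)dx * dy * dz);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int k = 0; k < dz; ++k)
    for (int j = 0; j < dy; ++j)
      for (int i = 0; i < dx; ++i) {
        double px = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double py = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double pz = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        o[i + (size_t)dx * (j + (size_t)dy * k)] =
          sample_lanczos3(v, sx, sy, sz, px, py, pz);
      }
  out.attr("dim") = dst_dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = sample_trilinear(vol.begin(), nx, ny, nz,
                              pts(r,0), pts(r,1), pts(r,2), nullptr);
  return out;
}

// Warp a volume by a node-grid displacement field:
// warped(p) = vol(p + u(p)), u trilinear between nodes with spacing ns.
// u_node: (nnx*nny*nnz) x 3 matrix, voxel units.
// [[Rcpp::export]]
NumericVector cpp_warp_by_node_field(NumericVector vol, IntegerVector dim,
                                     NumericMatrix u_node, IntegerVector n_node,
                                     double ns, NumericVector pad, bool lanczos) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ax = n_node[0], ay = n_node[1], az = n_node[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = (i + pad[0]) / ns, gy = (j + pad[1]) / ns,
               gz = (k + pad[2]) / ns;
        int cx = std::min((int)std::floor(gx), ax - 2);
        int cy = std::min((int)std::floor(gy), ay - 2);
        int cz = std::min((int)std::floor(gz), az - 2);
        double tx = gx - cx, ty = gy - cy, tz = gz - cz;
        double ux = 0.0, uy = 0.0, uz = 0.0;
        for (int c = 0; c < 2; ++c)
          for (int bb = 0; bb < 2; ++bb)
            for (int a = 0; a < 2; ++a) {
              double w = (a ? tx : 1 - tx) * (bb ? ty : 1 - ty) * (c ? tz : 1 - tz);
              if (w == 0.0) continue;
              size_t nidx = (cx + a) + (size_t)ax * ((cy + bb) + (size_t)ay * (cz + c));
              ux += w * u_node(nidx, 0);
              uy += w * u_node(nidx, 1);
              uz += w * u_node(nidx, 2);
            }
        double val = lanczos
          ? sample_lanczos3(v, nx, ny, nz, i + ux, j + uy, k + uz)
          : sample_trilinear(v, nx, ny, nz, i + ux, j + uy, k + uz, nullptr);
        out[i + (size_t)nx * (j + (size_t)ny * k)] = val;
      }
  out.attr("dim") = dim;
  return out;
}

// Dense per-voxel field from node values (trilinear), voxel units in and out.
// [[Rcpp::export]]
NumericMatrix cpp_dense_field_from_nodes(NumericMatrix u_node, IntegerVector n_node,
                                         double ns, NumericVector pad,
                                         IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ax = n_node[0], ay = n_node[1], az = n_node[2];
  int ncomp = u_node.ncol();
  NumericMatrix out((size_t)nx * ny * nz, ncomp);
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
          for (int bb = 0; bb < 2; ++bb)
            for (int a = 0; a < 2; ++a) {
              double w = (a ? tx : 1 - tx) * (bb ? ty : 1 - ty) * (c ? tz : 1 - tz);
              if (w == 0.0) continue;
              size_t nidx = (cx + a) + (size_t)ax * ((cy + bb) + (size_t)ay * (cz + c));
              for (int m = 0; m < ncomp; ++m)
                out(row, m) += w * u_node(nidx, m);
            }
      }
  return out;
}

// Generate a late image from an early image and a FORWARD dense field f
// (early -> late, voxel units, sampled on the early lattice):
// late(y) = early(x) where x solves x + f(x) = y (fixed-point iteration).
// [[Rcpp::export]]
NumericVector cpp_warp_inverse_fixedpoint(NumericVector vol, IntegerVector dim,
                                          NumericMatrix f, int n_iter) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vol.begin();
  size_t nvox = (size_t)nx * ny * nz;
  // component views of the dense field
  const double* fx = &f(0, 0);
  const double* fy = &f(0, 1);
  const double* fz = &f(0, 2);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double x = i, y = j, z = k;
        for (int it = 0; it < n_iter; ++it) {
          double ux = sample_trilinear(fx, nx, ny, nz, x, y, z, nullptr);
          double uy = sample_trilinear(fy, nx, ny, nz, x, y, z, nullptr);
          double uz = sample_trilinear(fz, nx, ny, nz, x, y, z, nullptr);
          x = i - ux; y = j - uy; z = k - uz;
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] =
          sample_lanczos3(v, nx, ny, nz, x, y, z);
      }
  (void)nvox;
  out.attr("dim") = dim;
  return out;
}

// Central-difference gradient (one-sided at faces), voxel units.
// [[Rcpp::export]]
List cpp_gradient(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector gx(nvox), gy(nvox), gz(nvox);
  const double* v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + (size_t)nx * (j + (size_t)ny * k);
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        gx[id] = (v[ip + (size_t)nx*(j + (size_t)ny*k)] - v[im + (size_t)nx*(j + (size_t)ny*k)]) / (ip - im);
        gy[id] = (v[i + (size_t)nx*(jp + (size_t)ny*k)] - v[i + (size_t)nx*(jm + (size_t)ny*k)]) / (jp - jm);
        gz[id] = (v[i + (size_t)nx*(j + (size_t)ny*kp)] - v[i + (size_t)nx*(j + (size_t)ny*km)]) / (kp - km);
      }
  gx.attr("dim") = dim; gy.attr("dim") = dim; gz.attr("dim") = dim;
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Lanczos-3 sampling at arbitrary voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_sample_lanczos(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = sample_lanczos3(vol.begin(), nx, ny, nz,
                             pts(r,0), pts(r,1), pts(r,2));
  return out;
}
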