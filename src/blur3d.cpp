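#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// reflect (scipy "reflect": d c b a | a b c d) index into [0, n)
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable 3D Gaussian convolution on an array stored with dim (nz, ny, nx)
// (first index fastest, R column-major). Kernel std sigma (voxels) on every
// axis, normalized sampled Gaussian truncated at radius floor(4*sigma + 0.5),
// reflect boundary handling.
// [[Rcpp::export(name = ".blur3d_cpp")]]
NumericVector blur3d_cpp(NumericVector x, double sigma) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  if (sigma < 0) stop("sigma must be non-negative");
  const int nz = dims[0], ny = dims[1], nx = dims[2];

  NumericVector out = clone(x);
  if (sigma == 0) return out;

  int r = (int)std::floor(4.0 * sigma + 0.5);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    ksum += k[i + r];
  }
  for (double &v : k) v /= ksum;

  std::vector<double> buf;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> tmp(n);

  // pass along z (stride 1)
  buf.resize(nz);
  for (int xi = 0; xi < nx; ++xi) {
    for (int yi = 0; yi < ny; ++yi) {
      const R_xlen_t base = ((R_xlen_t)xi * ny + yi) * nz;
      for (int zi = 0; zi < nz; ++zi) buf[zi] = out[base + zi];
      for (int zi = 0; zi < nz; ++zi) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j)
          acc += k[j + r] * buf[reflect_index(zi + j, nz)];
        tmp[base + zi] = acc;
      }
    }
  }
  // pass along y (stride nz)
  buf.resize(ny);
  for (int xi = 0; xi < nx; ++xi) {
    for (int zi = 0; zi < nz; ++zi) {
      const R_xlen_t base = (R_xlen_t)xi * ny * nz + zi;
      for (int yi = 0; yi < ny; ++yi) buf[yi] = tmp[base + (R_xlen_t)yi * nz];
      for (int yi = 0; yi < ny; ++yi) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j)
          acc += k[j + r] * buf[reflect_index(yi + j, ny)];
        out[base + (R_xlen_t)yi * nz] = acc;
      }
    }
  }
  // pass along x (stride nz*ny)
  buf.resize(nx);
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int yi = 0; yi < ny; ++yi) {
    for (int zi = 0; zi < nz; ++zi) {
      const R_xlen_t base = (R_xlen_t)yi * nz + zi;
      for (int xi = 0; xi < nx; ++xi) buf[xi] = out[base + (R_xlen_t)xi * sx];
      for (int xi = 0; xi < nx; ++xi) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j)
          acc += k[j + r] * buf[reflect_index(xi + j, nx)];
        tmp[base + (R_xlen_t)xi * sx] = acc;
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = tmp[i];
  out.attr("dim") = dims;
  return out;
}
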