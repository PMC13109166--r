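#include <Rcpp.h>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

// 3D connected-component labeling of a boolean mask stored with dim
// (nz, ny, nx), connectivity 6 (faces), 18 (faces+edges) or 26 (full cube).
// Labels are assigned in raster-scan order of each component's first voxel,
// so the labeling is deterministic. Background is 0.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        int nn = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nb = (int)dz.size();

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      const int zi = (int)(v % nz);
      const int yi = (int)((v / nz) % ny);
      const int xi = (int)(v / ((R_xlen_t)nz * ny));
      for (int j = 0; j < nb; ++j) {
        const int z2 = zi + dz[j], y2 = yi + dy[j], x2 = xi + dx[j];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        const R_xlen_t w = ((R_xlen_t)x2 * ny + y2) * nz + z2;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_objects") = current;
  return labels;
}
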