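#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flood-fill connected-component labeling for 2D/3D logical arrays.
// Labels are assigned in raster-scan order of the first voxel encountered,
// so the labeling is deterministic for a given mask.

static void build_offsets(const IntegerVector& dim, int connectivity,
                          std::vector<std::array<int, 3>>& offs) {
  bool is3d = dim.size() == 3;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (!is3d && dz != 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        bool keep;
        if (!is3d) {
          keep = (connectivity == 8) || manhattan == 1;
        } else {
          keep = (connectivity == 26) || manhattan == 1;
        }
        if (keep) offs.push_back({dz, dy, dx});
      }
    }
  }
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  int ndim = dim.size();
  if (ndim != 2 && ndim != 3) stop("mask must be 2D or 3D");
  int nz = dim[0];
  int ny = ndim == 3 ? dim[1] : dim[0];
  int nx = ndim == 3 ? dim[2] : dim[1];
  if (ndim == 2) { ny = dim[0]; nx = dim[1]; nz = 1; }

  std::vector<std::array<int, 3>> offs;
  build_offsets(dim, connectivity, offs);

  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  // linear index: for 3D arrays dim = (nz, ny, nx): i = z + y*nz + x*nz*ny
  // for 2D: i = y + x*ny (treat z axis as singleton, dim0 = rows)
  R_xlen_t stride_y = (ndim == 3) ? nz : 1;
  R_xlen_t stride_x = (ndim == 3) ? (R_xlen_t)nz * ny : ny;
  R_xlen_t stride_z = (ndim == 3) ? 1 : 0;
  int d0 = (ndim == 3) ? nz : 1;  // extent of the first stored axis (z for 3D)

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z, y, x;
      if (ndim == 3) {
        z = cur % nz;
        y = (cur / nz) % ny;
        x = cur / ((R_xlen_t)nz * ny);
      } else {
        z = 0;
        y = cur % ny;
        x = cur / ny;
      }
      for (const auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (ndim == 3 && (zz < 0 || zz >= nz)) continue;
        R_xlen_t j = (R_xlen_t)zz * stride_z + (R_xlen_t)yy * stride_y +
                     (R_xlen_t)xx * stride_x;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  (void)d0;
  labels.attr("dim") = dim;
  return labels;
}
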