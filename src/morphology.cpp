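#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Neighbour offsets for a 3D grid. connectivity is 6 (faces) or 26 (faces,
// edges, corners).
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (s == 0) continue;
        if (connectivity == 6 && s != 1) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// Label connected components of a 3D logical mask (column-major, dims d1,d2,d3).
// Returns an integer vector: 0 outside the mask, 1..k component labels.
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity = 26) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int i1 = cur % d1;
      int i2 = (cur / d1) % d2;
      int i3 = cur / ((R_xlen_t)d1 * d2);
      for (const auto &o : off) {
        int j1 = i1 + o[0], j2 = i2 + o[1], j3 = i3 + o[2];
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
          continue;
        R_xlen_t j = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          q.push(j);
        }
      }
    }
  }
  return labels;
}

// Separable box dilation along one axis with the given radius (voxels).
static void dilate_axis(std::vector<char> &m, int d1, int d2, int d3, int axis,
                        int radius) {
  if (radius <= 0) return;
  std::vector<char> out(m.size(), 0);
  int dim[3] = {d1, d2, d3};
  R_xlen_t stride[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
  int len = dim[axis];
  // iterate over all lines along `axis`
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int a = 0; a < dim[oa]; ++a)
    for (int b = 0; b < dim[ob]; ++b) {
      R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int i = 0; i < len; ++i) {
        if (!m[base + (R_xlen_t)i * stride[axis]]) continue;
        int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
        for (int j = lo; j <= hi; ++j)
          out[base + (R_xlen_t)j * stride[axis]] = 1;
      }
    }
  m.swap(out);
}

// Box dilation of a 3D logical mask; radius is per-axis in voxels.
// [[Rcpp::export]]
LogicalVector box_dilate_3d(LogicalVector mask, IntegerVector dims,
                            IntegerVector radius) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  for (int ax = 0; ax < 3; ++ax) dilate_axis(m, d1, d2, d3, ax, radius[ax]);
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}
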