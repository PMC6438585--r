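#include <Rcpp.h>
using namespace Rcpp;

// 26-connected component labeling on a 3D integer grid (column-major, as R
// stores arrays). Cells with value <= 0 are background. When same_value_only
// is true, two adjacent cells connect only if they hold the same value, which
// turns the labeling into gray-level zone extraction.
// [[Rcpp::export(name = ".label26")]]
IntegerVector label26(IntegerVector cells, IntegerVector dims, bool same_value_only) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (cells.size() != n) stop("cells length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (cells[start] <= 0 || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int idx = stack.back();
      stack.pop_back();
      int z = idx / (nx * ny);
      int r = idx % (nx * ny);
      int y = r / nx;
      int x = r % nx;
      int v = cells[idx];
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            int j = xx + nx * (yy + ny * zz);
            if (labels[j] != 0 || cells[j] <= 0) continue;
            if (same_value_only && cells[j] != v) continue;
            labels[j] = next;
            stack.push_back(j);
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
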