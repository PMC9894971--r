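#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of the voxels of `grid` equal to `target`.
// Returns an integer array of the same length: 0 off-target, 1..K per
// component, components numbered in scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector grid, IntegerVector dims, int target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (grid[s] != target || comp[s] != 0) continue;
    ++next;
    comp[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (grid[w] == target && comp[w] == 0) {
              comp[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  comp.attr("n_components") = next;
  return comp;
}
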