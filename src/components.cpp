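#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3-D logical array by breadth-first
// search. Labels are arbitrary positive integers (renumbered in R).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              queue.push_back(q);
            }
          }
        }
      }
    }
  }
  return lab;
}
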