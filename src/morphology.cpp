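#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected BFS flood fill on a 3D logical array.
// [[Rcpp::export]]
LogicalVector cpp_flood(LogicalVector mask, IntegerVector dims,
                        IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t i = 0; i < seeds.size(); ++i) {
    R_xlen_t s = seeds[i] - 1;  // 1-based from R
    if (s >= 0 && s < n && mask[s] && !out[s]) {
      out[s] = true;
      stack.push_back(s);
    }
  }
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + nx * (yy + (R_xlen_t)ny * zz);
      if (mask[w] && !out[w]) {
        out[w] = true;
        stack.push_back(w);
      }
    }
  }
  return out;
}

// Label 6-connected components; returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
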