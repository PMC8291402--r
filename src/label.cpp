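#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a binary volume (BFS). Labels 1..K,
// background 0.
// [[Rcpp::export(name = ".label26")]]
IntegerVector label26(IntegerVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = dim;
  std::vector<long> stack;
  int next = 0;
  for (long i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      long c = stack.back(); stack.pop_back();
      int z = (int)(c % nz), y = (int)((c / nz) % ny), x = (int)(c / ((long)nz * ny));
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            long j = zz + (long)yy * nz + (long)xx * nz * ny;
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  return lab;
}
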