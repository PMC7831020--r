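#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3-D connected-component labeling of a binary volume by breadth-first
// search. Connectivity 6 = face neighbors, 18 = face + edge, 26 = face +
// edge + corner ("bwlabeln"-style). Components are numbered 1..K in
// column-major scan order of their first voxel.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets for the requested connectivity
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nonzero = std::abs(a) + std::abs(b) + std::abs(c);
        if (nonzero == 0) continue;
        if (connectivity == 6 && nonzero > 1) continue;
        if (connectivity == 18 && nonzero > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const size_t noff = dx.size();

  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;
  int next_label = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (mask[idx] == 0 || labels[idx] != 0) continue;
    ++next_label;
    labels[idx] = next_label;
    q.push(idx);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = cur % nx;
      int y = (cur / nx) % ny;
      int z = cur / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < noff; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] != 0 && labels[nb] == 0) {
          labels[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
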