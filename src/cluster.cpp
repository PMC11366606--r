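// Euclidean (fixed-radius connected component) clustering with a uniform grid
// hash: two points share a cluster iff they are linked by a chain of hops each
// no longer than eps. Exact distances are checked inside the 27-cell stencil.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {
inline int64_t pack_key(int ix, int iy, int iz) {
  // cell indices are offset to be non-negative and bounded by ~2^20
  return ((int64_t)ix << 42) | ((int64_t)iy << 21) | (int64_t)iz;
}
}

// [[Rcpp::export(name = ".cpp_euclidean_cluster")]]
IntegerVector cpp_euclidean_cluster(NumericMatrix pts, double eps, int min_size) {
  int n = pts.nrow();
  IntegerVector labels(n, NA_INTEGER);
  if (n == 0) return labels;
  if (eps <= 0) stop("eps must be > 0");
  double minc[3];
  for (int a = 0; a < 3; ++a) {
    minc[a] = pts(0, a);
    for (int i = 1; i < n; ++i) minc[a] = std::min(minc[a], pts(i, a));
  }
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor((pts(i, 0) - minc[0]) / eps);
    cy[i] = (int)std::floor((pts(i, 1) - minc[1]) / eps);
    cz[i] = (int)std::floor((pts(i, 2) - minc[2]) / eps);
    grid[pack_key(cx[i], cy[i], cz[i])].push_back(i);
  }
  double eps2 = eps * eps;
  std::vector<int> comp(n, -1);
  std::vector<int> stack;
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    comp[s] = ncomp;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
                grid.find(pack_key(cx[i] + dx, cy[i] + dy, cz[i] + dz));
            if (it == grid.end()) continue;
            const std::vector<int>& cell = it->second;
            for (size_t j = 0; j < cell.size(); ++j) {
              int q = cell[j];
              if (comp[q] >= 0) continue;
              double ddx = pts(q, 0) - xi, ddy = pts(q, 1) - yi, ddz = pts(q, 2) - zi;
              if (ddx * ddx + ddy * ddy + ddz * ddz <= eps2) {
                comp[q] = ncomp;
                stack.push_back(q);
              }
            }
          }
    }
    ++ncomp;
  }
  // relabel: clusters of size >= min_size get 1..K in order of first appearance
  std::vector<int> size(ncomp, 0);
  for (int i = 0; i < n; ++i) ++size[comp[i]];
  std::vector<int> newlab(ncomp, -1);
  int K = 0;
  for (int i = 0; i < n; ++i) {
    int c = comp[i];
    if (size[c] >= min_size && newlab[c] == -1) newlab[c] = ++K;
  }
  for (int i = 0; i < n; ++i) {
    int c = comp[i];
    labels[i] = size[c] >= min_size ? newlab[c] : -1;
  }
  return labels;
}
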