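#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// 3D connected-component labeling by union-find. `mask` is a flattened
// logical array with dims (nz, ny, nx) in R's column-major order, i.e.
// linear index = z + nz*(y + ny*x). Connectivity 6 (faces), 18 (+edges) or
// 26 (+corners). Returns provisional labels (positive, not necessarily
// consecutive or size-ordered); relabeling happens in R.

static int findRoot(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = findRoot(parent, a), rb = findRoot(parent, b);
  if (ra != rb) parent[ra < rb ? rb : ra] = ra < rb ? ra : rb;
}

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  std::vector<int> parent(n);
  // neighbor offsets with strictly negative lexicographic order (scan once)
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && l1 > 1) continue;
        if (connectivity == 18 && l1 > 2) continue;
        // keep only the "earlier" half of the neighborhood
        if (dx > 0) continue;
        if (dx == 0 && dy > 0) continue;
        if (dx == 0 && dy == 0 && dz > 0) continue;
        offs.push_back({dz, dy, dx});
      }
  for (long i = 0; i < n; ++i) parent[i] = (int)i;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = z + (long)nz * (y + (long)ny * x);
        if (!mask[i]) continue;
        for (auto &o : offs) {
          int z2 = z + o[0], y2 = y + o[1], x2 = x + o[2];
          if (z2 < 0 || y2 < 0 || x2 < 0 || z2 >= nz || y2 >= ny || x2 >= nx)
            continue;
          long j = z2 + (long)nz * (y2 + (long)ny * x2);
          if (mask[j]) unite(parent, (int)i, (int)j);
        }
      }
  IntegerVector out(n, 0);
  for (long i = 0; i < n; ++i)
    if (mask[i]) out[i] = findRoot(parent, (int)i) + 1;
  return out;
}
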