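#include <Rcpp.h>
#include <vector>
#include <array>
#include <set>
#include <utility>
#include <cstdlib>
using namespace Rcpp;

// Flood-fill labelling of connected components in a 3D logical grid.
// `mask` is the flattened array (x fastest, then y, then z, R order),
// `dims` its extents, `connectivity` one of 6, 18, 26.
// [[Rcpp::export]]
IntegerVector label_components_3d_cpp(LogicalVector mask, IntegerVector dims,
                                      int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != mask.size())
    stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector labels(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (mask[i] != TRUE || labels[i] != 0) continue;
    ++cur;
    labels[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / nxy);
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t u = xx + (R_xlen_t)nx * yy + nxy * zz;
        if (mask[u] == TRUE && labels[u] == 0) {
          labels[u] = cur;
          stack.push_back(u);
        }
      }
    }
  }
  return labels;
}

// For every voxel set true in `mask`, collect the distinct positive values
// of `labels` found in its neighbourhood (given connectivity). Returns, for
// each mask voxel in flattened order, nothing directly; instead returns a
// two-column matrix (component id from `comp`, touched label) of unique
// pairs. Used to find which MTs each mesh component touches.
// [[Rcpp::export]]
IntegerMatrix touched_labels_cpp(IntegerVector comp, IntegerVector labels,
                                 IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (comp.size() != labels.size()) stop("comp/labels size mismatch");

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  std::set<std::pair<int, int>> pairs;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t v = 0; v < comp.size(); ++v) {
    if (comp[v] == 0) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / nxy);
    for (const auto &o : offs) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t u = xx + (R_xlen_t)nx * yy + nxy * zz;
      if (labels[u] > 0) pairs.insert({comp[v], labels[u]});
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int i = 0;
  for (const auto &p : pairs) {
    out(i, 0) = p.first;
    out(i, 1) = p.second;
    ++i;
  }
  return out;
}
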