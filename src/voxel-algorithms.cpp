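// 3D voxel kernels: connected-component labelling (6/26-connectivity) and
// marker-based watershed by priority flooding (Meyer's algorithm with
// FIFO tie-breaking for determinism).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline void neighbour_offsets(const IntegerVector& dim, int connectivity,
                                     std::vector<std::array<int, 3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(dim, connectivity, off);

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sxy);
      for (const auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sxy;
        if (mask[w] && labels[w] == 0) { labels[w] = next; stack.push_back(w); }
      }
    }
  }
  return labels;
}

struct QItem {
  double value;
  uint64_t order;
  R_xlen_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.order > b.order;                          // FIFO on ties
  }
};

// [[Rcpp::export(name = ".watershed_flood_cpp")]]
IntegerVector watershed_flood_cpp(NumericVector surface, IntegerVector markers,
                                  LogicalVector retained, IntegerVector dim,
                                  int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (surface.size() != n || markers.size() != n || retained.size() != n)
    stop("surface/markers/retained size does not match dim");
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(dim, connectivity, off);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  IntegerVector labels(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t counter = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (retained[s] && markers[s] > 0) {
      labels[s] = markers[s];
      pq.push({surface[s], counter++, s, markers[s]});
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    R_xlen_t v = it.idx;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sxy);
    for (const auto& o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sxy;
      if (!retained[w] || labels[w] != 0) continue;
      labels[w] = labels[v];
      pq.push({surface[w], counter++, w, labels[w]});
    }
  }
  return labels;
}
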