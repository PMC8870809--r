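#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Label connected foreground voxels; connectivity 26 (face+edge+corner) or 6.
// Returns integer labels 1..n, 0 for background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t nb = vidx(ii, jj, kk, nx, ny);
            if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Regional maxima of `field` restricted to `mask` (26-neighbourhood):
// voxels whose value is >= every in-mask neighbour.  Plateau maxima are
// returned as all their voxels; the caller merges nearby maxima.
// [[Rcpp::export]]
LogicalVector regional_maxima_cpp(NumericVector field, LogicalVector mask,
                                  IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t s = vidx(i, j, k, nx, ny);
        if (!mask[s]) continue;
        double v = field[s];
        bool is_max = true;
        for (int dk = -1; dk <= 1 && is_max; ++dk)
          for (int dj = -1; dj <= 1 && is_max; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              R_xlen_t nb = vidx(ii, jj, kk, nx, ny);
              if (mask[nb] && field[nb] > v) { is_max = false; break; }
            }
        out[s] = is_max;
      }
  return out;
}

struct WsNode {
  double value;   // intensity (flood descends from high values)
  R_xlen_t order; // FIFO tie-break for determinism
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value < b.value; // max-heap on value
    return a.order > b.order;                         // then first-pushed wins
  }
};

// Marker-controlled watershed on an intensity field, restricted to a mask.
// `markers` carries positive seed labels inside the mask (0 elsewhere).
// Flooding proceeds from high intensity downwards (suited to SUV peaks);
// every in-mask voxel receives the label of the marker basin that reaches it
// first.  26-connectivity, deterministic FIFO tie-break.
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector field, LogicalVector mask,
                            IntegerVector markers, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(markers.size(), 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t order = 0;
  for (R_xlen_t s = 0; s < markers.size(); ++s)
    if (markers[s] > 0 && mask[s]) {
      lab[s] = markers[s];
      pq.push({field[s], order++, s});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t cur = nd.idx;
    int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((R_xlen_t)nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = ci + di, jj = cj + dj, kk = ck + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          R_xlen_t nb = vidx(ii, jj, kk, nx, ny);
          if (!mask[nb] || lab[nb]) continue;
          lab[nb] = lab[cur];
          pq.push({field[nb], order++, nb});
        }
  }
  return lab;
}
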