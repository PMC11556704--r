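#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8- and 4-neighbourhood offsets (row, col)
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

struct QNode {
  double elev;
  unsigned long order; // FIFO tie-break: lower insertion order wins
  int idx;
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order;
  }
};

// Meyer's flooding (marker-based watershed), region-filling variant:
// every pixel is assigned the label of the marker basin that reaches it
// first in elevation-ordered flooding. Deterministic given inputs.
// [[Rcpp::export]]
IntegerMatrix watershed_flood(NumericMatrix elevation, IntegerMatrix markers,
                              int connectivity = 8) {
  int nr = elevation.nrow(), nc = elevation.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("elevation and markers must have identical dimensions");
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int* DR = (connectivity == 8) ? DR8 : DR4;
  const int* DC = (connectivity == 8) ? DC8 : DC4;
  int nnb = connectivity;

  IntegerMatrix labels = clone(markers);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  unsigned long order = 0;

  // seed the queue with all marker pixels
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (labels(r, c) > 0)
        pq.push({elevation(r, c), order++, r + c * nr});

  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int lab = labels(r, c);
    for (int k = 0; k < nnb; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) == 0) {
        labels(rr, cc) = lab;
        pq.push({elevation(rr, cc), order++, rr + cc * nr});
      }
    }
  }
  return labels;
}

// Connected-component labeling of a binary mask with 4- or 8-connectivity.
// Returns an integer matrix with components numbered 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 4) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int* DR = (connectivity == 8) ? DR8 : DR4;
  const int* DC = (connectivity == 8) ? DC8 : DC4;
  int nnb = connectivity;

  IntegerMatrix labels(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = pr + DR[k], cc = pc + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return labels;
}
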