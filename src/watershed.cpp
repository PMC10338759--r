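// Seeded watershed by descending-height priority flood (8-connectivity).
// At each step the globally highest unlabeled frontier pixel is labeled
// with the label of its highest already-labeled neighbor. Ties broken by
// (row, col) lexicographic order so results are bit-reproducible.
#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  double z;
  int row, col;
};

struct NodeLess {
  // max-heap on z; ties -> smaller (row, col) first
  bool operator()(const Node& a, const Node& b) const {
    if (a.z != b.z) return a.z < b.z;
    if (a.row != b.row) return a.row > b.row;
    return a.col > b.col;
  }
};

}  // namespace

// z: CHM matrix; seed_rows/seed_cols: 1-based pixel coordinates, seed i gets
// label i; min_height: background cutoff. Returns integer label matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_flood(NumericMatrix z, IntegerVector seed_rows,
                                  IntegerVector seed_cols, double min_height) {
  int nr = z.nrow(), nc = z.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<Node, std::vector<Node>, NodeLess> heap;
  int ns = seed_rows.size();
  for (int s = 0; s < ns; ++s) {
    int r = seed_rows[s] - 1, c = seed_cols[s] - 1;
    lab(r, c) = s + 1;
  }
  auto push_neighbors = [&](int r, int c) {
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (lab(rr, cc) != 0) continue;
        if (!(z(rr, cc) >= min_height)) continue;
        heap.push({z(rr, cc), rr, cc});
      }
  };
  for (int s = 0; s < ns; ++s) push_neighbors(seed_rows[s] - 1, seed_cols[s] - 1);
  while (!heap.empty()) {
    Node nd = heap.top();
    heap.pop();
    if (lab(nd.row, nd.col) != 0) continue;  // stale entry
    // highest labeled neighbor, ties by (row, col)
    int best = 0;
    double bestz = R_NegInf;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = nd.row + dr, cc = nd.col + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l == 0) continue;
        if (z(rr, cc) > bestz) { bestz = z(rr, cc); best = l; }
      }
    if (best == 0) continue;  // can happen only for stale geometry; skip
    lab(nd.row, nd.col) = best;
    push_neighbors(nd.row, nd.col);
  }
  return lab;
}
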