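#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the growth region with lexicographic
// (cost, label) ordering. A step from p to q costs
// sqrt((I(p) - I(q))^2 + lambda * |p - q|^2) with |p - q| the Euclidean step
// length (1 or sqrt(2)). Seed pixels start at cost 0, keep their own label,
// and are never traversed by other labels' paths. Cost ties resolve to the
// smaller label id.

struct Node {
  double cost;
  int label;
  int idx;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.label > b.label;
  }
};

// [[Rcpp::export]]
IntegerMatrix propagate_cpp(IntegerMatrix seeds, NumericMatrix guide,
                            LogicalMatrix region, double lambda,
                            int connectivity) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  const int n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, 0);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;

  for (int idx = 0; idx < n; ++idx) {
    if (seeds[idx] > 0) {
      dist[idx] = 0.0;
      lab[idx] = seeds[idx];
      pq.push(Node{0.0, seeds[idx], idx});
    }
  }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    const int idx = nd.idx;
    if (nd.cost > dist[idx] ||
        (nd.cost == dist[idx] && nd.label > lab[idx])) continue;
    const int i = idx % nr, j = idx / nr;
    for (int k = 0; k < nnb; ++k) {
      const int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      const int jdx = ii + jj * nr;
      if (!region[jdx]) continue;
      if (seeds[jdx] > 0) continue;  // seeds are never re-assigned
      const double dI = guide(i, j) - guide(ii, jj);
      const double step2 = (k < 4) ? 1.0 : 2.0;
      const double ncost = dist[idx] + std::sqrt(dI * dI + lambda * step2);
      if (ncost < dist[jdx] ||
          (ncost == dist[jdx] && nd.label < lab[jdx])) {
        dist[jdx] = ncost;
        lab[jdx] = nd.label;
        pq.push(Node{ncost, nd.label, jdx});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int idx = 0; idx < n; ++idx) out[idx] = lab[idx];
  return out;
}
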