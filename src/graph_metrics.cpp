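#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local efficiency per node: global efficiency (mean inverse shortest-path
// length) of the subgraph induced by the node's neighbours, 0 for degree < 2.
// Plain BFS within each neighbour set; graphs here are small and dense.
// [[Rcpp::export(name = ".local_efficiency_core")]]
NumericVector local_efficiency_core(IntegerMatrix adj) {
  int n = adj.nrow();
  NumericVector out(n);
  std::vector<int> nb, dist, queue;
  for (int i = 0; i < n; i++) {
    nb.clear();
    for (int j = 0; j < n; j++) if (adj(i, j)) nb.push_back(j);
    int k = (int)nb.size();
    if (k < 2) { out[i] = 0.0; continue; }
    dist.assign(k, -1);
    queue.assign(k, 0);
    double sum = 0.0;
    for (int s = 0; s < k; s++) {
      std::fill(dist.begin(), dist.end(), -1);
      dist[s] = 0;
      int qh = 0, qt = 0;
      queue[qt++] = s;
      while (qh < qt) {
        int u = queue[qh++];
        for (int v = 0; v < k; v++) {
          if (dist[v] < 0 && adj(nb[u], nb[v])) {
            dist[v] = dist[u] + 1;
            queue[qt++] = v;
          }
        }
      }
      for (int t = 0; t < k; t++)
        if (t != s && dist[t] > 0) sum += 1.0 / dist[t];
    }
    out[i] = sum / ((double)k * (k - 1));
  }
  return out;
}
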