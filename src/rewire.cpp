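#include <Rcpp.h>
using namespace Rcpp;

// Double-edge-swap core of the Maslov-Sneppen rewiring. Uses R's RNG so a
// set.seed() on the R side makes the whole surrogate deterministic.
//
// adj: logical adjacency matrix (modified copy is returned)
// edges: m x 2 integer matrix of 0-based node indices, i < j per row
// target: number of successful swaps requested
// max_attempts: attempt budget before accepting partial mixing
// [[Rcpp::export(name = ".rewire_core")]]
List rewire_core(LogicalMatrix adj, IntegerMatrix edges, int target,
                 double max_attempts) {
  LogicalMatrix A = clone(adj);
  IntegerMatrix E = clone(edges);
  int m = E.nrow();
  int succ = 0;
  double att = 0;
  while (succ < target && att < max_attempts) {
    att += 1;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m || e2 >= m || e1 == e2) continue;
    int a = E(e1, 0), b = E(e1, 1);
    int c = E(e2, 0), d = E(e2, 1);
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    if (a == c || a == d || b == c || b == d) continue;
    if (A(a, d) || A(c, b)) continue;
    A(a, b) = A(b, a) = false;
    A(c, d) = A(d, c) = false;
    A(a, d) = A(d, a) = true;
    A(c, b) = A(b, c) = true;
    E(e1, 0) = a < d ? a : d; E(e1, 1) = a < d ? d : a;
    E(e2, 0) = c < b ? c : b; E(e2, 1) = c < b ? b : c;
    succ += 1;
  }
  return List::create(_["adj"] = A, _["swaps"] = succ,
                      _["attempts"] = att);
}
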