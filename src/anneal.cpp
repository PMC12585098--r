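#include <Rcpp.h>
using namespace Rcpp;

// Total linear-arrangement cost: sum over edges of |pos(u) - pos(v)|.
static double arrangement_cost(const std::vector<int> &pos,
                               const IntegerVector &u,
                               const IntegerVector &v) {
  double cost = 0.0;
  for (int e = 0; e < u.size(); ++e) {
    cost += std::abs(pos[u[e]] - pos[v[e]]);
  }
  return cost;
}

// Simulated annealing for the minimum linear arrangement of a graph.
// Nodes 0..n-1, edges (u, v). Proposal: swap the positions of two random
// nodes; geometric cooling with ratio `cool`, initial temperature
// cost0 / n. Stops after `patience` sweeps (n proposals each) without
// improving the best cost, or after `max_sweeps`. Uses R's RNG, so
// set.seed() in R makes the result reproducible.
// [[Rcpp::export]]
IntegerVector anneal_order_cpp(IntegerVector u, IntegerVector v, int n,
                               int max_sweeps, int patience, double cool) {
  std::vector<int> pos(n), arr(n);
  for (int i = 0; i < n; ++i) { pos[i] = i; arr[i] = i; }

  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < u.size(); ++e) {
    adj[u[e]].push_back(v[e]);
    adj[v[e]].push_back(u[e]);
  }

  double cost = arrangement_cost(pos, u, v);
  double best_cost = cost;
  std::vector<int> best_arr = arr;
  double temp = cost > 0 ? cost / n : 1.0;
  int stale = 0;

  for (int sweep = 0; sweep < max_sweeps && stale < patience; ++sweep) {
    bool improved = false;
    for (int it = 0; it < n; ++it) {
      int a = (int)(unif_rand() * n);
      int b = (int)(unif_rand() * n);
      if (a >= n) a = n - 1;
      if (b >= n) b = n - 1;
      if (a == b) continue;
      int pa = pos[a], pb = pos[b];
      double delta = 0.0;
      for (int x : adj[a]) {
        if (x == b) continue;
        delta += std::abs(pb - pos[x]) - std::abs(pa - pos[x]);
      }
      for (int x : adj[b]) {
        if (x == a) continue;
        delta += std::abs(pa - pos[x]) - std::abs(pb - pos[x]);
      }
      if (delta <= 0 || unif_rand() < std::exp(-delta / temp)) {
        pos[a] = pb; pos[b] = pa;
        arr[pb] = a; arr[pa] = b;
        cost += delta;
        if (cost < best_cost - 1e-9) {
          best_cost = cost;
          best_arr = arr;
          improved = true;
        }
      }
    }
    temp *= cool;
    if (temp < 1e-6) temp = 1e-6;
    stale = improved ? 0 : stale + 1;
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_arr[i];
  return out;
}
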