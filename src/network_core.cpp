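#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Tolerance for treating two weighted path lengths as tied when counting
// shortest paths. SRI weights are small rationals, so genuine ties are exact
// up to rounding noise far below this.
static const double PATH_EPS = 1e-9;

namespace {

struct Graph {
  int n;
  std::vector<int> from, to;       // 0-based endpoints, from < to
  std::vector<double> w;           // association weight (strength)
  std::vector<double> len;         // distance used for betweenness
  std::vector<std::vector<std::pair<int,int>>> adj; // node -> (nbr, edge id)

  void build_adj(const std::vector<char> &active) {
    adj.assign(n, {});
    for (size_t e = 0; e < from.size(); ++e) {
      if (!active[e]) continue;
      adj[from[e]].push_back({to[e], (int)e});
      adj[to[e]].push_back({from[e], (int)e});
    }
  }
};

// Scratch buffers for repeated Brandes single-source passes.
struct BrandesWorkspace {
  std::vector<double> dist, sigma, delta;
  std::vector<char> done;
  std::vector<int> order;
  std::vector<std::vector<std::pair<int,int>>> preds; // (pred node, edge)
  void resize(int n) {
    dist.resize(n); sigma.resize(n); delta.resize(n); done.resize(n);
    order.reserve(n); preds.resize(n);
  }
};

// Directed dependency of source s on every edge (Brandes accumulation with
// Dijkstra; O(n * comp_size) node selection - networks here are tens of
// nodes). Writes into row (length m), which must be zeroed by the caller.
void single_source_dependency(const Graph &g, int s, BrandesWorkspace &ws,
                              double *row) {
  int n = g.n;
  std::fill(ws.dist.begin(), ws.dist.end(), R_PosInf);
  std::fill(ws.sigma.begin(), ws.sigma.end(), 0.0);
  std::fill(ws.done.begin(), ws.done.end(), 0);
  for (int v = 0; v < n; ++v) ws.preds[v].clear();
  ws.order.clear();
  ws.dist[s] = 0.0; ws.sigma[s] = 1.0;

  for (int it = 0; it < n; ++it) {
    int u = -1; double best = R_PosInf;
    for (int v = 0; v < n; ++v)
      if (!ws.done[v] && ws.dist[v] < best) { best = ws.dist[v]; u = v; }
    if (u < 0) break;
    ws.done[u] = 1;
    ws.order.push_back(u);
    for (auto &pr : g.adj[u]) {
      int v = pr.first, e = pr.second;
      if (ws.done[v]) continue;
      double nd = ws.dist[u] + g.len[e];
      if (nd < ws.dist[v] - PATH_EPS) {
        ws.dist[v] = nd;
        ws.sigma[v] = ws.sigma[u];
        ws.preds[v].assign(1, {u, e});
      } else if (std::fabs(nd - ws.dist[v]) <= PATH_EPS) {
        ws.sigma[v] += ws.sigma[u];
        ws.preds[v].push_back({u, e});
      }
    }
  }

  std::fill(ws.delta.begin(), ws.delta.end(), 0.0);
  for (int i = (int)ws.order.size() - 1; i > 0; --i) {
    int v = ws.order[i];
    for (auto &pe : ws.preds[v]) {
      double c = ws.sigma[pe.first] / ws.sigma[v] * (1.0 + ws.delta[v]);
      row[pe.second] += c;
      ws.delta[pe.first] += c;
    }
  }
}

// Betweenness per edge, each unordered pair counted once.
std::vector<double> edge_betweenness_core(Graph &g,
                                          const std::vector<char> &active) {
  int n = g.n;
  size_t m = g.from.size();
  std::vector<double> btw(m, 0.0);
  std::vector<double> row(m);
  g.build_adj(active);
  BrandesWorkspace ws;
  ws.resize(n);
  for (int s = 0; s < n; ++s) {
    std::fill(row.begin(), row.end(), 0.0);
    single_source_dependency(g, s, ws, row.data());
    for (size_t e = 0; e < m; ++e) btw[e] += row[e];
  }
  for (auto &b : btw) b *= 0.5; // each (s,t) pair visited from both ends
  return btw;
}

// Connected components of the active subgraph; labels contiguous from 0 in
// order of first appearance (node index order).
std::vector<int> components_core(const Graph &g,
                                 const std::vector<char> &active) {
  int n = g.n;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (size_t e = 0; e < g.from.size(); ++e) {
    if (!active[e]) continue;
    int a = find(g.from[e]), b = find(g.to[e]);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
  std::vector<int> lab(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (lab[r] < 0) lab[r] = next++;
    lab[i] = lab[r];
  }
  return lab;
}

// Newman modularity Q = sum_c (e_cc - a_c^2) on the FULL edge set.
double modularity_core(const Graph &g, const std::vector<int> &memb,
                       bool weighted) {
  int n = g.n;
  int ncomm = 0;
  for (int i = 0; i < n; ++i) ncomm = std::max(ncomm, memb[i] + 1);
  std::vector<double> within(ncomm, 0.0), str(ncomm, 0.0);
  double total2 = 0.0;
  for (size_t e = 0; e < g.from.size(); ++e) {
    double ww = weighted ? g.w[e] : 1.0;
    str[memb[g.from[e]]] += ww;
    str[memb[g.to[e]]] += ww;
    total2 += 2.0 * ww;
    if (memb[g.from[e]] == memb[g.to[e]]) within[memb[g.from[e]]] += 2.0 * ww;
  }
  if (total2 <= 0) return 0.0;
  double q = 0.0;
  for (int c = 0; c < ncomm; ++c) {
    double a = str[c] / total2;
    q += within[c] / total2 - a * a;
  }
  return q;
}

Graph make_graph(int n, const IntegerVector &from, const IntegerVector &to,
                 const NumericVector &w, bool weighted) {
  Graph g;
  g.n = n;
  size_t m = from.size();
  g.from.resize(m); g.to.resize(m); g.w.resize(m); g.len.resize(m);
  for (size_t e = 0; e < m; ++e) {
    g.from[e] = from[e] - 1;
    g.to[e] = to[e] - 1;
    g.w[e] = w[e];
    g.len[e] = weighted ? 1.0 / w[e] : 1.0;
  }
  return g;
}

struct GNResult {
  std::vector<int> best_memb;
  double best_q;
  int best_step;
  std::vector<double> q_steps;
  std::vector<std::vector<int>> memb_steps; // only if keep_steps
  std::vector<int> removal_order;           // edge ids, 0-based
};

GNResult girvan_newman_core(Graph &g, bool weighted, bool keep_steps) {
  size_t m = g.from.size();
  std::vector<char> active(m, 1);
  GNResult res;
  res.best_q = R_NegInf;
  res.best_step = 0;

  int step = 0;
  std::vector<int> memb = components_core(g, active);
  double q = modularity_core(g, memb, weighted);
  res.q_steps.push_back(q);
  if (keep_steps) res.memb_steps.push_back(memb);
  res.best_q = q; res.best_memb = memb;

  // Incremental betweenness: cache each source's directed dependency on
  // every edge. Removing an edge only perturbs shortest paths inside its
  // own connected component, so only sources in that component are redone.
  int n = g.n;
  std::vector<double> contrib((size_t)n * m, 0.0);
  std::vector<double> btw(m, 0.0);
  BrandesWorkspace ws;
  ws.resize(n);
  g.build_adj(active);
  for (int s = 0; s < n; ++s) {
    double *row = contrib.data() + (size_t)s * m;
    single_source_dependency(g, s, ws, row);
    for (size_t e = 0; e < m; ++e) btw[e] += row[e];
  }

  size_t remaining = m;
  while (remaining > 0) {
    // max over active edges; ties (within tolerance) -> lowest edge index,
    // i.e. lexicographically first (id_a, id_b) pair given sorted input.
    double best = -1.0;
    for (size_t e = 0; e < m; ++e)
      if (active[e] && btw[e] > best) best = btw[e];
    int pick = -1;
    for (size_t e = 0; e < m; ++e)
      if (active[e] && btw[e] >= best - PATH_EPS * (1.0 + best)) { pick = (int)e; break; }
    int affected = memb[g.from[pick]]; // component label before removal
    active[pick] = 0;
    --remaining;
    ++step;
    res.removal_order.push_back(pick);
    std::vector<int> memb_old = memb;
    memb = components_core(g, active);
    q = modularity_core(g, memb, weighted);
    res.q_steps.push_back(q);
    if (keep_steps) res.memb_steps.push_back(memb);
    if (q > res.best_q + 1e-12) { // strict improvement keeps earliest partition on ties
      res.best_q = q;
      res.best_memb = memb;
      res.best_step = step;
    }
    if (remaining == 0) break;
    g.build_adj(active);
    for (int s = 0; s < n; ++s) {
      if (memb_old[s] != affected) continue;
      double *row = contrib.data() + (size_t)s * m;
      for (size_t e = 0; e < m; ++e) { btw[e] -= row[e]; row[e] = 0.0; }
      single_source_dependency(g, s, ws, row);
      for (size_t e = 0; e < m; ++e) btw[e] += row[e];
    }
  }
  return res;
}

// One checkerboard swap attempt stream on a GBI matrix (in place).
// Draws (row i, row j, col a, col b) uniformly with rejection; falls back to
// exhaustive enumeration if max_attempts rejections occur. Returns:
// 1 swapped, 0 no valid swap exists.
int gbi_swap_core(IntegerMatrix &g, int max_attempts) {
  int nr = g.nrow(), nc = g.ncol();
  if (nr < 2 || nc < 2) return 0;
  for (int t = 0; t < max_attempts; ++t) {
    int i = (int)(unif_rand() * nr); if (i >= nr) i = nr - 1;
    int j = (int)(unif_rand() * nr); if (j >= nr) j = nr - 1;
    int a = (int)(unif_rand() * nc); if (a >= nc) a = nc - 1;
    int b = (int)(unif_rand() * nc); if (b >= nc) b = nc - 1;
    if (i == j || a == b) continue;
    if (g(i, a) == 1 && g(i, b) == 0 && g(j, a) == 0 && g(j, b) == 1) {
      g(i, a) = 0; g(i, b) = 1; g(j, a) = 1; g(j, b) = 0;
      return 1;
    }
  }
  // Exhaustive: count valid (i, j, a, b) with i<j in either orientation.
  long long total = 0;
  for (int i = 0; i < nr - 1; ++i)
    for (int j = i + 1; j < nr; ++j) {
      long long ab = 0, ba = 0;
      for (int c = 0; c < nc; ++c) {
        if (g(i, c) == 1 && g(j, c) == 0) ++ab;
        else if (g(i, c) == 0 && g(j, c) == 1) ++ba;
      }
      total += ab * ba;
    }
  if (total == 0) return 0;
  long long target = (long long)(unif_rand() * total);
  if (target >= total) target = total - 1;
  for (int i = 0; i < nr - 1; ++i)
    for (int j = i + 1; j < nr; ++j) {
      std::vector<int> A, B;
      for (int c = 0; c < nc; ++c) {
        if (g(i, c) == 1 && g(j, c) == 0) A.push_back(c);
        else if (g(i, c) == 0 && g(j, c) == 1) B.push_back(c);
      }
      long long k = (long long)A.size() * (long long)B.size();
      if (target < k) {
        int a = A[target / B.size()];
        int b = B[target % B.size()];
        g(i, a) = 0; g(i, b) = 1; g(j, a) = 1; g(j, b) = 0;
        return 1;
      }
      target -= k;
    }
  return 0; // unreachable
}

// SRI edge list from a GBI matrix: x / (n_a + n_b - x) for co-sighted pairs.
void sri_edges_core(const IntegerMatrix &g, std::vector<int> &from,
                    std::vector<int> &to, std::vector<double> &w) {
  int nr = g.nrow(), nc = g.ncol();
  std::vector<int> colsum(nc, 0);
  std::vector<std::vector<double>> X(nc, std::vector<double>(nc, 0.0));
  std::vector<int> members;
  for (int r = 0; r < nr; ++r) {
    members.clear();
    for (int c = 0; c < nc; ++c)
      if (g(r, c) == 1) { members.push_back(c); ++colsum[c]; }
    for (size_t u = 0; u < members.size(); ++u)
      for (size_t v = u + 1; v < members.size(); ++v)
        X[members[u]][members[v]] += 1.0;
  }
  from.clear(); to.clear(); w.clear();
  for (int a = 0; a < nc - 1; ++a)
    for (int b = a + 1; b < nc; ++b) {
      double x = X[a][b];
      if (x > 0) {
        from.push_back(a + 1);
        to.push_back(b + 1);
        w.push_back(x / (colsum[a] + colsum[b] - x));
      }
    }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_edge_betweenness(int n, IntegerVector from, IntegerVector to,
                                   NumericVector w, bool weighted) {
  Graph g = make_graph(n, from, to, w, weighted);
  std::vector<char> active(g.from.size(), 1);
  std::vector<double> btw = edge_betweenness_core(g, active);
  return wrap(btw);
}

// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerVector from, IntegerVector to) {
  NumericVector w(from.size(), 1.0);
  Graph g = make_graph(n, from, to, w, false);
  std::vector<char> active(g.from.size(), 1);
  std::vector<int> lab = components_core(g, active);
  return wrap(lab);
}

// [[Rcpp::export]]
double cpp_modularity(int n, IntegerVector from, IntegerVector to,
                      NumericVector w, IntegerVector membership,
                      bool weighted) {
  Graph g = make_graph(n, from, to, w, weighted);
  std::vector<int> memb(membership.begin(), membership.end());
  return modularity_core(g, memb, weighted);
}

// [[Rcpp::export]]
List cpp_girvan_newman(int n, IntegerVector from, IntegerVector to,
                       NumericVector w, bool weighted, bool keep_steps) {
  Graph g = make_graph(n, from, to, w, weighted);
  GNResult res = girvan_newman_core(g, weighted, keep_steps);
  List out = List::create(
    _["membership"] = wrap(res.best_memb),
    _["q"] = res.best_q,
    _["step"] = res.best_step,
    _["q_steps"] = wrap(res.q_steps),
    _["removal_order"] = wrap(res.removal_order));
  if (keep_steps) {
    IntegerMatrix ms(res.memb_steps.size(), n);
    for (size_t i = 0; i < res.memb_steps.size(); ++i)
      for (int v = 0; v < n; ++v) ms(i, v) = res.memb_steps[i][v];
    out["memb_steps"] = ms;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_gbi_swap(IntegerMatrix gbi, int max_attempts) {
  IntegerMatrix g = clone(gbi);
  RNGScope scope;
  int ok = gbi_swap_core(g, max_attempts);
  return List::create(_["gbi"] = g, _["swapped"] = (ok == 1));
}

// [[Rcpp::export]]
List cpp_sri_edges(IntegerMatrix gbi) {
  std::vector<int> from, to;
  std::vector<double> w;
  sri_edges_core(gbi, from, to, w);
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["weight"] = wrap(w));
}

// Serial chain: apply n_swaps sequential checkerboard swaps to a copy of the
// GBI, recomputing the Girvan-Newman maximum-modularity Q after each swap.
// [[Rcpp::export]]
List cpp_serial_q_chain(IntegerMatrix gbi, int n_swaps, bool weighted,
                        int max_attempts) {
  IntegerMatrix g = clone(gbi);
  RNGScope scope;
  int nc = g.ncol();
  NumericVector q(n_swaps);
  LogicalVector swapped(n_swaps);
  std::vector<int> from, to;
  std::vector<double> w;
  for (int s = 0; s < n_swaps; ++s) {
    swapped[s] = gbi_swap_core(g, max_attempts) == 1;
    sri_edges_core(g, from, to, w);
    Graph gr;
    gr.n = nc;
    size_t m = from.size();
    gr.from.resize(m); gr.to.resize(m); gr.w.resize(m); gr.len.resize(m);
    for (size_t e = 0; e < m; ++e) {
      gr.from[e] = from[e] - 1; gr.to[e] = to[e] - 1;
      gr.w[e] = w[e];
      gr.len[e] = weighted ? 1.0 / w[e] : 1.0;
    }
    GNResult res = girvan_newman_core(gr, weighted, false);
    q[s] = res.best_q;
    if (s % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["q"] = q, _["swapped"] = swapped);
}
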