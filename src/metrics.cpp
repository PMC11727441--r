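#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Adjacency list from a 0/1 symmetric matrix; diagonal ignored.
static std::vector< std::vector<int> > adj_list(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nb[i].push_back(j);
  return nb;
}

// [[Rcpp::export]]
NumericMatrix bfs_distances_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nb = adj_list(adj);
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t k = 0; k < nb[v].size(); ++k) {
        int w = nb[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    for (int j = 0; j < n; ++j)
      if (dist[j] >= 0) D(s, j) = dist[j];
  }
  return D;
}

// Global efficiency of the subgraph induced by `keep` (local indices into nb).
static double subgraph_efficiency(const std::vector< std::vector<int> >& nb,
                                  const std::vector<int>& keep,
                                  std::vector<int>& local_id) {
  int m = (int) keep.size();
  if (m < 2) return 0.0;
  for (size_t i = 0; i < keep.size(); ++i) local_id[keep[i]] = (int) i;
  double sum_inv = 0.0;
  std::vector<int> dist(m);
  std::queue<int> q;
  for (int s = 0; s < m; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int gv = keep[v];
      for (size_t k = 0; k < nb[gv].size(); ++k) {
        int gw = nb[gv][k];
        int w = local_id[gw];
        if (w >= 0 && dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    for (int j = 0; j < m; ++j)
      if (j != s && dist[j] > 0) sum_inv += 1.0 / dist[j];
  }
  for (size_t i = 0; i < keep.size(); ++i) local_id[keep[i]] = -1;
  return sum_inv / ((double) m * (m - 1));
}

// All global and nodal binary-graph metrics in one pass.
// need_betweenness / need_local switch off the expensive parts for null ensembles.
// [[Rcpp::export]]
List graph_metrics_cpp(IntegerMatrix adj, bool need_betweenness, bool need_local) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nb = adj_list(adj);

  NumericVector deg(n), ncp(n), nlp(n), ne(n), nle(n), bc(n);

  // clustering: edges among neighbours
  for (int v = 0; v < n; ++v) {
    int k = (int) nb[v].size();
    deg[v] = k;
    if (k < 2) { ncp[v] = 0.0; continue; }
    int links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb[v][a], nb[v][b]) != 0) ++links;
    ncp[v] = 2.0 * links / ((double) k * (k - 1));
  }

  // BFS (+ Brandes if requested)
  double lp_sum = 0.0, eg_sum = 0.0;
  long long lp_cnt = 0, unreachable = 0;
  std::vector<int> dist(n), order(n);
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred;
  if (need_betweenness) pred.resize(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    order[tail++] = s;
    if (need_betweenness) {
      std::fill(sigma.begin(), sigma.end(), 0.0);
      sigma[s] = 1.0;
      for (int i = 0; i < n; ++i) pred[i].clear();
    }
    while (head < tail) {
      int v = order[head++];
      for (size_t k = 0; k < nb[v].size(); ++k) {
        int w = nb[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; order[tail++] = w; }
        if (need_betweenness && dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    double d_sum = 0.0, inv_sum = 0.0;
    long long reach = 0;
    for (int j = 0; j < n; ++j) {
      if (j == s) continue;
      if (dist[j] > 0) {
        d_sum += dist[j];
        inv_sum += 1.0 / dist[j];
        ++reach;
      } else {
        ++unreachable;
      }
    }
    nlp[s] = (reach > 0) ? d_sum / reach : NA_REAL;
    ne[s]  = (n > 1) ? inv_sum / (n - 1) : 0.0;
    lp_sum += d_sum; lp_cnt += reach; eg_sum += inv_sum;

    if (need_betweenness) {
      std::fill(delta.begin(), delta.end(), 0.0);
      for (int i = tail - 1; i >= 0; --i) {
        int w = order[i];
        for (size_t k = 0; k < pred[w].size(); ++k) {
          int v = pred[w][k];
          delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
        }
        if (w != s) bc[w] += delta[w];
      }
    }
  }
  if (need_betweenness)
    for (int v = 0; v < n; ++v) bc[v] /= 2.0;  // unordered pairs

  double lp = (lp_cnt > 0) ? lp_sum / lp_cnt : NA_REAL;
  double eglob = (n > 1) ? eg_sum / ((double) n * (n - 1)) : 0.0;

  double eloc = NA_REAL;
  if (need_local) {
    std::vector<int> local_id(n, -1);
    double acc = 0.0;
    for (int v = 0; v < n; ++v) {
      nle[v] = (nb[v].size() < 2) ? 0.0 : subgraph_efficiency(nb, nb[v], local_id);
      acc += nle[v];
    }
    eloc = (n > 0) ? acc / n : NA_REAL;
  }

  double cp = 0.0;
  for (int v = 0; v < n; ++v) cp += ncp[v];
  cp = (n > 0) ? cp / n : NA_REAL;

  return List::create(
    _["cp"] = cp, _["lp"] = lp, _["eglob"] = eglob, _["eloc"] = eloc,
    _["deg"] = deg, _["ncp"] = ncp, _["nlp"] = nlp, _["ne"] = ne,
    _["nle"] = need_local ? nle : NumericVector(0),
    _["bc"] = need_betweenness ? bc : NumericVector(0),
    _["unreachable_pairs"] = (double) unreachable);
}

// Sizes of connected components (descending).
// [[Rcpp::export]]
IntegerVector component_sizes_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nb = adj_list(adj);
  std::vector<int> comp(n, -1);
  std::vector<int> sizes;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    int c = (int) sizes.size(), sz = 0;
    std::queue<int> q;
    q.push(s); comp[s] = c;
    while (!q.empty()) {
      int v = q.front(); q.pop(); ++sz;
      for (size_t k = 0; k < nb[v].size(); ++k) {
        int w = nb[v][k];
        if (comp[w] < 0) { comp[w] = c; q.push(w); }
      }
    }
    sizes.push_back(sz);
  }
  IntegerVector out(sizes.begin(), sizes.end());
  std::sort(out.begin(), out.end(), std::greater<int>());
  return out;
}
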