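#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Generalized (Sankoff) parsimony on a rooted tree given as an edge list.
// Exact for multifurcating trees and for both unordered (unit-cost) and
// ordered (|i-j| cost) characters; missing states carry zero cost everywhere,
// i.e. they are free to take any state.

static const double INF = 1e18;

// Postorder over an edge list with arbitrary positive node ids.
// Node ids 1..n_nodes; leaves are 1..n_leaf. Returns node order, children in
// `kids`, and the root id.
static void build_topology(const IntegerMatrix &edge, int n_nodes,
                           std::vector<std::vector<int> > &kids,
                           std::vector<int> &order, int &root) {
  std::vector<char> is_child(n_nodes + 1, 0);
  kids.assign(n_nodes + 1, std::vector<int>());
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    is_child[edge(i, 1)] = 1;
  }
  root = -1;
  for (int v = 1; v <= n_nodes; ++v) {
    if (!kids[v].empty() && !is_child[v]) { root = v; break; }
  }
  if (root < 0) stop("edge list has no root (cyclic or empty)");
  order.clear();
  order.reserve(n_nodes);
  std::vector<std::pair<int, size_t> > stk;
  stk.push_back(std::make_pair(root, (size_t)0));
  while (!stk.empty()) {
    size_t top = stk.size() - 1;
    int v = stk[top].first;
    size_t k = stk[top].second;
    if (k < kids[v].size()) {
      stk[top].second++;
      stk.push_back(std::make_pair(kids[v][k], (size_t)0));
    } else {
      order.push_back(v);
      stk.pop_back();
    }
  }
}

// leaf_states: n_leaf x n_char, entries in 0..(n_states-1), NA = missing.
// n_states, ordered: per character. Returns per-character minimum change
// counts (cost 1 per step for unordered, |i-j| for ordered).
// [[Rcpp::export]]
NumericVector cpp_parsimony_per_char(IntegerMatrix edge, int n_leaf,
                                     IntegerMatrix leaf_states,
                                     IntegerVector n_states,
                                     LogicalVector ordered) {
  int n_char = leaf_states.ncol();
  int n_nodes = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    if (edge(i, 0) > n_nodes) n_nodes = edge(i, 0);
    if (edge(i, 1) > n_nodes) n_nodes = edge(i, 1);
  }
  std::vector<std::vector<int> > kids;
  std::vector<int> order;
  int root;
  build_topology(edge, n_nodes, kids, order, root);

  NumericVector out(n_char);
  // cost[node][state], reused per character
  std::vector<std::vector<double> > cost(n_nodes + 1);
  for (int v = 0; v <= n_nodes; ++v) cost[v].assign(4, 0.0);

  for (int k = 0; k < n_char; ++k) {
    int S = n_states[k];
    bool ord = ordered[k];
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int v = order[oi];
      std::vector<double> &cv = cost[v];
      if (v <= n_leaf) {
        int s = leaf_states(v - 1, k);
        if (s == NA_INTEGER) {
          for (int i = 0; i < S; ++i) cv[i] = 0.0;
        } else {
          for (int i = 0; i < S; ++i) cv[i] = (i == s) ? 0.0 : INF;
        }
      } else {
        for (int i = 0; i < S; ++i) cv[i] = 0.0;
        for (size_t c = 0; c < kids[v].size(); ++c) {
          std::vector<double> &cc = cost[kids[v][c]];
          for (int i = 0; i < S; ++i) {
            double best = INF;
            for (int j = 0; j < S; ++j) {
              double step = cc[j];
              if (step >= INF) continue;
              step += ord ? std::abs(i - j) : (i == j ? 0.0 : 1.0);
              if (step < best) best = step;
            }
            cv[i] += best;
          }
        }
      }
    }
    double best = INF;
    for (int i = 0; i < S; ++i)
      if (cost[root][i] < best) best = cost[root][i];
    out[k] = best;
  }
  return out;
}

// Weighted total parsimony score (single number), same conventions.
// [[Rcpp::export]]
double cpp_parsimony_score(IntegerMatrix edge, int n_leaf,
                           IntegerMatrix leaf_states, IntegerVector n_states,
                           LogicalVector ordered, NumericVector weights) {
  NumericVector per = cpp_parsimony_per_char(edge, n_leaf, leaf_states,
                                             n_states, ordered);
  double tot = 0.0;
  for (int k = 0; k < per.size(); ++k) tot += weights[k] * per[k];
  return tot;
}
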