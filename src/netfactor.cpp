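#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Equal-frequency (rank) binning of each row of X into n_bins bins.
// Ties are broken by column index (stable sort) so that results are
// deterministic, including on bootstrap-resampled matrices with exact
// duplicates. Bin of the k-th smallest value (0-based k) is
// floor(k * n_bins / n), which splits samples into bins of near-equal size.
// [[Rcpp::export]]
IntegerMatrix bin_rows(NumericMatrix X, int n_bins) {
  const int G = X.nrow(), n = X.ncol();
  IntegerMatrix B(G, n);
  std::vector<int> ord(n);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    NumericMatrix::Row row = X(g, _);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return row[a] < row[b]; });
    for (int k = 0; k < n; ++k)
      B(g, ord[k]) = (int)(((double)k * n_bins) / n);
  }
  return B;
}

static double mi_from_bins(const int* bx, const int* by, int n, int nb) {
  std::vector<int> joint(nb * nb, 0), rx(nb, 0), cy(nb, 0);
  for (int i = 0; i < n; ++i) {
    joint[bx[i] * nb + by[i]]++;
    rx[bx[i]]++;
    cy[by[i]]++;
  }
  double mi = 0.0, dn = (double)n;
  for (int a = 0; a < nb; ++a) {
    if (rx[a] == 0) continue;
    for (int b = 0; b < nb; ++b) {
      int c = joint[a * nb + b];
      if (c == 0 || cy[b] == 0) continue;
      double p = c / dn;
      mi += p * std::log(p * dn * dn / ((double)rx[a] * (double)cy[b]));
    }
  }
  return mi > 0 ? mi : 0.0; // clamp tiny negative rounding
}

// Plug-in MI (nats) for a set of row pairs of a pre-binned matrix.
// I, J are 1-based row indices.
// [[Rcpp::export]]
NumericVector mi_pairs_cpp(IntegerMatrix B, IntegerVector I, IntegerVector J,
                           int n_bins) {
  const int n = B.ncol(), m = I.size();
  NumericVector out(m);
  // copy rows once into contiguous buffers on demand
  std::vector<int> bx(n), by(n);
  for (int k = 0; k < m; ++k) {
    int i = I[k] - 1, j = J[k] - 1;
    for (int s = 0; s < n; ++s) { bx[s] = B(i, s); by[s] = B(j, s); }
    out[k] = mi_from_bins(bx.data(), by.data(), n, n_bins);
  }
  return out;
}

// [[Rcpp::export]]
double mi_bins_single(IntegerVector bx, IntegerVector by, int n_bins) {
  return mi_from_bins(bx.begin(), by.begin(), bx.size(), n_bins);
}

// DPI pruning over all 3-cliques of an undirected weighted graph.
//
// Nodes are 1-based indices, assumed ordered so that index order equals
// lexicographic order of node identifiers (the R wrapper guarantees this,
// which makes the tie-break below deterministic). For every triangle the
// minimum-MI edge is marked for removal (ties at tolerance 0: the edge with
// the lexicographically smallest endpoint pair among the tied minima),
// unless that victim is transcriptional (>=1 TF endpoint) while the triangle
// contains a non-TF<->non-TF edge; such an edge is not a transcriptional
// interaction and is removed instead. With tolerance t > 0 the triangle is
// skipped when min_mi >= (1 - t) * second_mi. Removals are evaluated on the
// input graph and applied at the end (an edge survives only if no triangle
// removed it).
// [[Rcpp::export]]
LogicalVector dpi_keep_cpp(int n_nodes, LogicalVector is_tf, IntegerVector ei,
                           IntegerVector ej, NumericVector mi, double tol) {
  const int E = ei.size();
  std::vector<char> removed(E, 0);
  // adjacency: node -> sorted (neighbor, edge index)
  std::vector<std::vector<std::pair<int, int> > > adj(n_nodes);
  for (int e = 0; e < E; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    adj[u].push_back(std::make_pair(v, e));
    adj[v].push_back(std::make_pair(u, e));
  }
  for (int u = 0; u < n_nodes; ++u) std::sort(adj[u].begin(), adj[u].end());

  // edge sort key: (tf endpoint first if exactly one, else min, then other)
  std::vector<std::pair<int, int> > key(E);
  for (int e = 0; e < E; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    int a = std::min(u, v), b = std::max(u, v);
    if (is_tf[a] != is_tf[b]) { // exactly one TF: (tf, target)
      if (is_tf[b]) std::swap(a, b);
    }
    key[e] = std::make_pair(a, b);
  }

  struct Tri { int e; double mi; std::pair<int,int> key; bool nontx; };
  // enumerate each triangle once via u < v < w
  for (int u = 0; u < n_nodes; ++u) {
    for (size_t iu = 0; iu < adj[u].size(); ++iu) {
      int v = adj[u][iu].first;
      if (v <= u) continue;
      int euv = adj[u][iu].second;
      // intersect neighbors of u and v with w > v
      size_t a = 0, b = 0;
      const std::vector<std::pair<int, int> >& Au = adj[u];
      const std::vector<std::pair<int, int> >& Av = adj[v];
      while (a < Au.size() && b < Av.size()) {
        int wu = Au[a].first, wv = Av[b].first;
        if (wu < wv) { ++a; continue; }
        if (wv < wu) { ++b; continue; }
        int w = wu;
        if (w > v) {
          int e1 = euv, e2 = Au[a].second, e3 = Av[b].second;
          Tri t[3];
          int uu[3] = {e1, e2, e3};
          for (int q = 0; q < 3; ++q) {
            int e = uu[q];
            int x = ei[e] - 1, y = ej[e] - 1;
            t[q].e = e; t[q].mi = mi[e]; t[q].key = key[e];
            t[q].nontx = !is_tf[x] && !is_tf[y];
          }
          std::sort(t, t + 3, [](const Tri& p, const Tri& q) {
            if (p.mi != q.mi) return p.mi < q.mi;
            return p.key < q.key;
          });
          bool fire;
          if (tol <= 0.0) {
            fire = true; // min <= second always; exact ties fire with tie-break
          } else {
            fire = t[0].mi < (1.0 - tol) * t[1].mi;
          }
          if (fire) {
            int victim = t[0].e;
            if (!t[0].nontx && (t[1].nontx || t[2].nontx)) {
              // remove the weakest non-transcriptional edge instead
              victim = t[1].nontx ? t[1].e : t[2].e;
              if (t[1].nontx && t[2].nontx) victim = t[1].e;
            }
            removed[victim] = 1;
          }
        }
        ++a; ++b;
      }
    }
  }
  LogicalVector keep(E);
  for (int e = 0; e < E; ++e) keep[e] = !removed[e];
  return keep;
}
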