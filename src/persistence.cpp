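#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <unordered_map>
#include <vector>

// Vietoris-Rips persistent homology for homological dimensions 0 and 1,
// computed from a dense distance matrix.
//
// H0 uses Kruskal union-find over the sorted edge list: the weights of the
// merging (spanning-forest) edges are exactly the deaths of the dim-0
// classes, all born at 0.
//
// H1 uses the dual (persistent cohomology) reduction with clearing, the
// standard fast scheme for Vietoris-Rips filtrations: columns are the
// non-spanning-forest edges processed in decreasing filtration order, rows
// are their cofacet triangles enumerated on the fly, and the pivot of a
// reduced column is its cofacet of minimal filtration position. The
// resulting (edge, triangle) pairs are exactly the dimension-1 persistence
// pairs of the clique complex restricted to simplices of dimension <= 2;
// most columns pair immediately ("apparent pairs"), which keeps the
// reduction near-linear in the number of edges.
//
// Ties in edge weights are broken by lexicographic vertex-pair order and
// triangle ties by lexicographic vertex-triple order, so output is fully
// deterministic.

namespace {

struct Edge {
  double w;
  int i, j;
};

struct Tri {
  double diam;
  int i, j, k;
};

// global filtration order of triangles (ascending)
inline bool tri_less(const Tri& a, const Tri& b) {
  if (a.diam != b.diam) return a.diam < b.diam;
  if (a.i != b.i) return a.i < b.i;
  if (a.j != b.j) return a.j < b.j;
  return a.k < b.k;
}

inline bool tri_eq(const Tri& a, const Tri& b) {
  return a.i == b.i && a.j == b.j && a.k == b.k;
}

// min-heap on the global triangle order = pivot order of the dual matrix
struct TriGreater {
  bool operator()(const Tri& a, const Tri& b) const { return tri_less(b, a); }
};

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List vr_persistence_cpp(Rcpp::NumericMatrix D, int max_hom_dim,
                              double threshold) {
  const int n = D.nrow();

  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = D(i, j);
      if (w <= threshold) edges.push_back({w, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });

  const size_t m = edges.size();

  // --- dimension 0: Kruskal ---
  UnionFind uf(n);
  std::vector<double> h0_deaths;
  std::vector<char> in_forest(m, 0);
  for (size_t e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      h0_deaths.push_back(edges[e].w);
      in_forest[e] = 1;
    }
  }

  std::vector<double> h1_births, h1_deaths;

  if (max_hom_dim >= 1 && n >= 3) {
    // reduced columns, keyed by their pivot triangle (encoded i*n^2+j*n+k)
    std::unordered_map<long long, int> owner;
    std::vector<std::vector<Tri> > stored;
    auto encode = [n](const Tri& t) {
      return (static_cast<long long>(t.i) * n + t.j) * n + t.k;
    };

    std::priority_queue<Tri, std::vector<Tri>, TriGreater> heap;
    std::vector<Tri> reduced;

    // clearing: spanning-forest edges are negative in dimension 0 and can
    // never pair with a triangle; skip them.
    for (size_t e = m; e-- > 0;) {
      if (in_forest[e]) continue;
      const int a = edges[e].i, b = edges[e].j;
      const double we = edges[e].w;

      while (!heap.empty()) heap.pop();
      for (int c = 0; c < n; ++c) {
        if (c == a || c == b) continue;
        double dac = D(a, c), dbc = D(b, c);
        if (dac > threshold || dbc > threshold) continue;
        double diam = std::max(we, std::max(dac, dbc));
        int i = a, j = b, k = c;  // sort vertices ascending
        if (k < i) std::swap(i, k);
        if (j < i) std::swap(i, j);
        if (k < j) std::swap(j, k);
        heap.push({diam, i, j, k});
      }

      reduced.clear();
      bool paired = false;
      Tri pivot{0, -1, -1, -1};
      while (!heap.empty()) {
        // pop with mod-2 cancellation of duplicate entries
        Tri t = heap.top();
        heap.pop();
        bool keep = true;
        while (!heap.empty() && tri_eq(heap.top(), t)) {
          heap.pop();
          keep = !keep;
        }
        if (!keep) continue;
        if (!paired) {
          auto it = owner.find(encode(t));
          if (it != owner.end()) {
            // pivot collision: add the owning reduced column and continue
            for (const Tri& s : stored[it->second]) heap.push(s);
            heap.push(t);  // re-insert so it cancels against the copy added
            continue;
          }
          pivot = t;
          paired = true;
        }
        reduced.push_back(t);
      }

      if (paired) {
        owner[encode(pivot)] = static_cast<int>(stored.size());
        stored.push_back(reduced);
        if (pivot.diam > we) {
          h1_births.push_back(we);
          h1_deaths.push_back(pivot.diam);
        }
      }
      // an empty column is an essential dimension-1 class (infinite bar,
      // only possible with a finite threshold); finalized diagrams drop it
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("h0_deaths") = Rcpp::wrap(h0_deaths),
      Rcpp::Named("h1_births") = Rcpp::wrap(h1_births),
      Rcpp::Named("h1_deaths") = Rcpp::wrap(h1_deaths));
}
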