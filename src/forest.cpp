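#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic splitmix64 generator: per-tree seeds must reproduce the same
// tree on any platform, independent of R's RNG state.
struct SplitMix {
  uint64_t state;
  explicit SplitMix(double seed) : state((uint64_t)seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // integer in [0, n)
  int upto(int n) { return (int)(unif() * n); }
};

// Flat tree arrays; node 0 is the root. feature == -1 marks a leaf.
struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y; // class labels 1 (HC) / 2 (PD)
  int q;
  SplitMix rng;
  std::vector<int> feature, left, right;
  std::vector<double> threshold, n1, n2;
  std::vector<int> feats; // feature permutation buffer

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int q_, double seed)
    : X(X_), y(y_), q(q_), rng(seed), feats(X_.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) feats[j] = j;
  }

  int new_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    threshold.push_back(NA_REAL); n1.push_back(0); n2.push_back(0);
    return (int)feature.size() - 1;
  }

  // idx: in-bag row indices (0-based, with bootstrap multiplicity)
  int build(std::vector<int>& idx) {
    int node = new_node();
    double c1 = 0, c2 = 0;
    for (int r : idx) (y[r] == 2 ? c2 : c1)++;
    n1[node] = c1; n2[node] = c2;
    if (c1 == 0 || c2 == 0 || idx.size() < 2) return node;

    int p = X.ncol();
    // partial Fisher-Yates: first q entries are the candidate features
    for (int i = 0; i < q; ++i) {
      int j = i + rng.upto(p - i);
      std::swap(feats[i], feats[j]);
    }
    double best_score = R_PosInf, best_thr = 0;
    int best_f = -1;
    std::vector<std::pair<double, int> > v;
    v.reserve(idx.size());
    for (int k = 0; k < q; ++k) {
      int f = feats[k];
      v.clear();
      for (int r : idx) v.push_back(std::make_pair(X(r, f), y[r]));
      std::sort(v.begin(), v.end());
      if (v.front().first == v.back().first) continue;
      double a = 0, b = 0; // left-side class counts (HC, PD)
      int m = (int)v.size();
      for (int i = 0; i < m - 1; ++i) {
        (v[i].second == 2 ? b : a)++;
        if (v[i].first == v[i + 1].first) continue;
        double nl = a + b, nr = (double)m - nl;
        // weighted Gini sum (up to constants): 2ab/nl + 2a'b'/nr
        double score = 2.0 * a * b / nl + 2.0 * (c1 - a) * (c2 - b) / nr;
        if (score < best_score - 1e-12) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (v[i].first + v[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node; // candidates all constant: leaf

    std::vector<int> li, ri;
    for (int r : idx) (X(r, best_f) <= best_thr ? li : ri).push_back(r);
    feature[node] = best_f; threshold[node] = best_thr;
    { std::vector<int>().swap(idx); } // release before recursing
    left[node] = build(li);
    right[node] = build(ri);
    return node;
  }

  List as_list() const {
    return List::create(
      _["feature"] = IntegerVector(feature.begin(), feature.end()),
      _["threshold"] = NumericVector(threshold.begin(), threshold.end()),
      _["left"] = IntegerVector(left.begin(), left.end()),
      _["right"] = IntegerVector(right.begin(), right.end()),
      _["n1"] = NumericVector(n1.begin(), n1.end()),
      _["n2"] = NumericVector(n2.begin(), n2.end()));
  }
};

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, List inbag, int q,
                     NumericVector seeds) {
  int B = inbag.size();
  if (seeds.size() != B) stop("one seed per tree required");
  List forest(B);
  for (int b = 0; b < B; ++b) {
    IntegerVector rows = inbag[b]; // 1-based
    std::vector<int> idx(rows.size());
    for (int i = 0; i < rows.size(); ++i) idx[i] = rows[i] - 1;
    TreeBuilder tb(X, y, q, seeds[b]);
    tb.build(idx);
    forest[b] = tb.as_list();
  }
  return forest;
}

struct TreeView {
  IntegerVector feature, left, right;
  NumericVector threshold, n1, n2;
  explicit TreeView(List t)
    : feature(t["feature"]), left(t["left"]), right(t["right"]),
      threshold(t["threshold"]), n1(t["n1"]), n2(t["n2"]) {}
  // override_f >= 0 substitutes override_v for feature override_f
  int leaf_of(const NumericMatrix& X, int row, int override_f = -1,
              double override_v = 0) const {
    int node = 0;
    while (feature[node] >= 0) {
      int f = feature[node];
      double v = (f == override_f) ? override_v : X(row, f);
      node = (v <= threshold[node]) ? left[node] : right[node];
    }
    return node;
  }
};

// Per-tree PD leaf frequency f(t, x, c = 2) for every row; n x B matrix.
// [[Rcpp::export]]
NumericMatrix cpp_leaf_freq2(List forest, NumericMatrix X) {
  int B = forest.size(), n = X.nrow();
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    TreeView t(forest[b]);
    for (int i = 0; i < n; ++i) {
      int leaf = t.leaf_of(X, i);
      out(i, b) = t.n2[leaf] / (t.n1[leaf] + t.n2[leaf]);
    }
  }
  return out;
}

// Terminal-node id (1-based within each tree) for every row; n x B matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_leaf_ids(List forest, NumericMatrix X) {
  int B = forest.size(), n = X.nrow();
  IntegerMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    TreeView t(forest[b]);
    for (int i = 0; i < n; ++i) out(i, b) = t.leaf_of(X, i) + 1;
  }
  return out;
}

// Co-leaf frequency over all trees from a leaf-id matrix.
// [[Rcpp::export]]
NumericMatrix cpp_proximity(IntegerMatrix ids) {
  int n = ids.nrow(), B = ids.ncol();
  NumericMatrix phi(n, n);
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j)
        if (ids(i, b) == ids(j, b)) { phi(i, j)++; }
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      phi(i, j) /= B;
      phi(j, i) = phi(i, j);
    }
  return phi;
}

// Mean decrease in per-tree OOB hard-vote accuracy when a feature is
// permuted among that tree's OOB rows. Hard class: PD iff leaf PD
// frequency exceeds 1/2 (tie counts as HC).
// [[Rcpp::export]]
NumericVector cpp_perm_importance(List forest, NumericMatrix X, IntegerVector y,
                                  List oob, NumericVector seeds) {
  int B = forest.size(), p = X.ncol();
  NumericVector imp(p);
  int used = 0;
  for (int b = 0; b < B; ++b) {
    IntegerVector rows = oob[b];
    int m = rows.size();
    if (m == 0) continue;
    used++;
    TreeView t(forest[b]);
    SplitMix rng(seeds[b]);
    double acc0 = 0;
    for (int k = 0; k < m; ++k) {
      int leaf = t.leaf_of(X, rows[k] - 1);
      int pred = (t.n2[leaf] > t.n1[leaf]) ? 2 : 1;
      if (pred == y[rows[k] - 1]) acc0++;
    }
    acc0 /= m;
    std::vector<int> perm(m);
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < m; ++k) perm[k] = k;
      for (int k = m - 1; k > 0; --k) std::swap(perm[k], perm[rng.upto(k + 1)]);
      double acc = 0;
      for (int k = 0; k < m; ++k) {
        int row = rows[k] - 1;
        double v = X(rows[perm[k]] - 1, j);
        int leaf = t.leaf_of(X, row, j, v);
        int pred = (t.n2[leaf] > t.n1[leaf]) ? 2 : 1;
        if (pred == y[row]) acc++;
      }
      imp[j] += acc0 - acc / m;
    }
  }
  if (used == 0) stop("no tree has out-of-bag rows");
  for (int j = 0; j < p; ++j) imp[j] /= used;
  return imp;
}
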