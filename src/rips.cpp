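// Vietoris-Rips persistent homology over Z/2 via persistent cohomology with
// clearing and emergent (zero-persistence) pair shortcuts.
//
// Simplices are encoded in the combinatorial number system: a simplex with
// vertices v0 < v1 < ... < vd has index sum_i C(v_i, i + 1).  Within a fixed
// dimension the filtration order is (diameter ascending, index descending);
// cofacet enumeration visits vertices in descending order so that, among
// cofacets tying the column simplex's diameter, the first one seen is the
// filtration-minimal pivot candidate.

#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>

typedef int64_t index_t;

namespace {

struct Binomial {
  int nmax, kmax;
  std::vector<index_t> tab;
  Binomial(int n, int k) : nmax(n), kmax(k), tab((size_t)(n + 1) * (k + 1), 0) {
    for (int i = 0; i <= n; ++i) {
      tab[(size_t)i * (kmax + 1)] = 1;
      for (int j = 1; j <= std::min(i, k); ++j)
        tab[(size_t)i * (kmax + 1) + j] =
            tab[(size_t)(i - 1) * (kmax + 1) + j - 1] +
            tab[(size_t)(i - 1) * (kmax + 1) + j];
    }
  }
  index_t operator()(int n, int k) const {
    if (k < 0 || k > n) return 0;
    return tab[(size_t)n * (kmax + 1) + k];
  }
};

struct Entry {
  double diam;
  index_t idx;
};

// "a enters the filtration strictly after b"
inline bool filt_later(const Entry& a, const Entry& b) {
  return (a.diam > b.diam) || (a.diam == b.diam && a.idx < b.idx);
}

// priority_queue comparator: top = filtration-minimal entry
struct HeapCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    return filt_later(a, b);
  }
};

struct UnionFind {
  std::vector<int> parent, rank_;
  explicit UnionFind(int n) : parent(n), rank_(n, 0) {
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
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

class RipsEngine {
 public:
  RipsEngine(const Rcpp::NumericMatrix& pts, int maxdim, double threshold)
      : n_(pts.nrow()),
        maxdim_(maxdim),
        threshold_(threshold),
        binom_(pts.nrow() + 1, maxdim + 3),
        dist_((size_t)pts.nrow() * pts.nrow(), 0.0) {
    const int p = pts.ncol();
    for (int i = 0; i < n_; ++i)
      for (int j = i + 1; j < n_; ++j) {
        double s = 0.0;
        for (int c = 0; c < p; ++c) {
          double d = pts(i, c) - pts(j, c);
          s += d * d;
        }
        double d = std::sqrt(s);
        dist_[(size_t)i * n_ + j] = d;
        dist_[(size_t)j * n_ + i] = d;
      }
  }

  void run() {
    compute_dim0();
    std::vector<bool> cleared = mst_edges_;  // pivots of the dim-0 pairing
    for (int dim = 1; dim <= maxdim_; ++dim)
      cleared = reduce_dimension(dim, cleared);
  }

  Rcpp::NumericMatrix result() const {
    Rcpp::NumericMatrix out(dims_.size(), 3);
    for (size_t i = 0; i < dims_.size(); ++i) {
      out(i, 0) = dims_[i];
      out(i, 1) = births_[i];
      out(i, 2) = deaths_[i];
    }
    Rcpp::colnames(out) =
        Rcpp::CharacterVector::create("dimension", "birth", "death");
    return out;
  }

 private:
  int n_, maxdim_;
  double threshold_;
  Binomial binom_;
  std::vector<double> dist_;
  std::vector<bool> mst_edges_;
  std::vector<int> dims_;
  std::vector<double> births_, deaths_;

  double dist(int i, int j) const { return dist_[(size_t)i * n_ + j]; }

  void emit(int dim, double birth, double death) {
    dims_.push_back(dim);
    births_.push_back(birth);
    deaths_.push_back(death);
  }

  index_t simplex_index(const std::vector<int>& vs) const {
    index_t idx = 0;
    for (size_t i = 0; i < vs.size(); ++i) idx += binom_(vs[i], (int)i + 1);
    return idx;
  }

  // vertices in ascending order; out must have size dim + 1
  void simplex_vertices(index_t idx, int dim, std::vector<int>* out) const {
    int v = n_ - 1;
    for (int pos = dim + 1; pos >= 1; --pos) {
      while (binom_(v, pos) > idx) --v;
      (*out)[pos - 1] = v;
      idx -= binom_(v, pos);
      --v;
    }
  }

  double simplex_diameter(const std::vector<int>& vs) const {
    double d = 0.0;
    for (size_t i = 0; i < vs.size(); ++i)
      for (size_t j = i + 1; j < vs.size(); ++j)
        d = std::max(d, dist(vs[i], vs[j]));
    return d;
  }

  void compute_dim0() {
    std::vector<Entry> edges;
    edges.reserve((size_t)n_ * (n_ - 1) / 2);
    std::vector<int> vs(2);
    for (int j = 1; j < n_; ++j)
      for (int i = 0; i < j; ++i) {
        double d = dist(i, j);
        if (d <= threshold_) {
          vs[0] = i;
          vs[1] = j;
          edges.push_back({d, simplex_index(vs)});
        }
      }
    std::sort(edges.begin(), edges.end(),
              [](const Entry& a, const Entry& b) { return filt_later(b, a); });
    mst_edges_.assign((size_t)binom_(n_, 2), false);
    UnionFind uf(n_);
    std::vector<int> verts(2);
    for (const Entry& e : edges) {
      simplex_vertices(e.idx, 1, &verts);
      if (uf.unite(verts[0], verts[1])) {
        mst_edges_[e.idx] = true;
        if (e.diam > 0.0) emit(0, 0.0, e.diam);
      }
    }
    for (int i = 0; i < n_; ++i)
      if (uf.find(i) == i) emit(0, 0.0, R_PosInf);
  }

  // Enumerate cofacets of (vs, idx, diam) in descending new-vertex order,
  // i.e. descending cofacet index = ascending filtration among diameter ties.
  template <typename F>
  void for_each_cofacet(const std::vector<int>& vs, double diam, F&& f) const {
    const int d1 = (int)vs.size();  // simplex has d1 vertices
    for (int w = n_ - 1; w >= 0; --w) {
      bool member = false;
      double cd = diam;
      for (int v : vs) {
        if (v == w) {
          member = true;
          break;
        }
        cd = std::max(cd, dist(v, w));
      }
      if (member || cd > threshold_) continue;
      // index of vs u {w}: vertices below w keep positions, above w shift up
      index_t cidx = 0;
      int pos = 0;
      for (int i = 0; i < d1; ++i) {
        if (vs[i] < w)
          cidx += binom_(vs[i], i + 1);
        else
          cidx += binom_(vs[i], i + 2);
      }
      for (int i = 0; i < d1; ++i)
        if (vs[i] < w) ++pos;
      cidx += binom_(w, pos + 1);
      if (!f(Entry{cd, cidx})) return;
    }
  }

  // Pop the heap top with mod-2 cancellation of duplicates.
  static bool pop_pivot(
      std::priority_queue<Entry, std::vector<Entry>, HeapCmp>* heap,
      Entry* out) {
    while (!heap->empty()) {
      Entry e = heap->top();
      heap->pop();
      size_t count = 1;
      while (!heap->empty() && heap->top().idx == e.idx) {
        heap->pop();
        ++count;
      }
      if (count % 2 == 1) {
        *out = e;
        return true;
      }
    }
    return false;
  }

  // Reduce dimension `dim`; `cleared` flags dim-simplices already paired as
  // pivots one dimension down.  Returns the flags for (dim+1)-simplices.
  std::vector<bool> reduce_dimension(int dim, const std::vector<bool>& cleared) {
    std::vector<Entry> columns;
    enumerate_simplices(dim, cleared, &columns);
    // process in decreasing filtration order
    std::sort(columns.begin(), columns.end(), filt_later);

    std::unordered_map<index_t, size_t> pivot_col;
    pivot_col.reserve(columns.size() * 2 + 16);
    std::vector<std::vector<index_t>> vcols(columns.size());
    std::vector<int> vs(dim + 1);

    for (size_t j = 0; j < columns.size(); ++j) {
      if (j % 4096 == 0) Rcpp::checkUserInterrupt();
      const Entry sigma = columns[j];
      simplex_vertices(sigma.idx, dim, &vs);

      std::priority_queue<Entry, std::vector<Entry>, HeapCmp> heap;
      std::vector<Entry> seen;
      bool emergent = false;
      bool check_emergent = true;
      index_t emergent_idx = 0;
      for_each_cofacet(vs, sigma.diam, [&](const Entry& cof) {
        if (check_emergent && cof.diam == sigma.diam) {
          if (pivot_col.find(cof.idx) == pivot_col.end()) {
            emergent = true;
            emergent_idx = cof.idx;
            return false;  // stop enumeration: zero-persistence pair
          }
          // the filtration-minimal cofacet is already a pivot: no shortcut
          check_emergent = false;
        }
        seen.push_back(cof);
        return true;
      });
      if (emergent) {
        pivot_col.emplace(emergent_idx, j);
        vcols[j].push_back(sigma.idx);
        continue;
      }
      for (const Entry& e : seen) heap.push(e);

      std::vector<index_t> vcol;
      vcol.push_back(sigma.idx);
      std::vector<int> tvs(dim + 1);
      for (;;) {
        Entry pivot;
        if (!pop_pivot(&heap, &pivot)) {
          emit(dim, sigma.diam, R_PosInf);  // essential class
          break;
        }
        auto it = pivot_col.find(pivot.idx);
        if (it == pivot_col.end()) {
          if (pivot.diam > sigma.diam) emit(dim, sigma.diam, pivot.diam);
          pivot_col.emplace(pivot.idx, j);
          vcols[j] = vcol;
          break;
        }
        // restore the net-odd pivot copy popped above; it cancels against
        // the matching entry of the added column's coboundary
        heap.push(pivot);
        for (index_t tidx : vcols[it->second]) {
          vcol.push_back(tidx);
          simplex_vertices(tidx, dim, &tvs);
          double tdiam = simplex_diameter(tvs);
          for_each_cofacet(tvs, tdiam, [&](const Entry& cof) {
            heap.push(cof);
            return true;
          });
        }
      }
    }

    std::vector<bool> next((size_t)binom_(n_, dim + 2), false);
    for (const auto& kv : pivot_col) next[kv.first] = true;
    return next;
  }

  // All dim-simplices with diameter <= threshold, minus cleared ones.
  void enumerate_simplices(int dim, const std::vector<bool>& cleared,
                           std::vector<Entry>* out) const {
    std::vector<int> vs(dim + 1);
    for (int i = 0; i <= dim; ++i) vs[i] = i;
    for (;;) {
      double diam = simplex_diameter(vs);
      if (diam <= threshold_) {
        index_t idx = simplex_index(vs);
        if (!cleared[idx]) out->push_back({diam, idx});
      }
      // odometer increment over ascending tuples
      int i = dim;
      while (i >= 0 && vs[i] == n_ - 1 - (dim - i)) --i;
      if (i < 0) break;
      ++vs[i];
      for (int k = i + 1; k <= dim; ++k) vs[k] = vs[k - 1] + 1;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix rips_pairs_cpp(Rcpp::NumericMatrix pts, int maxdim,
                                   double threshold) {
  if (pts.nrow() < 2) Rcpp::stop("point cloud must contain at least 2 points");
  if (maxdim < 0 || maxdim > 2) Rcpp::stop("maxdim must be 0, 1 or 2");
  if (!R_FINITE(threshold) || threshold < 0)
    Rcpp::stop("threshold must be a finite non-negative number");
  RipsEngine engine(pts, maxdim, threshold);
  engine.run();
  return engine.result();
}
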