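// node2vec core: biased second-order random walks over an unweighted graph
// in CSR form, and a skip-gram model with negative sampling trained on the
// resulting walk corpus. Single-threaded and driven by an internal splitmix64
// generator so that a given seed reproduces the embedding bit-for-bit.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

inline bool has_edge(const std::vector<int>& indptr, const std::vector<int>& indices,
                     int u, int v) {
  const int lo = indptr[u], hi = indptr[u + 1];
  return std::binary_search(indices.begin() + lo, indices.begin() + hi, v);
}

} // namespace

// Walks are generated node-major (num_walks passes over all nodes) and then
// shuffled once, so the corpus order is fixed before skip-gram training.
// [[Rcpp::export(".n2v_walks")]]
IntegerMatrix n2v_walks(IntegerVector indptr_, IntegerVector indices_,
                        double p, double q, int walk_length, int num_walks,
                        double seed) {
  const std::vector<int> indptr(indptr_.begin(), indptr_.end());
  const std::vector<int> indices(indices_.begin(), indices_.end());
  const int n = static_cast<int>(indptr.size()) - 1;
  for (int v = 0; v < n; ++v)
    if (indptr[v + 1] == indptr[v])
      stop("node2vec walks require every node to have at least one neighbour");

  SplitMix rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  const int n_walk = n * num_walks;
  IntegerMatrix walks(n_walk, walk_length);
  std::vector<double> w;

  int row = 0;
  for (int pass = 0; pass < num_walks; ++pass) {
    for (int start = 0; start < n; ++start, ++row) {
      int prev = -1, cur = start;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_length; ++step) {
        const int lo = indptr[cur], hi = indptr[cur + 1];
        int nxt;
        if (prev < 0) {
          nxt = indices[lo + rng.below(hi - lo)];
        } else {
          w.assign(hi - lo, 0.0);
          double tot = 0.0;
          for (int j = lo; j < hi; ++j) {
            const int x = indices[j];
            double wt;
            if (x == prev) wt = 1.0 / p;              // return
            else if (has_edge(indptr, indices, prev, x)) wt = 1.0;  // common
            else wt = 1.0 / q;                        // outward
            w[j - lo] = wt;
            tot += wt;
          }
          double u = rng.unif() * tot;
          int j = lo;
          for (; j < hi - 1; ++j) {
            u -= w[j - lo];
            if (u <= 0) break;
          }
          nxt = indices[j];
        }
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }

  // Fisher-Yates shuffle of walk order
  for (int i = n_walk - 1; i > 0; --i) {
    const int j = rng.below(i + 1);
    for (int c = 0; c < walk_length; ++c)
      std::swap(walks(i, c), walks(j, c));
  }
  return walks;
}

// Skip-gram with negative sampling. Input/output layers follow the classic
// word2vec layout: syn0 (the embedding that is returned) updated against
// syn1neg targets; negatives drawn from the unigram^0.75 distribution;
// learning rate decays linearly over epochs * corpus tokens.
// [[Rcpp::export(".sgns_embed")]]
NumericMatrix sgns_embed(IntegerMatrix walks, int n_nodes, int dim,
                         int window, int negative, int epochs,
                         double alpha0, double seed) {
  const int n_walk = walks.nrow(), wl = walks.ncol();
  SplitMix rng(static_cast<uint64_t>(seed) * 0x9E3779B9ULL + 7ULL);

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> cnt(n_nodes, 0.0);
  for (int i = 0; i < n_walk; ++i)
    for (int j = 0; j < wl; ++j) cnt[walks(i, j)] += 1.0;
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    tot += std::pow(cnt[v], 0.75);
    cum[v] = tot;
  }
  if (tot <= 0) stop("empty walk corpus");

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const double total_tokens =
      static_cast<double>(epochs) * n_walk * wl;
  double processed = 0.0;
  std::vector<double> err(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walk; ++i) {
      for (int pos = 0; pos < wl; ++pos, processed += 1.0) {
        const double frac = processed / total_tokens;
        const double alpha = std::max(alpha0 * (1.0 - frac), alpha0 * 1e-4);
        const int center = walks(i, pos);
        const int b = rng.below(window);  // dynamic window shrink
        for (int off = -(window - b); off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= wl) continue;
          const int context = walks(i, cpos);
          double* v0 = &syn0[static_cast<size_t>(context) * dim];
          std::fill(err.begin(), err.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              const double u = rng.unif() * tot;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == center) continue;
              label = 0.0;
            }
            double* v1 = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int c = 0; c < dim; ++c) f += v0[c] * v1[c];
            const double g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int c = 0; c < dim; ++c) {
              err[c] += g * v1[c];
              v1[c] += g * v0[c];
            }
          }
          for (int c = 0; c < dim; ++c) v0[c] += err[c];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int c = 0; c < dim; ++c)
      out(v, c) = syn0[static_cast<size_t>(v) * dim + c];
  return out;
}
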