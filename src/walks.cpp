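#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Weighted sample from cumulative weights in [0, total). Returns index.
static int sample_cum(const std::vector<double>& cum, double total,
                      std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(0.0, total);
  double u = unif(rng);
  return std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
}

// Biased (second-order) random walks. `neighbors` holds 0-based sorted
// neighbor ids per node, `weights` the matching positive edge weights.
// p = q = 1 collapses to a first-order weighted walk. Isolated start nodes
// emit a length-1 walk padded with -1.
// [[Rcpp::export]]
IntegerMatrix cpp_random_walks(List neighbors, List weights,
                               int walks_per_node, int walk_length,
                               double p, double q, int seed) {
  if (p <= 0 || q <= 0) stop("p and q must be positive");
  int n = neighbors.size();
  std::vector<std::vector<int>> nbr(n);
  std::vector<std::vector<double>> wgt(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector nv = neighbors[v];
    NumericVector wv = weights[v];
    nbr[v] = std::vector<int>(nv.begin(), nv.end());
    wgt[v] = std::vector<double>(wv.begin(), wv.end());
  }
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int n_walks = n * walks_per_node;
  IntegerMatrix walks(n_walks, walk_length);
  std::vector<double> cum;
  int row = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start, ++row) {
      for (int j = 0; j < walk_length; ++j) walks(row, j) = -1;
      walks(row, 0) = start;
      if (nbr[start].empty()) continue;
      // first step: first-order weighted
      cum.assign(nbr[start].size(), 0.0);
      double tot = 0.0;
      for (size_t k = 0; k < nbr[start].size(); ++k) {
        tot += wgt[start][k];
        cum[k] = tot;
      }
      int prev = start;
      int cur = nbr[start][sample_cum(cum, tot, rng)];
      walks(row, 1) = cur;
      for (int step = 2; step < walk_length; ++step) {
        const std::vector<int>& cand = nbr[cur];
        if (cand.empty()) break;
        const std::vector<double>& cw = wgt[cur];
        cum.assign(cand.size(), 0.0);
        double total = 0.0;
        const std::vector<int>& tn = nbr[prev];
        for (size_t k = 0; k < cand.size(); ++k) {
          double bias;
          int x = cand[k];
          if (x == prev) {
            bias = 1.0 / p;
          } else if (std::binary_search(tn.begin(), tn.end(), x)) {
            bias = 1.0;
          } else {
            bias = 1.0 / q;
          }
          total += cw[k] * bias;
          cum[k] = total;
        }
        int nxt = cand[sample_cum(cum, total, rng)];
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

static inline double sigmoid(double x) {
  if (x > 10.0) return 1.0;
  if (x < -10.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus. `walks` is 0-based
// with -1 padding. skip = 0: all contexts within `window`; skip = k > 0:
// only contexts at exact offset +/- k (Walklets scales). Noise distribution
// is the corpus unigram distribution raised to 3/4. Returns the center
// vectors plus a flag per node marking participation in at least one pair.
// [[Rcpp::export]]
List cpp_sgns(IntegerMatrix walks, int n_nodes, int dim, int window,
              int negative, int epochs, double lr, int seed, int skip) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  // unigram^{3/4} noise distribution
  std::vector<double> counts(n_nodes, 0.0);
  long long n_tokens = 0;
  for (int i = 0; i < walks.nrow(); ++i)
    for (int j = 0; j < walks.ncol(); ++j)
      if (walks(i, j) >= 0) { counts[walks(i, j)] += 1.0; ++n_tokens; }
  if (n_tokens == 0) stop("empty walk corpus");
  std::vector<double> noise_cum(n_nodes, 0.0);
  double noise_tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    noise_tot += std::pow(counts[v], 0.75);
    noise_cum[v] = noise_tot;
  }

  // init: centers small uniform, contexts zero (word2vec convention)
  std::vector<double> W((size_t)n_nodes * dim), C((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (unif01(rng) - 0.5) / dim;
  std::vector<bool> seen(n_nodes, false);

  // total pair count for linear lr decay
  long long total_pairs = 0;
  for (int i = 0; i < walks.nrow(); ++i) {
    int len = 0;
    for (int j = 0; j < walks.ncol(); ++j) if (walks(i, j) >= 0) ++len; else break;
    for (int a = 0; a < len; ++a) {
      if (skip > 0) {
        if (a - skip >= 0) ++total_pairs;
        if (a + skip < len) ++total_pairs;
      } else {
        int lo = std::max(0, a - window), hi = std::min(len - 1, a + window);
        total_pairs += hi - lo; // excludes a itself
      }
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) {
    NumericMatrix emb(n_nodes, dim);
    return List::create(_["embedding"] = emb,
                        _["seen"] = LogicalVector(n_nodes, false));
  }

  std::vector<double> grad(dim);
  long long processed = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < walks.nrow(); ++i) {
      int len = 0;
      for (int j = 0; j < walks.ncol(); ++j)
        if (walks(i, j) >= 0) ++len; else break;
      for (int a = 0; a < len; ++a) {
        int center = walks(i, a);
        double* wv = &W[(size_t)center * dim];
        int offsets[2] = {-1, -1};
        int lo = 0, hi = -1;
        if (skip > 0) {
          offsets[0] = a - skip;
          offsets[1] = a + skip;
        } else {
          lo = std::max(0, a - window);
          hi = std::min(len - 1, a + window);
        }
        int b_start = (skip > 0) ? 0 : lo;
        int b_end = (skip > 0) ? 1 : hi;
        for (int bi = b_start; bi <= b_end; ++bi) {
          int b;
          if (skip > 0) {
            b = offsets[bi];
            if (b < 0 || b >= len) continue;
          } else {
            b = bi;
            if (b == a) continue;
          }
          int context = walks(i, b);
          double alpha = lr * std::max(1e-4,
              1.0 - (double)processed / (double)total_pairs);
          ++processed;
          seen[center] = true;
          seen[context] = true;
          std::fill(grad.begin(), grad.end(), 0.0);
          // positive + `negative` noise samples
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = context;
              label = 1.0;
            } else {
              std::uniform_real_distribution<double> un(0.0, noise_tot);
              target = std::lower_bound(noise_cum.begin(), noise_cum.end(),
                                        un(rng)) - noise_cum.begin();
              if (target == context) continue;
              label = 0.0;
            }
            double* cv = &C[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += wv[d] * cv[d];
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * cv[d];
              cv[d] += g * wv[d];
            }
          }
          for (int d = 0; d < dim; ++d) wv[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix emb(n_nodes, dim);
  LogicalVector seen_out(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    seen_out[v] = seen[v];
    for (int d = 0; d < dim; ++d)
      emb(v, d) = seen[v] ? W[(size_t)v * dim + d] : 0.0;
  }
  return List::create(_["embedding"] = emb, _["seen"] = seen_out);
}
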