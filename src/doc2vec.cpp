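#include <Rcpp.h>
using namespace Rcpp;

// Distributed bag-of-tokens document embedding (PV-DBOW) trained with
// negative sampling, single-threaded for bitwise reproducibility. Each
// document (one trajectory frame's WL token multiset) gets a dense vector;
// token output vectors are discarded. Negative samples are drawn from the
// unigram distribution raised to 3/4, word2vec-style, via a fixed-size
// sampling table. All randomness comes from an internal xorshift generator
// seeded from the `seed` argument.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  inline uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// precomputed sigmoid over [-6, 6] (word2vec convention): the SGD updates
// saturate outside that range, and the table removes exp() from the inner
// loop
struct SigmoidTable {
  static const int size = 1024;
  double tab[size];
  SigmoidTable() {
    for (int i = 0; i < size; ++i) {
      double x = (i / (double)size * 2.0 - 1.0) * 6.0;
      tab[i] = 1.0 / (1.0 + std::exp(-x));
    }
  }
  inline double operator()(double x) const {
    if (x >= 6.0) return 1.0;
    if (x <= -6.0) return 0.0;
    return tab[(int)((x + 6.0) / 12.0 * size)];
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_pvdbow_train(IntegerVector tokens, IntegerVector offsets,
                               IntegerVector token_counts, int dim,
                               int epochs, double learning_rate, int negative,
                               int seed) {
  const int n_docs = offsets.size() - 1;
  const int V = token_counts.size();
  if (V < 1) stop("empty token vocabulary");
  const size_t T = tokens.size();

  static const SigmoidTable sigmoid;
  XorShift64 rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // doc vectors: small random init; token output vectors: zero init.
  std::vector<double> doc((size_t)n_docs * dim);
  for (size_t i = 0; i < doc.size(); ++i)
    doc[i] = (rng.unif() - 0.5) / dim;
  std::vector<double> out((size_t)V * dim, 0.0);

  // unigram^0.75 negative-sampling table
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int w = 0; w < V; ++w) total += std::pow((double)token_counts[w], 0.75);
    int w = 0;
    double cum = std::pow((double)token_counts[0], 0.75) / total;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((i + 1.0) / table_size > cum && w < V - 1) {
        ++w;
        cum += std::pow((double)token_counts[w], 0.75) / total;
      }
    }
  }

  std::vector<double> grad(dim);
  const double min_alpha = learning_rate * 1e-4;
  const double total_steps = (double)epochs * (double)T;
  double step = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      double* dv = &doc[(size_t)d * dim];
      for (int p = offsets[d]; p < offsets[d + 1]; ++p) {
        double alpha = learning_rate * (1.0 - step / total_steps);
        if (alpha < min_alpha) alpha = min_alpha;
        step += 1.0;
        const int target = tokens[p];
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int s = 0; s <= negative; ++s) {
          int w;
          double label;
          if (s == 0) {
            w = target;
            label = 1.0;
          } else {
            w = table[rng.next() % table_size];
            if (w == target) continue;
            label = 0.0;
          }
          double* wv = &out[(size_t)w * dim];
          double f = 0.0;
          for (int k = 0; k < dim; ++k) f += dv[k] * wv[k];
          const double g = (label - sigmoid(f)) * alpha;
          for (int k = 0; k < dim; ++k) {
            grad[k] += g * wv[k];
            wv[k] += g * dv[k];
          }
        }
        for (int k = 0; k < dim; ++k) dv[k] += grad[k];
      }
    }
  }

  NumericMatrix res(n_docs, dim);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < dim; ++k) res(d, k) = doc[(size_t)d * dim + k];
  return res;
}
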