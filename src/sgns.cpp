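// Skip-Gram with negative sampling, single-threaded and bit-reproducible.
// Sentences are integer token sequences (0-based); the context window is
// symmetric and fixed (no random shrinking) so that with window >= sentence
// length every token pair in a sentence is trained.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t state;
  explicit XorShift64(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    state = x;
    return x;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List sgns_train(List sentences, int vocab_size,
                         NumericVector counts, int dim, int window,
                         int negative, int epochs, double alpha0,
                         double alpha_min, int seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  if (dim < 1) stop("dimension must be >= 1");
  const int n_sent = sentences.size();

  // cumulative unigram^0.75 table for negative sampling (binary search)
  std::vector<double> cum(vocab_size);
  double acc = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    acc += std::pow(counts[v], 0.75);
    cum[v] = acc;
  }
  const double cum_total = acc;

  std::vector<std::vector<int> > sents(n_sent);
  long long total_pairs = 0;
  for (int sidx = 0; sidx < n_sent; ++sidx) {
    IntegerVector s = sentences[sidx];
    sents[sidx].assign(s.begin(), s.end());
    const int L = s.size();
    for (int p = 0; p < L; ++p) {
      int lo = p - window < 0 ? 0 : p - window;
      int hi = p + window >= L ? L - 1 : p + window;
      total_pairs += (hi - lo);  // excludes the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) stop("corpus contains no trainable pairs");

  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // input vectors: small random init; output (negative-sampling) vectors: 0
  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (rng.unif() - 0.5) / dim;

  std::vector<double> neu1e(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int sidx = 0; sidx < n_sent; ++sidx) {
      const std::vector<int>& sen = sents[sidx];
      const int L = static_cast<int>(sen.size());
      for (int p = 0; p < L; ++p) {
        const int wo = sen[p];  // output (predicted) token
        int lo = p - window < 0 ? 0 : p - window;
        int hi = p + window >= L ? L - 1 : p + window;
        for (int q = lo; q <= hi; ++q) {
          if (q == p) continue;
          const int wi = sen[q];  // input (context) token
          const double lr_frac = 1.0 - static_cast<double>(processed) / total_pairs;
          double lr = alpha0 * lr_frac;
          if (lr < alpha_min) lr = alpha_min;
          ++processed;
          double* v_in = &syn0[static_cast<size_t>(wi) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int n = 0; n <= negative; ++n) {
            int target;
            double label;
            if (n == 0) {
              target = wo;
              label = 1.0;
            } else {
              double r = rng.unif() * cum_total;
              int lo2 = 0, hi2 = vocab_size - 1;
              while (lo2 < hi2) {
                int mid = (lo2 + hi2) / 2;
                if (cum[mid] < r) lo2 = mid + 1; else hi2 = mid;
              }
              target = lo2;
              if (target == wo) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            const double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < dim; ++k) {
              neu1e[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  NumericMatrix out1(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k) {
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
      out1(v, k) = syn1[static_cast<size_t>(v) * dim + k];
    }
  return List::create(Named("input") = out, Named("output") = out1);
}
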