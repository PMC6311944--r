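// Skip-gram with negative sampling over random-walk corpora.
// Single-threaded SGD so results are bit-reproducible for a given seed;
// the RNG is a self-contained xorshift64* stream independent of R's RNG.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t state;
  explicit XorShift64(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

// word2vec-style precomputed logistic table on [-8, 8]
struct SigmoidTable {
  static const int N = 2048;
  double tab[N];
  SigmoidTable() {
    for (int i = 0; i < N; ++i) {
      double x = (i * 2.0 / N - 1.0) * 8.0;
      tab[i] = 1.0 / (1.0 + std::exp(-x));
    }
  }
  double operator()(double x) const {
    if (x >= 8.0) return 1.0;
    if (x <= -8.0) return 0.0;
    return tab[(int)((x + 8.0) * (N / 16.0))];
  }
};
static const SigmoidTable sigmoid;

} // namespace

// [[Rcpp::export(name = "sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha0, int seed) {
  XorShift64 rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // input vectors: uniform(-0.5/dim, 0.5/dim); output vectors: zero
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // cumulative unigram^{3/4} table for negative sampling (binary search)
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }
  auto sample_negative = [&]() {
    double r = rng.unif() * tot;
    int lo = 0, hi = vocab_size - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  long long total_words = 0;
  int n_sent = sentences.size();
  std::vector<IntegerVector> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    sents[s] = sentences[s];
    total_words += sents[s].size();
  }

  std::vector<double> grad(dim);
  long long processed = 0;
  long long budget = (long long)epochs * total_words + 1;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const IntegerVector& sent = sents[s];
      int len = sent.size();
      for (int i = 0; i < len; ++i) {
        ++processed;
        double alpha = alpha0 * std::max(1.0 - (double)processed / budget, 1e-4);
        int center = sent[i];
        int lo = std::max(0, i - window);
        int hi = std::min(len - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int context = sent[j];
          double* v = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = context;
              label = 1.0;
            } else {
              target = sample_negative();
              if (target == context) continue;
              label = 0.0;
            }
            double* u = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v[k] * u[k];
            double g = (label - sigmoid(dot)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * u[k];
              u[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
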