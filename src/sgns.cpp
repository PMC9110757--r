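#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// xorshift64: deterministic, independent of R's RNG so embedding training
// cannot perturb the caller's random stream.
static inline uint64_t rng_next(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double rng_unif(uint64_t &s) {
  return (rng_next(s) >> 11) * (1.0 / 9007199254740992.0); // 53-bit mantissa
}

// precomputed logistic table on [-6, 6], the classic word2vec device
#define SIG_TABLE_SIZE 1024
#define SIG_MAX 6.0
static float sig_table[SIG_TABLE_SIZE];
static bool sig_ready = false;

static inline void sig_init() {
  if (sig_ready) return;
  for (int i = 0; i < SIG_TABLE_SIZE; ++i) {
    double x = (2.0 * SIG_MAX * i) / (SIG_TABLE_SIZE - 1) - SIG_MAX;
    sig_table[i] = static_cast<float>(1.0 / (1.0 + std::exp(-x)));
  }
  sig_ready = true;
}

static inline float sigmoid(float x) {
  if (x >= SIG_MAX) return 1.0f;
  if (x <= -SIG_MAX) return 0.0f;
  int i = static_cast<int>((x + SIG_MAX) * ((SIG_TABLE_SIZE - 1) / (2.0 * SIG_MAX)));
  return sig_table[i];
}

// Skip-gram with negative sampling over pre-tokenised sentences.
//
// sentences: list of integer vectors of 0-based token ids (invalid k-mers
//            already removed upstream); counts: per-id corpus frequency.
// Single-threaded SGD; reduced (sampled) context window as in word2vec;
// negatives drawn from the unigram distribution raised to 3/4.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha, double min_alpha, int seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  if (dim <= 0 || window <= 0 || epochs <= 0) stop("dim, window and epochs must be positive");

  const int V = vocab_size;
  uint64_t state = static_cast<uint64_t>(seed) * 2654435761ULL + 88172645463325252ULL;
  if (state == 0) state = 1;

  // cumulative table for negative sampling, unigram^0.75
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int i = 0; i < V; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }

  sig_init();
  std::vector<float> syn0(static_cast<size_t>(V) * dim);
  std::vector<float> syn1(static_cast<size_t>(V) * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = static_cast<float>((rng_unif(state) - 0.5) / dim);

  long long total_tokens = 0;
  const int n_sent = sentences.size();
  for (int s = 0; s < n_sent; ++s)
    total_tokens += static_cast<IntegerVector>(sentences[s]).size();
  if (total_tokens == 0) stop("empty vocabulary");
  const double span = static_cast<double>(total_tokens) * epochs;

  std::vector<float> grad(dim);
  long long seen = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int pos = 0; pos < n; ++pos) {
        ++seen;
        double lr = alpha - (alpha - min_alpha) * (seen - 1) / span;
        const int center = sent[pos];
        const int b = 1 + static_cast<int>(rng_next(state) % window);
        const int lo = std::max(0, pos - b), hi = std::min(n - 1, pos + b);
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          const int ctx = sent[cpos];
          float *vin = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double u = rng_unif(state) * tot;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= V) target = V - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            float *vout = &syn1[static_cast<size_t>(target) * dim];
            float dot = 0.0f;
            for (int j = 0; j < dim; ++j) dot += vin[j] * vout[j];
            const float g = static_cast<float>((label - sigmoid(dot)) * lr);
            for (int j = 0; j < dim; ++j) {
              grad[j] += g * vout[j];
              vout[j] += g * vin[j];
            }
          }
          for (int j = 0; j < dim; ++j) vin[j] += grad[j];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < dim; ++j)
      out(i, j) = syn0[static_cast<size_t>(i) * dim + j];
  return out;
}
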