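#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Self-contained PCG32 generator: keeps the sampler bit-reproducible for a
// given integer seed independently of R's RNG state and platform.
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() {  // in [0, 1)
    return next() * 2.3283064365386963e-10;  // 2^-32
  }
};

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// doc, word: 0-based parallel vectors, one entry per token occurrence.
// Returns topic-term (phi, K x V) and doc-topic (theta, D x K) estimates
// averaged over the post-burn-in sweeps.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab, int K,
                   double alpha, double eta,
                   int n_iter, int burnin, double seed) {
  const int N = doc.size();
  if (K < 1) stop("K must be >= 1");
  if (n_iter < 1) stop("n_iter must be >= 1");
  if (burnin >= n_iter) burnin = n_iter - 1;

  std::vector<int> z(N);
  std::vector<int> ndk((size_t)n_docs * K, 0);
  std::vector<int> nkw((size_t)K * n_vocab, 0);
  std::vector<int> nk(K, 0);

  Pcg32 rng((uint64_t)seed);

  for (int t = 0; t < N; ++t) {
    int k = (int)(rng.unif() * K);
    if (k >= K) k = K - 1;
    z[t] = k;
    ndk[(size_t)doc[t] * K + k]++;
    nkw[(size_t)k * n_vocab + word[t]]++;
    nk[k]++;
  }

  std::vector<double> phi_sum((size_t)K * n_vocab, 0.0);
  std::vector<double> theta_sum((size_t)n_docs * K, 0.0);
  std::vector<double> p(K);
  const double Veta = n_vocab * eta;
  int n_avg = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < N; ++t) {
      const int d = doc[t], w = word[t], kold = z[t];
      ndk[(size_t)d * K + kold]--;
      nkw[(size_t)kold * n_vocab + w]--;
      nk[kold]--;

      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (ndk[(size_t)d * K + k] + alpha) *
               (nkw[(size_t)k * n_vocab + w] + eta) / (nk[k] + Veta);
        p[k] = tot;
      }
      const double u = rng.unif() * tot;
      int knew = 0;
      while (knew < K - 1 && p[knew] <= u) ++knew;

      z[t] = knew;
      ndk[(size_t)d * K + knew]++;
      nkw[(size_t)knew * n_vocab + w]++;
      nk[knew]++;
    }
    if (it >= burnin) {
      ++n_avg;
      for (int k = 0; k < K; ++k) {
        const double denom = nk[k] + Veta;
        for (int w = 0; w < n_vocab; ++w)
          phi_sum[(size_t)k * n_vocab + w] +=
            (nkw[(size_t)k * n_vocab + w] + eta) / denom;
      }
      for (int d = 0; d < n_docs; ++d) {
        int nd = 0;
        for (int k = 0; k < K; ++k) nd += ndk[(size_t)d * K + k];
        const double denom = nd + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_sum[(size_t)d * K + k] +=
            (ndk[(size_t)d * K + k] + alpha) / denom;
      }
    }
  }

  NumericMatrix phi(K, n_vocab), theta(n_docs, K);
  for (int k = 0; k < K; ++k) {
    double rowsum = 0.0;
    for (int w = 0; w < n_vocab; ++w) rowsum += phi_sum[(size_t)k * n_vocab + w];
    for (int w = 0; w < n_vocab; ++w)
      phi(k, w) = phi_sum[(size_t)k * n_vocab + w] / rowsum;
  }
  for (int d = 0; d < n_docs; ++d) {
    double rowsum = 0.0;
    for (int k = 0; k < K; ++k) rowsum += theta_sum[(size_t)d * K + k];
    for (int k = 0; k < K; ++k)
      theta(d, k) = theta_sum[(size_t)d * K + k] / rowsum;
  }
  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["n_averaged"] = n_avg);
}
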