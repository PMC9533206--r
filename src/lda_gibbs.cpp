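#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained xorshift64* generator so fits are bit-identical for a given
// seed regardless of R's RNG state or platform.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s * 2685821657736338717ULL;
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

// Collapsed Gibbs sampler for LDA. doc and word are 0-based per-token
// (occurrence-expanded) indices. Returns final-sample count matrices.
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int n_doc,
                   int n_vocab, int K, double alpha, double beta,
                   int n_iter, double seed) {
  const int N = doc.size();
  if (N == 0) stop("empty corpus");
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K exceeds the total token count");

  uint64_t state = (uint64_t)seed * 2862933555777941757ULL + 3037000493ULL;
  if (state == 0) state = 88172645463325252ULL;
  for (int i = 0; i < 16; ++i) xorshift64(state); // warm up

  IntegerVector z(N);
  IntegerMatrix ndk(n_doc, K);   // doc-topic counts
  IntegerMatrix nkw(K, n_vocab); // topic-word counts
  IntegerVector nk(K);           // topic totals

  for (int i = 0; i < N; ++i) {
    int t = (int)(runif01(state) * K);
    if (t >= K) t = K - 1;
    z[i] = t;
    ndk(doc[i], t)++;
    nkw(t, word[i])++;
    nk[t]++;
  }

  const double vbeta = n_vocab * beta;
  std::vector<double> p(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int t = z[i];
      ndk(d, t)--; nkw(t, w)--; nk[t]--;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        total += (ndk(d, kk) + alpha) * (nkw(kk, w) + beta) / (nk[kk] + vbeta);
        p[kk] = total;
      }
      const double u = runif01(state) * total;
      int tnew = 0;
      while (tnew < K - 1 && p[tnew] < u) ++tnew;
      z[i] = tnew;
      ndk(d, tnew)++; nkw(tnew, w)++; nk[tnew]++;
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["z"] = z, _["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = nk);
}
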