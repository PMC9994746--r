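// Subword-aware skip-gram with negative sampling, single-threaded and
// deterministic under a caller-supplied seed. Words are represented as the
// mean of one per-word input vector and hashed character n-gram bucket
// vectors, so out-of-vocabulary tokens remain embeddable at inference time.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// FNV-1a 32-bit, the hash fastText uses for n-gram bucketing.
static uint32_t fnv1a(const std::string& s) {
  uint32_t h = 2166136261u;
  for (unsigned char c : s) {
    h ^= c;
    h *= 16777619u;
  }
  return h;
}

// [[Rcpp::export]]
IntegerVector cpp_subword_ids(std::string word, int minn, int maxn, int nbuckets) {
  std::string w = "<" + word + ">";
  std::vector<int> ids;
  int len = (int)w.size();
  for (int n = minn; n <= maxn; ++n) {
    for (int i = 0; i + n <= len; ++i) {
      // skip the full bracketed word only when it equals the whole token and
      // spans every n: fastText keeps it; we keep it too (no skip).
      ids.push_back((int)(fnv1a(w.substr(i, n)) % (uint32_t)nbuckets));
    }
  }
  return wrap(ids);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ull) {}
  uint64_t next() {  // xorshift64*
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1Dull;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sentences: list of integer vectors of 0-based vocab ids (OOV already
// dropped); subwords: per vocab word, 0-based bucket ids; counts: vocab
// frequencies for the unigram^0.75 negative-sampling table.
// [[Rcpp::export]]
List cpp_sgns_train(List sentences, IntegerVector counts, List subwords,
                    int dim, int nbuckets, int window, int negative,
                    int epochs, double lr0, double sample_t, int seed) {
  const int V = counts.size();
  if (V == 0) stop("empty vocabulary");
  Rng rng((uint64_t)seed * 6364136223846793005ull + 1442695040888963407ull);

  // input vectors: per-word plus shared n-gram buckets; output vectors per word
  std::vector<double> win((size_t)V * dim), wbuck((size_t)nbuckets * dim),
      wout((size_t)V * dim, 0.0);
  for (auto& x : win) x = (rng.unif() - 0.5) / dim;
  for (auto& x : wbuck) x = (rng.unif() - 0.5) / dim;

  // cumulative unigram^0.75 table sampled by binary search
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int i = 0; i < V; ++i) {
    tot += std::pow((double)counts[i], 0.75);
    cum[i] = tot;
  }

  // cache subword id lists
  std::vector<std::vector<int>> sub(V);
  for (int i = 0; i < V; ++i) sub[i] = as<std::vector<int>>(subwords[i]);

  long long total_tokens = 0;
  const int S = sentences.size();
  std::vector<std::vector<int>> sent(S);
  for (int i = 0; i < S; ++i) {
    sent[i] = as<std::vector<int>>(sentences[i]);
    total_tokens += (long long)sent[i].size();
  }
  if (total_tokens == 0) stop("no trainable tokens");
  const long long planned = total_tokens * epochs;

  // word2vec-style frequent-word subsampling: keep probability per token
  std::vector<double> keep_p(V, 1.0);
  if (sample_t > 0) {
    for (int i = 0; i < V; ++i) {
      double f = (double)counts[i] / (double)total_tokens;
      double p = std::sqrt(sample_t / f) + sample_t / f;
      keep_p[i] = p < 1.0 ? p : 1.0;
    }
  }

  std::vector<double> h(dim), e(dim);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < S; ++si) {
      std::vector<int> s;
      s.reserve(sent[si].size());
      for (int w : sent[si]) {
        if (keep_p[w] >= 1.0 || rng.unif() < keep_p[w]) s.push_back(w);
      }
      const int n = (int)s.size();
      for (int c = 0; c < n; ++c, ++done) {
        double lr = lr0 * (1.0 - (double)done / (double)(planned + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        const int w = s[c];
        const std::vector<int>& gw = sub[w];
        const double inv = 1.0 / (1.0 + (double)gw.size());
        // composed input representation of the center word
        for (int d = 0; d < dim; ++d) h[d] = win[(size_t)w * dim + d];
        for (int g : gw)
          for (int d = 0; d < dim; ++d) h[d] += wbuck[(size_t)g * dim + d];
        for (int d = 0; d < dim; ++d) h[d] *= inv;

        const int b = rng.below(window);  // dynamic window, word2vec-style
        for (int off = -(window - b); off <= window - b; ++off) {
          if (off == 0) continue;
          const int pos = c + off;
          if (pos < 0 || pos >= n) continue;
          const int ctx = s[pos];
          std::fill(e.begin(), e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double u = rng.unif() * tot;
              int lo = 0, hi = V - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (cum[mid] < u) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* u_t = &wout[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += h[d] * u_t[d];
            const double g = lr * (label - sigmoid(f));
            for (int d = 0; d < dim; ++d) {
              e[d] += g * u_t[d];
              u_t[d] += g * h[d];
            }
          }
          // distribute the accumulated input gradient across constituents
          double* v_w = &win[(size_t)w * dim];
          for (int d = 0; d < dim; ++d) v_w[d] += e[d] * inv;
          for (int g : gw) {
            double* z = &wbuck[(size_t)g * dim];
            for (int d = 0; d < dim; ++d) z[d] += e[d] * inv;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix word(V, dim), bucket(nbuckets, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) word(i, d) = win[(size_t)i * dim + d];
  for (int i = 0; i < nbuckets; ++i)
    for (int d = 0; d < dim; ++d) bucket(i, d) = wbuck[(size_t)i * dim + d];
  return List::create(_["word"] = word, _["bucket"] = bucket,
                      _["tokens_trained"] = (double)planned);
}
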