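#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Pairwise counts of epitope sets recognized by both alleles of a pair.
// Patterns are bit-packed into 64-bit words so the k*(k+1)/2 pair counts
// reduce to AND + popcount over ls/64 words per pair.
// [[Rcpp::export]]
IntegerMatrix pattern_intersect_counts(LogicalMatrix patterns) {
  const int k = patterns.nrow();
  const int ls = patterns.ncol();
  if (k < 1 || ls < 1) stop("patterns must be a non-empty matrix");
  const int nw = (ls + 63) / 64;
  std::vector<uint64_t> bits((size_t)k * nw, 0ULL);
  const int* pd = LOGICAL(patterns);
  for (int j = 0; j < ls; ++j) {
    const int* col = pd + (size_t)j * k;
    const uint64_t bit = 1ULL << (j & 63);
    const int w = j >> 6;
    for (int i = 0; i < k; ++i)
      if (col[i]) bits[(size_t)i * nw + w] |= bit;
  }
  IntegerMatrix out(k, k);
  for (int i = 0; i < k; ++i) {
    const uint64_t* bi = bits.data() + (size_t)i * nw;
    for (int j = i; j < k; ++j) {
      const uint64_t* bj = bits.data() + (size_t)j * nw;
      long long c = 0;
      for (int w = 0; w < nw; ++w)
        c += __builtin_popcountll(bi[w] & bj[w]);
      out(i, j) = (int)c;
      out(j, i) = (int)c;
    }
  }
  return out;
}

// xoshiro256++ with splitmix64 seeding: a fast local generator for the
// subset sampling below.  It is seeded from R's RNG, so set.seed() still
// fully determines the draw, but the hot loop avoids the per-call overhead
// of the R RNG API.
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform integer in [0, n) by Lemire's multiply-shift with rejection
  uint32_t bounded(uint32_t n) {
    uint64_t x = next() & 0xFFFFFFFFULL;
    uint64_t m = x * n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      uint32_t t = (uint32_t)(-(int32_t)n) % n;
      while (l < t) {
        x = next() & 0xFFFFFFFFULL;
        m = x * n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }
};
}

// Sample one uniform random m[i]-subset of ls sites per allele (partial
// Fisher-Yates over the site indices), bit-pack the patterns and return the
// pairwise counts of sites recognized by both alleles.  Equivalent to
// sample_patterns() followed by pattern_intersect_counts(), but never
// materializes the k x ls matrix; used on the simulation fast path where
// ls can reach 1e5.
// [[Rcpp::export]]
IntegerMatrix sampled_intersect_counts(IntegerVector m, int ls) {
  const int k = m.size();
  if (k < 1 || ls < 1) stop("need at least one allele and one site");
  const int nw = (ls + 63) / 64;
  // derive a 64-bit stream seed from R's RNG
  const uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  const uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  Xoshiro rng((hi << 32) ^ lo);
  std::vector<uint64_t> bits((size_t)k * nw, 0ULL);
  std::vector<int> perm(ls);
  for (int i = 0; i < k; ++i) {
    const int mi = m[i];
    if (mi < 0 || mi > ls) stop("site counts must lie in [0, ls]");
    for (int j = 0; j < ls; ++j) perm[j] = j;
    uint64_t* bi = bits.data() + (size_t)i * nw;
    for (int j = 0; j < mi; ++j) {
      int r = j + (int)rng.bounded((uint32_t)(ls - j));
      std::swap(perm[j], perm[r]);
      const int s = perm[j];
      bi[s >> 6] |= 1ULL << (s & 63);
    }
  }
  IntegerMatrix out(k, k);
  for (int i = 0; i < k; ++i) {
    const uint64_t* bi = bits.data() + (size_t)i * nw;
    for (int j = i; j < k; ++j) {
      const uint64_t* bj = bits.data() + (size_t)j * nw;
      long long c = 0;
      for (int w = 0; w < nw; ++w)
        c += __builtin_popcountll(bi[w] & bj[w]);
      out(i, j) = (int)c;
      out(j, i) = (int)c;
    }
  }
  return out;
}

// Discrete-generation viability dynamics p_i' = p_i * (F p)_i / (p' F p),
// iterated until the marginal fitnesses of all non-vanishing alleles agree
// with the population fitness within tol.  Alleles whose proportion is
// below vanish_tol and still decreasing are treated as vanishing: at a
// boundary equilibrium their marginal-fitness gap closes only algebraically,
// so they would otherwise stall the spread criterion forever.
// [[Rcpp::export]]
List iterate_dynamics_cpp(NumericMatrix F, NumericVector p0, double tol,
                          double max_steps, double prune, double vanish_tol,
                          int check_every) {
  const int k = F.nrow();
  if (F.ncol() != k || p0.size() != k) stop("dimension mismatch");
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> wm(k), pprev(p);
  bool converged = false, wbar_monotone = true;
  double wbar = 0.0, wbar_last = -1.0;
  double steps = 0.0;
  int since_check = 0;
  std::vector<int> vanishing(k, 0);

  while (steps < max_steps) {
    // marginal fitnesses wm = F p and population fitness wbar = p . wm
    wbar = 0.0;
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      const double* col = &F(0, i);  // symmetric: column i == row i
      for (int j = 0; j < k; ++j) s += col[j] * p[j];
      wm[i] = s;
      wbar += p[i] * s;
    }
    if (!(wbar > 0.0))
      return List::create(_["proportions"] = NumericVector(p.begin(), p.end()),
                          _["marginal"] = NumericVector(wm.begin(), wm.end()),
                          _["population_fitness"] = wbar,
                          _["steps"] = steps, _["converged"] = false,
                          _["wbar_monotone"] = wbar_monotone,
                          _["vanishing"] = LogicalVector(vanishing.begin(), vanishing.end()),
                          _["error"] = "population fitness reached zero");
    if (wbar_last >= 0.0 && wbar < wbar_last - 1e-13) wbar_monotone = false;
    wbar_last = wbar;

    if (since_check == 0) {
      double spread = 0.0;
      for (int i = 0; i < k; ++i) {
        vanishing[i] = (p[i] <= 0.0) ||
                       (p[i] < vanish_tol && p[i] < pprev[i]);
        if (!vanishing[i]) {
          double d = std::fabs(wm[i] - wbar);
          if (d > spread) spread = d;
        }
      }
      if (spread < tol && steps > 0.0) { converged = true; break; }
      pprev = p;
    }

    // one generation
    double tot = 0.0;
    for (int i = 0; i < k; ++i) {
      p[i] *= wm[i] / wbar;
      if (p[i] < prune) p[i] = 0.0;
      tot += p[i];
    }
    if (tot <= 0.0)
      return List::create(_["proportions"] = NumericVector(p.begin(), p.end()),
                          _["marginal"] = NumericVector(wm.begin(), wm.end()),
                          _["population_fitness"] = wbar,
                          _["steps"] = steps + 1.0, _["converged"] = false,
                          _["wbar_monotone"] = wbar_monotone,
                          _["vanishing"] = LogicalVector(vanishing.begin(), vanishing.end()),
                          _["error"] = "all alleles pruned");
    for (int i = 0; i < k; ++i) p[i] /= tot;
    steps += 1.0;
    if (++since_check >= check_every) since_check = 0;
  }

  return List::create(_["proportions"] = NumericVector(p.begin(), p.end()),
                      _["marginal"] = NumericVector(wm.begin(), wm.end()),
                      _["population_fitness"] = wbar,
                      _["steps"] = steps, _["converged"] = converged,
                      _["wbar_monotone"] = wbar_monotone,
                      _["vanishing"] = LogicalVector(vanishing.begin(), vanishing.end()),
                      _["error"] = R_NilValue);
}
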