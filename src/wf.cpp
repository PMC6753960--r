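#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Haplotypes are raw 0/1 vectors, sites in rows, one column per haplotype
// (two consecutive columns per diploid individual). All randomness comes
// from R's RNG so set.seed() governs every draw.

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Draw k distinct values in [0, n); positions of Bernoulli successes given
// their binomial count. Falls back to a per-element sweep when dense.
static void sample_positions(int k, int n, std::vector<int>& out) {
  out.clear();
  if (k <= 0) return;
  if (k > n / 16) {
    // dense: Fisher-Yates over an index vector would allocate n; instead use
    // sequential selection (exact conditional Bernoulli)
    int remaining = k;
    for (int i = 0; i < n && remaining > 0; ++i) {
      if (unif_rand() * (n - i) < remaining) {
        out.push_back(i);
        --remaining;
      }
    }
  } else {
    std::unordered_set<int> seen;
    while ((int)seen.size() < k) {
      int p = runif_int(n);
      if (seen.insert(p).second) out.push_back(p);
    }
    std::sort(out.begin(), out.end());
  }
}

// One gamete: start on a uniformly chosen parental strand, switch strands
// independently with probability rec at each of the L-1 inter-site
// boundaries, then flip each site independently with probability mu.
static void gamete_into(const Rbyte* h1, const Rbyte* h2, int L,
                        double mu, double rec, Rbyte* out,
                        std::vector<int>& scratch) {
  const Rbyte* cur = unif_rand() < 0.5 ? h1 : h2;
  const Rbyte* oth = (cur == h1) ? h2 : h1;
  int k = (rec <= 0.0 || L < 2) ? 0 : (int)R::rbinom((double)(L - 1), rec);
  if (k == 0) {
    std::memcpy(out, cur, (size_t)L);
  } else {
    sample_positions(k, L - 1, scratch);
    int pos = 0;
    for (int i = 0; i < k; ++i) {
      int cut = scratch[i] + 1;  // first site of the following segment
      std::memcpy(out + pos, cur + pos, (size_t)(cut - pos));
      pos = cut;
      std::swap(cur, oth);
    }
    std::memcpy(out + pos, cur + pos, (size_t)(L - pos));
  }
  if (mu > 0.0) {
    int m = (int)R::rbinom((double)L, mu);
    if (m > 0) {
      sample_positions(m, L, scratch);
      for (int i = 0; i < m; ++i) out[scratch[i]] ^= 1;
    }
  }
}

// [[Rcpp::export]]
RawVector meiosis_cpp(RawVector h1, RawVector h2, double mu, double rec) {
  int L = h1.size();
  if (h2.size() != L) stop("parental haplotypes differ in length");
  RawVector out(L);
  std::vector<int> scratch;
  gamete_into(h1.begin(), h2.begin(), L, mu, rec, out.begin(), scratch);
  return out;
}

// Evolve one randomly mating deme for `generations` discrete generations of
// Wright-Fisher reproduction at constant size (monoecious, selfing allowed).
// [[Rcpp::export]]
RawMatrix wf_evolve_cpp(RawMatrix pop, int generations, double mu, double rec) {
  int L = pop.nrow(), H = pop.ncol();
  if (H % 2) stop("haplotype count must be even");
  int N = H / 2;
  if (N < 1) stop("empty population");
  if (generations <= 0) return pop;
  std::vector<Rbyte> cur(pop.begin(), pop.end()), nxt((size_t)L * H);
  std::vector<int> scratch;
  for (int g = 0; g < generations; ++g) {
    for (int j = 0; j < N; ++j) {
      int p1 = runif_int(N), p2 = runif_int(N);
      gamete_into(&cur[(size_t)L * (2 * p1)], &cur[(size_t)L * (2 * p1 + 1)],
                  L, mu, rec, &nxt[(size_t)L * (2 * j)], scratch);
      gamete_into(&cur[(size_t)L * (2 * p2)], &cur[(size_t)L * (2 * p2 + 1)],
                  L, mu, rec, &nxt[(size_t)L * (2 * j + 1)], scratch);
    }
    cur.swap(nxt);
    if ((g & 63) == 0) Rcpp::checkUserInterrupt();
  }
  RawMatrix outm(L, H);
  std::copy(cur.begin(), cur.end(), outm.begin());
  return outm;
}

// Derived-allele copy count per site.
// [[Rcpp::export]]
IntegerVector site_counts_cpp(RawMatrix pop) {
  int L = pop.nrow(), H = pop.ncol();
  IntegerVector out(L);
  int* o = out.begin();
  for (int j = 0; j < H; ++j) {
    const Rbyte* col = pop.begin() + (size_t)L * j;
    for (int i = 0; i < L; ++i) o[i] += col[i];
  }
  return out;
}

// 5-bit haplotype codes per window of five consecutive sites; the leftmost
// (lowest-coordinate) site is the most significant bit.
// [[Rcpp::export]]
IntegerMatrix encode_windows_cpp(RawMatrix pop) {
  int L = pop.nrow(), H = pop.ncol();
  if (L % 5) stop("sequence length not divisible by 5");
  int W = L / 5;
  IntegerMatrix out(W, H);
  for (int j = 0; j < H; ++j) {
    const Rbyte* col = pop.begin() + (size_t)L * j;
    int* oc = &out(0, j);
    for (int w = 0; w < W; ++w) {
      const Rbyte* s = col + 5 * w;
      oc[w] = (s[0] << 4) | (s[1] << 3) | (s[2] << 2) | (s[3] << 1) | s[4];
    }
  }
  return out;
}
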