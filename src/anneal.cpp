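#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Contribution/mating/migration plans are stored slot-wise: D destination
// demes times N offspring slots, slot s lives in destination deme s / N.
// Each slot carries (natal deme, sire, dam); parents are row indices into
// the genotype matrices. All indices 0-based internally, 1-based at the R
// boundary. Objective evaluation is a full recompute per proposal; plans
// are small (D*N slots) so copying dominates nothing.

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Ctx {
  int np, L, D, N, M;            // parents, managed loci, demes, deme size, migrants
  const int *a1, *a2;            // np x L allele codes, column-major
  std::vector<std::vector<int> > males, females;  // per deme
  int method;                    // 0 = maxHT, 1 = maxAT, 2 = maxK
  double lambda;
  std::vector<double> pw;        // pw[g] = 0.5^g
  std::vector<unsigned char> present;  // 32 x L: allele present among parents
  // scratch buffers
  std::vector<double> acc;       // D x 32 x L frequency or loss array
  std::vector<int> gam;          // per-parent gamete counts (one deme at a time)
  std::vector<int> touched;
  std::vector<int> slots_a, slots_b;   // move scratch
};

static inline int code1(const Ctx& c, int k, int l) { return c.a1[k + (size_t)l * c.np]; }
static inline int code2(const Ctx& c, int k, int l) { return c.a2[k + (size_t)l * c.np]; }

// Expected progeny allele frequencies per destination deme, then the Nei
// partition on them: score = D_G + lambda * H_S, averaged over loci.
static double eval_ht(Ctx& c, const int* natal, const int* sire, const int* dam) {
  (void)natal;
  std::fill(c.acc.begin(), c.acc.end(), 0.0);
  double norm = 1.0 / (2.0 * c.N);
  for (int d = 0; d < c.D; ++d) {
    double* pd = &c.acc[(size_t)d * 32 * c.L];
    for (int s = 0; s < c.N; ++s) {
      int idx = d * c.N + s;
      int par[2] = { sire[idx], dam[idx] };
      for (int t = 0; t < 2; ++t) {
        int k = par[t];
        for (int l = 0; l < c.L; ++l) {
          double* pl = pd + (size_t)l * 32;
          pl[code1(c, k, l)] += 0.5;
          pl[code2(c, k, l)] += 0.5;
        }
      }
    }
  }
  double score = 0.0;
  for (int l = 0; l < c.L; ++l) {
    double hs = 0.0, dg = 0.0;
    double s1[32], mp2[32];
    std::memset(s1, 0, sizeof s1);
    std::memset(mp2, 0, sizeof mp2);
    for (int d = 0; d < c.D; ++d) {
      const double* pl = &c.acc[((size_t)d * c.L + l) * 32];
      double sq = 0.0;
      for (int a = 0; a < 32; ++a) {
        double v = pl[a] * norm;
        sq += v * v;
        s1[a] += v;
        mp2[a] += v * v;
      }
      hs += 1.0 - sq;
    }
    hs /= c.D;
    for (int a = 0; a < 32; ++a) {
      double m1 = s1[a] / c.D;
      dg += mp2[a] / c.D - m1 * m1;
    }
    score += dg + c.lambda * hs;
  }
  return score / c.L;
}

// Per-allele loss probabilities under independent Mendelian transmission:
// fill c.acc with P_loss(deme, locus, allele).
static void fill_loss(Ctx& c, const int* natal, const int* sire, const int* dam) {
  (void)natal;
  std::fill(c.acc.begin(), c.acc.end(), 1.0);
  for (int d = 0; d < c.D; ++d) {
    double* ld = &c.acc[(size_t)d * 32 * c.L];
    c.touched.clear();
    for (int s = 0; s < c.N; ++s) {
      int idx = d * c.N + s;
      int par[2] = { sire[idx], dam[idx] };
      for (int t = 0; t < 2; ++t) {
        if (c.gam[par[t]]++ == 0) c.touched.push_back(par[t]);
      }
    }
    for (size_t i = 0; i < c.touched.size(); ++i) {
      int k = c.touched[i];
      int g = c.gam[k];
      double w = c.pw[g];
      for (int l = 0; l < c.L; ++l) {
        double* ll = ld + (size_t)l * 32;
        int u = code1(c, k, l), v = code2(c, k, l);
        if (u == v) {
          ll[u] = 0.0;  // homozygous carrier always transmits the allele
        } else {
          ll[u] *= w;
          ll[v] *= w;
        }
      }
      c.gam[k] = 0;
    }
  }
}

// Expected allelic partition from retention probabilities R = 1 - P_loss:
// score = E[D_A] + lambda * E[A_S], averaged over loci.
static double eval_at(Ctx& c, const int* natal, const int* sire, const int* dam) {
  fill_loss(c, natal, sire, dam);
  double as_sum = 0.0;
  for (int d = 0; d < c.D; ++d) {
    const double* ld = &c.acc[(size_t)d * 32 * c.L];
    for (size_t i = 0; i < (size_t)32 * c.L; ++i) as_sum += 1.0 - ld[i];
  }
  double A_S = as_sum / c.D / c.L - 1.0;
  double D_A = 0.0;
  if (c.D > 1) {
    double da_sum = 0.0;
    for (int i = 0; i < c.D; ++i) {
      const double* li = &c.acc[(size_t)i * 32 * c.L];
      for (int j = i + 1; j < c.D; ++j) {
        const double* lj = &c.acc[(size_t)j * 32 * c.L];
        for (size_t t = 0; t < (size_t)32 * c.L; ++t) {
          double Ri = 1.0 - li[t], Rj = 1.0 - lj[t];
          da_sum += 0.5 * (Ri * (1.0 - Rj) + Rj * (1.0 - Ri));
        }
      }
    }
    int npairs = c.D * (c.D - 1) / 2;
    D_A = da_sum / npairs / c.L;
  }
  return D_A + c.lambda * A_S;
}

// maxK: minimise the expected number of global allele losses, i.e. maximise
// -sum over (locus, allele present in parents) of prod over demes P_loss.
static double eval_k(Ctx& c, const int* natal, const int* sire, const int* dam) {
  fill_loss(c, natal, sire, dam);
  double score = 0.0;
  for (int l = 0; l < c.L; ++l) {
    for (int a = 0; a < 32; ++a) {
      if (!c.present[a + 32 * l]) continue;
      double prod = 1.0;
      for (int d = 0; d < c.D; ++d)
        prod *= c.acc[((size_t)d * c.L + l) * 32 + a];
      score -= prod;
    }
  }
  return score;
}

static double eval_plan(Ctx& c, const int* natal, const int* sire, const int* dam) {
  switch (c.method) {
  case 0: return eval_ht(c, natal, sire, dam);
  case 1: return eval_at(c, natal, sire, dam);
  default: return eval_k(c, natal, sire, dam);
  }
}

// One elementary plan move, feasibility-preserving (per-destination totals,
// within-deme matings, fixed total migrant count). Returns false if no
// feasible move was found within the attempt budget.
static bool do_move(Ctx& c, int* natal, int* sire, int* dam) {
  int total = c.D * c.N;
  for (int attempt = 0; attempt < 40; ++attempt) {
    switch (runif_int(5)) {
    case 0: {  // slot adopts another mating with the same destination
      if (c.N < 2) break;
      int d = runif_int(c.D);
      int i = runif_int(c.N), j = runif_int(c.N);
      if (i == j) break;
      int ii = d * c.N + i, jj = d * c.N + j;
      if ((natal[ii] != d) != (natal[jj] != d)) break;  // keep migrant status
      if (natal[ii] == natal[jj] && sire[ii] == sire[jj] && dam[ii] == dam[jj]) break;
      natal[ii] = natal[jj]; sire[ii] = sire[jj]; dam[ii] = dam[jj];
      return true;
    }
    case 1: {  // replace one parent of a mating within its natal deme
      int ii = runif_int(total);
      int nd = natal[ii];
      if (unif_rand() < 0.5) {
        const std::vector<int>& m = c.males[nd];
        int k = m[runif_int((int)m.size())];
        if (k == sire[ii]) break;
        sire[ii] = k;
      } else {
        const std::vector<int>& f = c.females[nd];
        int k = f[runif_int((int)f.size())];
        if (k == dam[ii]) break;
        dam[ii] = k;
      }
      return true;
    }
    case 2: {  // swap the destinations of two offspring (migrant-preserving)
      if (c.D < 2) break;
      int d1 = runif_int(c.D), d2 = runif_int(c.D);
      if (d1 == d2) break;
      int i = d1 * c.N + runif_int(c.N), j = d2 * c.N + runif_int(c.N);
      int before = (natal[i] != d1) + (natal[j] != d2);
      int after  = (natal[i] != d2) + (natal[j] != d1);
      if (before != after) break;
      std::swap(natal[i], natal[j]);
      std::swap(sire[i], sire[j]);
      std::swap(dam[i], dam[j]);
      return true;
    }
    case 3: {  // re-source one migrant from a different natal deme
      if (c.M == 0 || c.D < 2) break;
      c.slots_a.clear();
      for (int s = 0; s < total; ++s)
        if (natal[s] != s / c.N) c.slots_a.push_back(s);
      if (c.slots_a.empty()) break;
      int s = c.slots_a[runif_int((int)c.slots_a.size())];
      int d = s / c.N;
      int nd = runif_int(c.D - 1);
      if (nd >= d) ++nd;
      natal[s] = nd;
      sire[s] = c.males[nd][runif_int((int)c.males[nd].size())];
      dam[s]  = c.females[nd][runif_int((int)c.females[nd].size())];
      return true;
    }
    default: {  // relocate migration: demote one migrant, promote a resident
      if (c.M == 0 || c.D < 2) break;
      c.slots_a.clear();
      c.slots_b.clear();
      for (int s = 0; s < total; ++s) {
        if (natal[s] != s / c.N) c.slots_a.push_back(s);
        else c.slots_b.push_back(s);
      }
      if (c.slots_a.empty() || c.slots_b.empty()) break;
      int s1 = c.slots_a[runif_int((int)c.slots_a.size())];
      int s2 = c.slots_b[runif_int((int)c.slots_b.size())];
      int d1 = s1 / c.N, d2 = s2 / c.N;
      natal[s1] = d1;  // becomes a resident of its destination
      sire[s1] = c.males[d1][runif_int((int)c.males[d1].size())];
      dam[s1]  = c.females[d1][runif_int((int)c.females[d1].size())];
      int nd = runif_int(c.D - 1);
      if (nd >= d2) ++nd;
      natal[s2] = nd;  // becomes a migrant into its destination
      sire[s2] = c.males[nd][runif_int((int)c.males[nd].size())];
      dam[s2]  = c.females[nd][runif_int((int)c.females[nd].size())];
      return true;
    }
    }
  }
  return false;
}

static Ctx make_ctx(IntegerMatrix a1, IntegerMatrix a2, IntegerVector deme,
                    LogicalVector female, int N, int M,
                    std::string method, double lambda) {
  Ctx c;
  c.np = a1.nrow();
  c.L = a1.ncol();
  if (a2.nrow() != c.np || a2.ncol() != c.L) stop("genotype matrices disagree");
  if (deme.size() != c.np || female.size() != c.np) stop("parent labels disagree");
  c.D = 0;
  for (int k = 0; k < c.np; ++k) c.D = std::max(c.D, deme[k]);
  c.N = N;
  c.M = M;
  c.a1 = a1.begin();
  c.a2 = a2.begin();
  c.males.assign(c.D, std::vector<int>());
  c.females.assign(c.D, std::vector<int>());
  for (int k = 0; k < c.np; ++k) {
    int d = deme[k] - 1;
    if (d < 0) stop("deme labels must be positive");
    if (female[k]) c.females[d].push_back(k);
    else c.males[d].push_back(k);
  }
  for (int d = 0; d < c.D; ++d)
    if (c.males[d].empty() || c.females[d].empty())
      stop("every deme needs at least one parent of each sex");
  if (method == "maxHT") c.method = 0;
  else if (method == "maxAT") c.method = 1;
  else if (method == "maxK") c.method = 2;
  else stop("unknown objective method '%s'", method.c_str());
  c.lambda = lambda;
  int gmax = 2 * c.N * c.D + 1;
  c.pw.resize(gmax + 1);
  c.pw[0] = 1.0;
  for (int g = 1; g <= gmax; ++g) c.pw[g] = c.pw[g - 1] * 0.5;
  c.present.assign((size_t)32 * c.L, 0);
  for (int l = 0; l < c.L; ++l)
    for (int k = 0; k < c.np; ++k) {
      int u = code1(c, k, l), v = code2(c, k, l);
      if (u < 0 || u > 31 || v < 0 || v > 31) stop("allele codes must lie in 0..31");
      c.present[u + 32 * l] = 1;
      c.present[v + 32 * l] = 1;
    }
  c.acc.assign((size_t)c.D * 32 * c.L, 0.0);
  c.gam.assign(c.np, 0);
  return c;
}

static void check_plan(const Ctx& c, const IntegerVector& natal,
                       const IntegerVector& sire, const IntegerVector& dam) {
  int total = c.D * c.N;
  if (natal.size() != total || sire.size() != total || dam.size() != total)
    stop("plan must have n_demes * deme_size slots");
  int mig = 0;
  for (int s = 0; s < total; ++s) {
    int nd = natal[s] - 1;
    if (nd < 0 || nd >= c.D) stop("natal deme out of range");
    if (nd != s / c.N) ++mig;
  }
  if (mig != c.M) stop("plan carries %d migrants, budget is %d", mig, c.M);
}

// [[Rcpp::export]]
double plan_score_cpp(IntegerMatrix a1, IntegerMatrix a2, IntegerVector deme,
                      LogicalVector female, int N, int M, std::string method,
                      double lambda, IntegerVector natal, IntegerVector sire,
                      IntegerVector dam) {
  Ctx c = make_ctx(a1, a2, deme, female, N, M, method, lambda);
  check_plan(c, natal, sire, dam);
  int total = c.D * c.N;
  std::vector<int> nt(total), si(total), da(total);
  for (int s = 0; s < total; ++s) {
    nt[s] = natal[s] - 1;
    si[s] = sire[s] - 1;
    da[s] = dam[s] - 1;
  }
  return eval_plan(c, nt.data(), si.data(), da.data());
}

// [[Rcpp::export]]
List propose_move_cpp(IntegerVector deme, LogicalVector female, int N, int M,
                      IntegerVector natal, IntegerVector sire, IntegerVector dam) {
  // genotypes are irrelevant to move feasibility; use a 1-locus dummy
  int np = deme.size();
  IntegerMatrix dummy(np, 1);
  Ctx c = make_ctx(dummy, dummy, deme, female, N, M, "maxHT", 1.0);
  check_plan(c, natal, sire, dam);
  int total = c.D * c.N;
  std::vector<int> nt(total), si(total), da(total);
  for (int s = 0; s < total; ++s) {
    nt[s] = natal[s] - 1;
    si[s] = sire[s] - 1;
    da[s] = dam[s] - 1;
  }
  bool moved = do_move(c, nt.data(), si.data(), da.data());
  IntegerVector on(total), os(total), od(total);
  for (int s = 0; s < total; ++s) {
    on[s] = nt[s] + 1;
    os[s] = si[s] + 1;
    od[s] = da[s] + 1;
  }
  return List::create(_["natal"] = on, _["sire"] = os, _["dam"] = od,
                      _["moved"] = moved);
}

// Simulated annealing with Metropolis acceptance and geometric cooling.
// Returns the best plan visited. t0 = NA calibrates the initial temperature
// so that a typical worsening probe move is accepted with probability 1/2.
// [[Rcpp::export]]
List anneal_cpp(IntegerMatrix a1, IntegerMatrix a2, IntegerVector deme,
                LogicalVector female, int N, int M, std::string method,
                double lambda, IntegerVector natal, IntegerVector sire,
                IntegerVector dam, double t0, double cooling,
                int steps_per_temp, int iterations) {
  if (cooling <= 0 || cooling >= 1) stop("cooling factor must be in (0, 1)");
  if (iterations < 1 || steps_per_temp < 1) stop("iteration counts must be positive");
  Ctx c = make_ctx(a1, a2, deme, female, N, M, method, lambda);
  check_plan(c, natal, sire, dam);
  int total = c.D * c.N;
  std::vector<int> cn(total), cs(total), cd(total);
  for (int s = 0; s < total; ++s) {
    cn[s] = natal[s] - 1;
    cs[s] = sire[s] - 1;
    cd[s] = dam[s] - 1;
  }
  std::vector<int> bn(cn), bs(cs), bd(cd), pn(total), ps(total), pd(total);
  double scur = eval_plan(c, cn.data(), cs.data(), cd.data());
  double sbest = scur, s0 = scur;

  if (!R_finite(t0)) {
    double worse = 0.0;
    int nworse = 0;
    for (int p = 0; p < 100; ++p) {
      pn = cn; ps = cs; pd = cd;
      if (!do_move(c, pn.data(), ps.data(), pd.data())) continue;
      double d = eval_plan(c, pn.data(), ps.data(), pd.data()) - scur;
      if (d < 0) { worse -= d; ++nworse; }
    }
    t0 = nworse ? (worse / nworse) / std::log(2.0) : 1e-3;
    if (t0 <= 0) t0 = 1e-3;
  }

  double T = t0;
  long accepted = 0;
  for (int it = 0; it < iterations; ++it) {
    if (it > 0 && it % steps_per_temp == 0) T *= cooling;
    pn = cn; ps = cs; pd = cd;
    if (!do_move(c, pn.data(), ps.data(), pd.data())) continue;
    double sc = eval_plan(c, pn.data(), ps.data(), pd.data());
    double delta = sc - scur;
    if (delta >= 0 || unif_rand() < std::exp(delta / T)) {
      cn.swap(pn); cs.swap(ps); cd.swap(pd);
      scur = sc;
      ++accepted;
      if (scur > sbest) {  // strict: ties keep the incumbent best
        sbest = scur;
        bn = cn; bs = cs; bd = cd;
      }
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector on(total), os(total), od(total);
  for (int s = 0; s < total; ++s) {
    on[s] = bn[s] + 1;
    os[s] = bs[s] + 1;
    od[s] = bd[s] + 1;
  }
  return List::create(_["natal"] = on, _["sire"] = os, _["dam"] = od,
                      _["score"] = sbest, _["score0"] = s0, _["t0"] = t0,
                      _["accepted"] = (double)accepted);
}
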