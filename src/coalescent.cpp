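// Coalescent core for the ancestral-change-plus-split model and the
// composite-likelihood sweep scan.
//
// Model (backward time, units of 2*NA generations):
//   t in [0, Td)   : two demes F and Y with relative sizes nu1F, nu2Y
//   t in [Td, Ta)  : merged ancestral deme with relative size nua
//   t >= Ta        : ancestral deme with relative size 1
// No migration, no recombination; sites are independent loci.
//
// RNG is self-contained (splitmix64 -> xoshiro256++) so that a given seed
// yields byte-identical output on any platform, and so that each site owns
// a private stream (needed for the cheap two-pass site simulation).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct Demography {
  double nua, Ta, Td, nu1F, nu2Y;
};

// One genealogy of the structured coalescent. Lineages carry an arbitrary
// integer payload (descendant-count index or bitmask) merged on coalescence.
//
// Exactly 3 uniforms are consumed per coalescent event (waiting time, deme
// choice, pair choice) regardless of epoch crossings, so two passes with the
// same per-site stream replay the identical genealogy.
//
// Branches (payload, length) of all non-root lineages are reported through
// the callback when `record` is true; total tree length is returned always.
struct Lineage {
  uint64_t mask;   // bitmask of descendant sample indices (n <= 64)
  double birth;    // time the lineage was created
  int deme;        // 0 = F, 1 = Y (only meaningful before Td)
};

template <typename BranchFn>
double sim_genealogy(int n_hap, const int *deme0, const Demography &dem,
                     Xoshiro &rng, bool record, BranchFn on_branch) {
  std::vector<Lineage> lin(n_hap);
  int kF = 0, kY = 0;
  for (int i = 0; i < n_hap; ++i) {
    lin[i].mask = record ? (1ULL << i) : 0ULL;
    lin[i].birth = 0.0;
    lin[i].deme = deme0[i];
    if (deme0[i] == 0) ++kF; else ++kY;
  }
  double t = 0.0, ttot = 0.0;
  int k = n_hap;
  while (k > 1) {
    // integrated-hazard inversion across epochs: one Exp(1) draw per event
    double E = -std::log(rng.unif());
    double rF = 0.0, rY = 0.0, ev_t = 0.0;
    for (;;) {
      double bound;
      if (t < dem.Td) {
        rF = kF * (kF - 1) / (2.0 * dem.nu1F);
        rY = kY * (kY - 1) / (2.0 * dem.nu2Y);
        bound = dem.Td;
      } else if (t < dem.Ta) {
        rF = k * (k - 1) / (2.0 * dem.nua);
        rY = 0.0;
        bound = dem.Ta;
      } else {
        rF = k * (k - 1) / 2.0;
        rY = 0.0;
        bound = R_PosInf;
      }
      double r = rF + rY;
      if (r <= 0.0) {           // no coalescence possible; jump to boundary
        ttot += k * (bound - t);
        t = bound;
        if (t >= dem.Td) { kF = k; kY = 0; } // demes merged
        continue;
      }
      double dt = E / r;
      if (t + dt <= bound) { ev_t = t + dt; ttot += k * dt; break; }
      E -= r * (bound - t);
      ttot += k * (bound - t);
      t = bound;
      if (t >= dem.Td) { kF = k; kY = 0; }
    }
    t = ev_t;
    // deme choice (always consume one uniform for stream parity)
    double ud = rng.unif();
    int d = (t < dem.Td && ud >= rF / (rF + rY)) ? 1 : 0;
    int kd = (t < dem.Td) ? (d == 0 ? kF : kY) : k;
    // unordered pair within the chosen deme
    double up = rng.unif();
    long npair = (long)kd * (kd - 1) / 2;
    long idx = (long)(up * npair);
    if (idx >= npair) idx = npair - 1;
    int a = 0;
    while (idx >= kd - 1 - a) { idx -= (kd - 1 - a); ++a; }
    int b = a + 1 + (int)idx;
    // map within-deme indices to global indices
    int ga = -1, gb = -1, seen = 0;
    for (int i = 0; i < k; ++i) {
      bool in_d = (t >= dem.Td) || (lin[i].deme == d);
      if (!in_d) continue;
      if (seen == a) ga = i;
      if (seen == b) { gb = i; }
      ++seen;
    }
    if (record) {
      on_branch(lin[ga].mask, t - lin[ga].birth);
      on_branch(lin[gb].mask, t - lin[gb].birth);
    }
    lin[ga].mask |= lin[gb].mask;
    lin[ga].birth = t;
    if (t < dem.Td) { if (d == 0) --kF; else --kY; } else { kF = k - 1; }
    lin[gb] = lin[k - 1];
    --k;
  }
  return ttot;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_expected_joint_branchlen")]]
NumericMatrix cpp_expected_joint_branchlen(int n1, int n2,
                                           double nua, double Ta, double Td,
                                           double nu1F, double nu2Y,
                                           int n_reps, double seed) {
  int n = n1 + n2;
  if (n > 64) stop("at most 64 haplotypes supported");
  std::vector<int> deme0(n);
  for (int i = 0; i < n; ++i) deme0[i] = (i < n1) ? 0 : 1;
  Demography dem{nua, Ta, Td, nu1F, nu2Y};
  NumericMatrix out(n1 + 1, n2 + 1);
  uint64_t mask1 = (n1 == 64) ? ~0ULL : ((1ULL << n1) - 1ULL);
  Xoshiro rng((uint64_t)seed);
  for (int r = 0; r < n_reps; ++r) {
    sim_genealogy(n, deme0.data(), dem, rng, true,
                  [&](uint64_t mask, double len) {
                    int c1 = __builtin_popcountll(mask & mask1);
                    int c2 = __builtin_popcountll(mask & ~mask1);
                    out(c1, c2) += len;
                  });
  }
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) out(i, j) /= n_reps;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_sites")]]
List cpp_simulate_sites(IntegerVector deme0, double nua, double Ta, double Td,
                        double nu1F, double nu2Y, double theta2, double L,
                        double seed) {
  int n = deme0.size();
  if (n > 64) stop("at most 64 haplotypes supported");
  Demography dem{nua, Ta, Td, nu1F, nu2Y};
  std::vector<double> site_idx;
  std::vector<uint64_t> patterns;
  long n_multi = 0;
  long Ll = (long)L;
  std::vector<uint64_t> br_mask;
  std::vector<double> br_len;
  for (long s = 0; s < Ll; ++s) {
    uint64_t sseed = (uint64_t)seed ^ (0x5851F42D4C957F2DULL * (uint64_t)(s + 1));
    // pass 1: tree length only
    Xoshiro rng1(sseed);
    double ttot = sim_genealogy(n, &deme0[0], dem, rng1, false,
                                [](uint64_t, double) {});
    double lam = theta2 * ttot;
    // Poisson by inversion (one uniform; lam is tiny in practice)
    double u = rng1.unif();
    int nmut = 0;
    double p = std::exp(-lam), cum = p;
    while (u > cum) { ++nmut; p *= lam / nmut; cum += p; if (nmut > 1000) break; }
    if (nmut == 0) continue;
    // pass 2: replay with branch recording
    br_mask.clear(); br_len.clear();
    Xoshiro rng2(sseed);
    sim_genealogy(n, &deme0[0], dem, rng2, true,
                  [&](uint64_t mask, double len) {
                    br_mask.push_back(mask);
                    br_len.push_back(len);
                  });
    rng2.unif(); // the Poisson draw, replayed for parity
    if (nmut > 1) { n_multi++; for (int m = 0; m < nmut; ++m) rng2.unif(); continue; }
    double um = rng2.unif() * ttot;
    size_t b = 0;
    for (; b + 1 < br_mask.size(); ++b) {
      if (um <= br_len[b]) break;
      um -= br_len[b];
    }
    site_idx.push_back((double)(s + 1));
    patterns.push_back(br_mask[b]);
  }
  int S = (int)site_idx.size();
  IntegerMatrix geno(S, n);
  NumericVector pos(S);
  for (int i = 0; i < S; ++i) {
    pos[i] = site_idx[i];
    for (int h = 0; h < n; ++h) geno(i, h) = (patterns[i] >> h) & 1ULL;
  }
  return List::create(_["site"] = pos, _["haplotypes"] = geno,
                      _["n_multiallelic_dropped"] = (double)n_multi);
}

namespace {

const double LOGEPS = 13.815510557964274; // -log(1e-6)

// Per-site log-likelihood-ratio contribution as a function of t = alpha * d
// and folded class j, tabulated densely over [0, -log(1e-6)] for linear
// interpolation: the binomial escape mixture depends on (alpha, d) only
// through t, so one table serves every grid position and every alpha.
// M: (n+1) x K matrix, row B = unnormalized folded class probabilities given
// B escaped lineages; mB = row sums (polymorphic mass); logphi = log
// background class probabilities. Beyond t the escape probability is ~1 and
// the site cancels against the background term.
struct LlrTable {
  int K, NT;
  double dt;
  std::vector<double> tab; // NT x K, row-major
  LlrTable(const NumericMatrix &M, const NumericVector &mB,
           const NumericVector &logphi, int n, int nt = 16384)
      : K(M.ncol()), NT(nt), dt(LOGEPS / (nt - 1)), tab((size_t)nt * M.ncol()) {
    std::vector<double> lch(n + 1);
    for (int B = 0; B <= n; ++B) lch[B] = Rf_lchoose((double)n, (double)B);
    std::vector<double> w(n + 1);
    for (int i = 0; i < NT; ++i) {
      double t = i * dt;
      double pe = -std::expm1(-t);
      if (pe <= 0.0) {
        std::fill(w.begin(), w.end(), 0.0);
        w[0] = 1.0;
      } else {
        double lp = std::log(pe), lq = std::log1p(-pe);
        for (int B = 0; B <= n; ++B)
          w[B] = std::exp(lch[B] + B * lp + (n - B) * lq);
      }
      double den = 0.0;
      for (int B = 0; B <= n; ++B) den += w[B] * mB[B];
      for (int j = 0; j < K; ++j) {
        double num = 0.0;
        for (int B = 0; B <= n; ++B) num += w[B] * M(B, j);
        tab[(size_t)i * K + j] = std::log(num / den) - logphi[j];
      }
    }
  }
  // sum of contributions at grid position x for sweep intensity alpha;
  // pos must be sorted ascending.
  double llr_at(double x, double alpha, const double *pos, const int *cls,
                int n_sites) const {
    double dmax = LOGEPS / alpha;
    int lo = (int)(std::lower_bound(pos, pos + n_sites, x - dmax) - pos);
    int hi = (int)(std::upper_bound(pos, pos + n_sites, x + dmax) - pos);
    double ll = 0.0;
    for (int s = lo; s < hi; ++s) {
      double t = alpha * std::fabs(pos[s] - x);
      double u = t / dt;
      int i0 = (int)u;
      if (i0 >= NT - 1) continue;
      double f = u - i0;
      const double *row = &tab[(size_t)i0 * K + (cls[s] - 1)];
      ll += row[0] + f * (row[K] - row[0]);
    }
    return ll;
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_clr_scan")]]
NumericMatrix cpp_clr_scan(NumericVector grid, NumericVector pos,
                           IntegerVector cls, NumericMatrix M,
                           NumericVector mB, NumericVector logphi,
                           NumericVector alphas) {
  int n = M.nrow() - 1;
  int n_sites = pos.size();
  LlrTable T(M, mB, logphi, n);
  NumericMatrix out(grid.size(), 2);
  const double GR = 0.6180339887498949;
  for (int g = 0; g < grid.size(); ++g) {
    double x = grid[g];
    int best = 0;
    double bestll = R_NegInf;
    std::vector<double> lls(alphas.size());
    for (int a = 0; a < alphas.size(); ++a) {
      lls[a] = T.llr_at(x, alphas[a], &pos[0], &cls[0], n_sites);
      if (lls[a] > bestll) { bestll = lls[a]; best = a; }
    }
    // golden-section refinement on log(alpha) between grid neighbours
    double lo = std::log(alphas[std::max(0, best - 1)]);
    double hi = std::log(alphas[std::min((int)alphas.size() - 1, best + 1)]);
    double a1 = hi - GR * (hi - lo), a2 = lo + GR * (hi - lo);
    double f1 = T.llr_at(x, std::exp(a1), &pos[0], &cls[0], n_sites);
    double f2 = T.llr_at(x, std::exp(a2), &pos[0], &cls[0], n_sites);
    for (int it = 0; it < 40 && (hi - lo) > 1e-3; ++it) {
      if (f1 < f2) {
        lo = a1; a1 = a2; f1 = f2; a2 = lo + GR * (hi - lo);
        f2 = T.llr_at(x, std::exp(a2), &pos[0], &cls[0], n_sites);
      } else {
        hi = a2; a2 = a1; f2 = f1; a1 = hi - GR * (hi - lo);
        f1 = T.llr_at(x, std::exp(a1), &pos[0], &cls[0], n_sites);
      }
    }
    double fb = std::max(f1, f2), ab = (f1 > f2) ? a1 : a2;
    double alpha_hat, llmax;
    if (fb > bestll) { llmax = fb; alpha_hat = std::exp(ab); }
    else { llmax = bestll; alpha_hat = alphas[best]; }
    out(g, 0) = 2.0 * std::max(0.0, llmax);
    out(g, 1) = alpha_hat;
  }
  return out;
}
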