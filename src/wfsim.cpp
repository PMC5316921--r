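#include <Rcpp.h>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Discrete-generation diploid Wright-Fisher forward simulator.
//
// A population is 2N haplotypes over a shared list of positions (1..L); the
// list is append-only between compactions and NOT kept sorted (gamete
// construction only needs each site's position relative to the crossover
// breakpoints, not site order). Each generation: parents are sampled
// proportional to fitness (additive at the sweep site: 1, 1+s/2, 1+s),
// gametes recombine with per-adjacent-bp crossover probability r, and
// Poisson(mu*L) new mutations per gamete arise at uniform positions;
// positions already in use are redrawn, so every site stays biallelic.
// Sites lost from the population are pruned at periodic compactions; fixed
// sites are retained so that the two post-split populations can be merged by
// position without losing fixed differences. All randomness flows through
// R's RNG, so runs are reproducible from set.seed().

struct Pop {
  std::vector<int> pos;                        // positions (append order)
  std::vector<std::vector<unsigned char>> hap; // 2N rows of length |pos|
  std::set<int> taken;                         // positions in use
  int sweep_idx;                               // index into pos, -1 if none
};

static int sample_weighted(const std::vector<double> &cum) {
  double u = R::unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

static void make_gamete(const Pop &p, int ind, double r, int L,
                        std::vector<unsigned char> &out) {
  const std::vector<unsigned char> &h1 = p.hap[2 * ind];
  const std::vector<unsigned char> &h2 = p.hap[2 * ind + 1];
  const size_t S = p.pos.size();
  int k = (int)R::rpois(r * (double)(L - 1));
  int start = (R::unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) {
    out = start ? h2 : h1;
    return;
  }
  double bk[8];
  std::vector<double> bkv;
  double *b = bk;
  if (k > 8) { bkv.resize(k); b = bkv.data(); }
  for (int i = 0; i < k; ++i) b[i] = 1.0 + R::unif_rand() * (double)(L - 1);
  out.resize(S);
  for (size_t s = 0; s < S; ++s) {
    double x = (double)p.pos[s];
    int par = start;
    for (int i = 0; i < k; ++i) par ^= (b[i] <= x);
    out[s] = par ? h2[s] : h1[s];
  }
}

// drop lost sites (count 0), keep fixed sites and the sweep site
static void compact(Pop &p, int twoN) {
  const size_t S = p.pos.size();
  std::vector<int> cnt(S, 0);
  for (int j = 0; j < twoN; ++j) {
    const std::vector<unsigned char> &h = p.hap[j];
    for (size_t i = 0; i < S; ++i) cnt[i] += h[i];
  }
  std::vector<int> keep;
  keep.reserve(S);
  for (size_t i = 0; i < S; ++i)
    if (cnt[i] > 0 || (int)i == p.sweep_idx) keep.push_back((int)i);
  if (keep.size() == S) return;
  std::vector<int> npos(keep.size());
  int new_sweep = -1;
  for (size_t t = 0; t < keep.size(); ++t) {
    npos[t] = p.pos[keep[t]];
    if (keep[t] == p.sweep_idx) new_sweep = (int)t;
  }
  for (int j = 0; j < twoN; ++j) {
    std::vector<unsigned char> nh(keep.size());
    for (size_t t = 0; t < keep.size(); ++t) nh[t] = p.hap[j][keep[t]];
    p.hap[j].swap(nh);
  }
  p.pos.swap(npos);
  p.sweep_idx = new_sweep;
  p.taken.clear();
  p.taken.insert(p.pos.begin(), p.pos.end());
}

static void next_generation(Pop &p, int N, double mu, double r, int L,
                            double s) {
  const int twoN = 2 * N;

  std::vector<double> cum(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (s != 0.0 && p.sweep_idx >= 0) {
      int d = p.hap[2 * i][p.sweep_idx] + p.hap[2 * i + 1][p.sweep_idx];
      w = 1.0 + 0.5 * s * (double)d;
    }
    tot += w;
    cum[i] = tot;
  }

  std::vector<std::vector<unsigned char>> off(twoN);
  std::vector<std::pair<int, int>> newmut;  // (position, offspring haplotype)
  for (int j = 0; j < twoN; ++j) {
    int par = sample_weighted(cum);
    make_gamete(p, par, r, L, off[j]);
    int nm = (int)R::rpois(mu * (double)L);
    for (int m = 0; m < nm; ++m) {
      int guard = 0;
      int q = 1 + (int)(R::unif_rand() * (double)L);
      if (q > L) q = L;
      while (p.taken.count(q) && ++guard < 1000) {
        q = 1 + (int)(R::unif_rand() * (double)L);
        if (q > L) q = L;
      }
      if (p.taken.count(q)) continue;  // genome saturated; drop this mutation
      p.taken.insert(q);
      newmut.push_back(std::make_pair(q, j));
    }
  }

  // append new mutation sites (carrier count 1)
  const size_t S2 = p.pos.size() + newmut.size();
  for (int j = 0; j < twoN; ++j) off[j].resize(S2, 0);
  for (size_t m = 0; m < newmut.size(); ++m) {
    p.pos.push_back(newmut[m].first);
    off[newmut[m].second][p.pos.size() - 1] = 1;
  }
  p.hap.swap(off);
}

static void run_generations(Pop &p, int N, double mu, double r, int L,
                            double s, int gens) {
  for (int g = 0; g < gens; ++g) {
    next_generation(p, N, mu, r, L, s);
    if ((g + 1) % 8 == 0 || g == gens - 1) compact(p, 2 * N);
  }
}

// Seed the sweep allele at count 1 on a random haplotype. A standing variant
// at that exact position is reset to a fresh count-1 state.
static void seed_sweep(Pop &p, int sweep_pos, int twoN) {
  int at = -1;
  for (size_t i = 0; i < p.pos.size(); ++i)
    if (p.pos[i] == sweep_pos) { at = (int)i; break; }
  if (at < 0) {
    p.pos.push_back(sweep_pos);
    p.taken.insert(sweep_pos);
    for (int j = 0; j < twoN; ++j) p.hap[j].push_back(0);
    at = (int)p.pos.size() - 1;
  } else {
    for (int j = 0; j < twoN; ++j) p.hap[j][at] = 0;
  }
  p.sweep_idx = at;
  int carrier = (int)(R::unif_rand() * twoN);
  if (carrier >= twoN) carrier = twoN - 1;
  p.hap[carrier][p.sweep_idx] = 1;
}

static double sweep_freq(const Pop &p, int twoN) {
  if (p.sweep_idx < 0) return 0.0;
  int c = 0;
  for (int j = 0; j < twoN; ++j) c += p.hap[j][p.sweep_idx];
  return (double)c / (double)twoN;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int N, int L, double mu, double r, int t_burn,
                     int t_split, int sweep_pos, double s, int sweep_start,
                     bool condition, int max_tries, int n_sample_ref,
                     int n_sample_test) {
  const int twoN = 2 * N;
  Pop anc;
  anc.sweep_idx = -1;
  anc.hap.assign(twoN, std::vector<unsigned char>());
  run_generations(anc, N, mu, r, L, 0.0, t_burn);

  Pop ref = anc;
  run_generations(ref, N, mu, r, L, 0.0, t_split);

  Pop test = anc;
  int tries = 0;
  bool fixed = false;
  double finalfreq = 0.0;
  if (sweep_pos >= 1) {
    run_generations(test, N, mu, r, L, 0.0, sweep_start);
    Pop saved = test;
    for (;;) {
      ++tries;
      test = saved;
      seed_sweep(test, sweep_pos, twoN);
      run_generations(test, N, mu, r, L, s, t_split - sweep_start);
      finalfreq = sweep_freq(test, twoN);
      fixed = (finalfreq == 1.0);
      if (!condition || fixed || tries >= max_tries) break;
    }
    if (condition && !fixed)
      stop("sweep allele failed to fix within max_tries trajectory restarts");
  } else {
    run_generations(test, N, mu, r, L, 0.0, t_split);
  }

  // sort each population's site list for merging and output
  auto sort_pop = [&](Pop &p) {
    std::vector<int> ord(p.pos.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return p.pos[a] < p.pos[b]; });
    std::vector<int> npos(ord.size());
    for (size_t i = 0; i < ord.size(); ++i) npos[i] = p.pos[ord[i]];
    int new_sweep = -1;
    for (size_t i = 0; i < ord.size(); ++i)
      if (ord[i] == p.sweep_idx && p.sweep_idx >= 0) new_sweep = (int)i;
    for (int j = 0; j < twoN; ++j) {
      std::vector<unsigned char> nh(ord.size());
      for (size_t i = 0; i < ord.size(); ++i) nh[i] = p.hap[j][ord[i]];
      p.hap[j].swap(nh);
    }
    p.pos.swap(npos);
    p.sweep_idx = new_sweep;
  };
  sort_pop(ref);
  sort_pop(test);

  // union of positions across the two populations
  std::vector<int> upos;
  {
    std::set<int> u(ref.pos.begin(), ref.pos.end());
    u.insert(test.pos.begin(), test.pos.end());
    upos.assign(u.begin(), u.end());
  }
  const int hr = 2 * n_sample_ref, ht = 2 * n_sample_test;
  const size_t S = upos.size();

  std::vector<int> ridx(S, -1), tidx(S, -1);
  {
    size_t i = 0;
    for (size_t t = 0; t < S; ++t) {
      while (i < ref.pos.size() && ref.pos[i] < upos[t]) ++i;
      if (i < ref.pos.size() && ref.pos[i] == upos[t]) ridx[t] = (int)i;
    }
    i = 0;
    for (size_t t = 0; t < S; ++t) {
      while (i < test.pos.size() && test.pos[i] < upos[t]) ++i;
      if (i < test.pos.size() && test.pos[i] == upos[t]) tidx[t] = (int)i;
    }
  }

  // keep rows with at least one ALT allele among sampled haplotypes (plus
  // the sweep site, even if monomorphic in the sample)
  std::vector<int> keep;
  for (size_t t = 0; t < S; ++t) {
    int c = 0;
    if (ridx[t] >= 0)
      for (int j = 0; j < hr; ++j) c += ref.hap[j][ridx[t]];
    if (tidx[t] >= 0)
      for (int j = 0; j < ht; ++j) c += test.hap[j][tidx[t]];
    if (c > 0 || upos[t] == sweep_pos) keep.push_back((int)t);
  }

  IntegerMatrix H((int)keep.size(), hr + ht);
  IntegerVector outpos((int)keep.size());
  for (size_t k = 0; k < keep.size(); ++k) {
    int t = keep[k];
    outpos[k] = upos[t];
    for (int j = 0; j < hr; ++j)
      H((int)k, j) = (ridx[t] >= 0) ? ref.hap[j][ridx[t]] : 0;
    for (int j = 0; j < ht; ++j)
      H((int)k, hr + j) = (tidx[t] >= 0) ? test.hap[j][tidx[t]] : 0;
  }

  return List::create(_["pos"] = outpos, _["H"] = H,
                      _["sweep_final_freq"] = finalfreq,
                      _["sweep_fixed"] = fixed, _["tries"] = tries);
}
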