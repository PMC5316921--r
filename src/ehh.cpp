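#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Extended haplotype homozygosity by incremental partition refinement.
//
// H is a sites x haplotypes 0/1 matrix. A "walk" starts at a core site with
// all carriers in one group (EHH = 1) and refines the partition at each
// successive site moving away from the core; EHH(x) = sum_g C(n_g,2) / C(n,2).
// The walk stops at the first site where EHH < cutoff (that site is kept, so
// the final trapezoid of any integral includes it), at EHH == 0 (no further
// change is possible), when sites run out, or when the bp extension exceeds
// max_ext_bp. hit_cutoff records whether the profile actually fell below the
// cutoff -- integrals from walks that never did are flagged invalid upstream.

struct WalkResult {
  std::vector<int> idx;      // site indices, starting with the core
  std::vector<double> ehh;   // EHH values, ehh[0] == 1
  bool hit_cutoff;
};

static WalkResult ehh_walk(const IntegerMatrix &H, int core,
                           const std::vector<int> &carriers, int dir,
                           double cutoff, const NumericVector &bp,
                           double max_ext_bp) {
  WalkResult w;
  const int n = (int)carriers.size();
  const double denom = n * (n - 1) / 2.0;
  std::vector<int> grp(n, 0);
  // scratch: group-splitting lookup (keys are grp*2+allele < 2n) and counts
  std::vector<int> remap(2 * n, -1), touched, cnt(n, 0), ng(n);
  touched.reserve(2 * n);
  w.idx.push_back(core);
  w.ehh.push_back(1.0);
  w.hit_cutoff = false;
  const int S = H.nrow();
  for (int i = core + dir; i >= 0 && i < S; i += dir) {
    if (std::fabs(bp[i] - bp[core]) > max_ext_bp) break;
    int k = 0;
    touched.clear();
    for (int j = 0; j < n; ++j) {
      int key = grp[j] * 2 + (H(i, carriers[j]) != 0);
      if (remap[key] < 0) {
        remap[key] = k++;
        touched.push_back(key);
      }
      ng[j] = remap[key];
    }
    for (size_t t = 0; t < touched.size(); ++t) remap[touched[t]] = -1;
    grp.swap(ng);
    std::fill(cnt.begin(), cnt.begin() + k, 0);
    for (int j = 0; j < n; ++j) cnt[grp[j]]++;
    double pairs = 0.0;
    for (int g = 0; g < k; ++g) pairs += cnt[g] * (cnt[g] - 1) / 2.0;
    double e = pairs / denom;
    w.idx.push_back(i);
    w.ehh.push_back(e);
    if (e < cutoff) { w.hit_cutoff = true; break; }
    if (e == 0.0) { w.hit_cutoff = true; break; }  // cannot decrease further
  }
  return w;
}

// [[Rcpp::export]]
List ehh_walk_cpp(IntegerMatrix H, int core, IntegerVector carriers, int dir,
                  double cutoff, NumericVector bp, double max_ext_bp) {
  std::vector<int> car(carriers.begin(), carriers.end());
  WalkResult w = ehh_walk(H, core, car, dir, cutoff, bp, max_ext_bp);
  return List::create(_["idx"] = wrap(w.idx), _["ehh"] = wrap(w.ehh),
                      _["hit_cutoff"] = w.hit_cutoff);
}

// Trapezoidal iHH (in cM) for one direction of a walk; valid only if the walk
// fell below the cutoff before running out of sites / extension.
static double ihh_one_dir(const IntegerMatrix &H, int core,
                          const std::vector<int> &carriers, int dir,
                          double cutoff, const NumericVector &bp,
                          const NumericVector &cm, double max_ext_bp,
                          bool &valid) {
  WalkResult w = ehh_walk(H, core, carriers, dir, cutoff, bp, max_ext_bp);
  valid = w.hit_cutoff;
  double ihh = 0.0;
  for (size_t t = 1; t < w.idx.size(); ++t) {
    double dg = std::fabs(cm[w.idx[t]] - cm[w.idx[t - 1]]);
    ihh += 0.5 * (w.ehh[t] + w.ehh[t - 1]) * dg;
  }
  return ihh;
}

static double ihh_both(const IntegerMatrix &H, int core,
                       const std::vector<int> &carriers, double cutoff,
                       const NumericVector &bp, const NumericVector &cm,
                       double max_ext_bp, bool &valid) {
  bool vl = false, vr = false;
  double l = ihh_one_dir(H, core, carriers, -1, cutoff, bp, cm, max_ext_bp, vl);
  double r = ihh_one_dir(H, core, carriers, +1, cutoff, bp, cm, max_ext_bp, vr);
  valid = vl && vr;
  return l + r;
}

// iHS scan core: H already subset to one population's haplotypes.
// derived[c] is the allele (0/1) counted as derived at cores[c].
// Returns ncore x 3 matrix: ihh_derived, ihh_ancestral, valid(0/1).
// [[Rcpp::export]]
NumericMatrix ihs_scan_cpp(IntegerMatrix H, NumericVector bp, NumericVector cm,
                           IntegerVector cores, IntegerVector derived,
                           double cutoff, double max_ext_bp) {
  const int nh = H.ncol();
  NumericMatrix out(cores.size(), 3);
  for (int c = 0; c < cores.size(); ++c) {
    int site = cores[c];
    std::vector<int> der, anc;
    for (int j = 0; j < nh; ++j) {
      if (H(site, j) == derived[c]) der.push_back(j); else anc.push_back(j);
    }
    if (der.size() < 2 || anc.size() < 2) {
      out(c, 0) = NA_REAL; out(c, 1) = NA_REAL; out(c, 2) = 0;
      continue;
    }
    bool vd = false, va = false;
    double id = ihh_both(H, site, der, cutoff, bp, cm, max_ext_bp, vd);
    double ia = ihh_both(H, site, anc, cutoff, bp, cm, max_ext_bp, va);
    out(c, 0) = id;
    out(c, 1) = ia;
    out(c, 2) = (vd && va && id > 0 && ia > 0) ? 1 : 0;
  }
  return out;
}

// XP-EHH scan core: carriers are ALL haplotypes of each population (the core
// allele never splits the partition). hapA/hapB are 0-based column indices.
// Returns ncore x 3 matrix: ihh_a, ihh_b, valid(0/1).
// [[Rcpp::export]]
NumericMatrix xpehh_scan_cpp(IntegerMatrix H, IntegerVector hapA,
                             IntegerVector hapB, NumericVector bp,
                             NumericVector cm, IntegerVector cores,
                             double cutoff, double max_ext_bp) {
  std::vector<int> A(hapA.begin(), hapA.end());
  std::vector<int> B(hapB.begin(), hapB.end());
  NumericMatrix out(cores.size(), 3);
  for (int c = 0; c < cores.size(); ++c) {
    int site = cores[c];
    bool va = false, vb = false;
    double ia = ihh_both(H, site, A, cutoff, bp, cm, max_ext_bp, va);
    double ib = ihh_both(H, site, B, cutoff, bp, cm, max_ext_bp, vb);
    out(c, 0) = ia;
    out(c, 1) = ib;
    out(c, 2) = (va && vb && ia > 0 && ib > 0) ? 1 : 0;
  }
  return out;
}
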