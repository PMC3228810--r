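#include <RcppArmadillo.h>
#include <vector>
#include <climits>
#include "dfemap.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward haploid Wright-Fisher codon simulator with hot-or-not recurrent
// selection and explicit ancestral-identity tracking.
//
// Scaling: M gene copies stand for one unit of P*Ne generations, the per-copy
// fitness advantage of the hot class is s' = gamma / (2M), and the per-copy
// per-generation mutation probability i -> j is rates(i,j) / M, so the
// diffusion-limit Dirichlet parameters are 2M u = 2 * rates, the
// population-scaled (2 P Ne mu) rates the likelihood theory uses.
//
// Ancestral identity is tracked under three operational definitions:
//   0 last allele to have fixed,
//   1 allele carried at the most recent whole-population common-ancestor
//     checkpoint (an anchor-coalescence approximation to the population MRCA),
//   2 oldest allele segregating in the population.
// The selection regime (hot = amino acid different from ancestor) re-anchors
// on the oldest-segregating allele, the definition under which the
// conditional sampling theory is exact.

struct Cls { int a; int h; int cnt; };

struct WFPop {
  int M;
  double sel;                       // s' = gamma / (2M)
  const arma::ivec* aa;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<double> > cump;  // conditional destination probs
  std::vector<double> Ucopy;               // per-copy mutation prob
  std::vector<Cls> cls;
  long origin[61];
  int cnt61[61];
  long gen;
  int anc, last_fixed, mrca_state;
  bool track_mrca;

  void setup(const arma::mat& R, const arma::ivec& aa_, double gamma, int M_,
             bool track_mrca_) {
    M = M_;
    sel = gamma / (2.0 * M);
    aa = &aa_;
    track_mrca = track_mrca_;
    int K = R.n_rows;
    nbr.assign(K, std::vector<int>());
    cump.assign(K, std::vector<double>());
    Ucopy.assign(K, 0.0);
    for (int i = 0; i < K; ++i) {
      double tot = 0.0;
      for (int j = 0; j < K; ++j)
        if (j != i && R(i, j) > 0.0) { nbr[i].push_back(j); tot += R(i, j); }
      Ucopy[i] = tot / M;
      double c = 0.0;
      for (size_t k = 0; k < nbr[i].size(); ++k) {
        c += R(i, nbr[i][k]) / tot;
        cump[i].push_back(c);
      }
    }
  }

  void copy_state_from(const WFPop& o) {
    cls = o.cls;
    for (int i = 0; i < 61; ++i) { origin[i] = o.origin[i]; cnt61[i] = o.cnt61[i]; }
    gen = o.gen;
    anc = o.anc; last_fixed = o.last_fixed; mrca_state = o.mrca_state;
  }

  void init(int codon) {
    cls.clear();
    Cls c0; c0.a = codon; c0.h = codon; c0.cnt = M;
    cls.push_back(c0);
    for (int i = 0; i < 61; ++i) { origin[i] = LONG_MAX; cnt61[i] = 0; }
    origin[codon] = 0;
    cnt61[codon] = M;
    gen = 0;
    anc = codon; last_fixed = codon; mrca_state = codon;
  }

  int pick_dest(int a) {
    double u = unif_rand();
    const std::vector<double>& cp = cump[a];
    for (size_t k = 0; k + 1 < cp.size(); ++k)
      if (u <= cp[k]) return nbr[a][k];
    return nbr[a][cp.size() - 1];
  }

  void merge_cls() {
    std::vector<Cls> out;
    for (size_t i = 0; i < cls.size(); ++i) {
      if (cls[i].cnt == 0) continue;
      bool merged = false;
      for (size_t j = 0; j < out.size(); ++j)
        if (out[j].a == cls[i].a && out[j].h == cls[i].h) {
          out[j].cnt += cls[i].cnt; merged = true; break;
        }
      if (!merged) out.push_back(cls[i]);
    }
    cls.swap(out);
  }

  void step() {
    ++gen;
    int ancaa = (*aa)(anc);
    // drift with selection (skip when monomorphic in allele and anchor)
    if (cls.size() > 1) {
      double wrem = 0.0;
      for (size_t c = 0; c < cls.size(); ++c) {
        double w = cls[c].cnt * (((*aa)(cls[c].a) != ancaa) ? 1.0 + sel : 1.0);
        wrem += w;
      }
      int remaining = M;
      for (size_t c = 0; c + 1 < cls.size(); ++c) {
        double w = cls[c].cnt * (((*aa)(cls[c].a) != ancaa) ? 1.0 + sel : 1.0);
        double p = (wrem > 0.0) ? w / wrem : 0.0;
        if (p > 1.0) p = 1.0;
        int k = (remaining > 0) ? (int) ::Rf_rbinom((double) remaining, p) : 0;
        cls[c].cnt = k; remaining -= k; wrem -= w;
      }
      cls[cls.size() - 1].cnt = remaining;
    }
    // mutation
    size_t ncls = cls.size();
    for (size_t c = 0; c < ncls; ++c) {
      if (cls[c].cnt == 0 || Ucopy[cls[c].a] <= 0.0) continue;
      int k = (int) ::Rf_rbinom((double) cls[c].cnt, Ucopy[cls[c].a]);
      for (int e = 0; e < k && cls[c].cnt > 0; ++e) {
        int j = pick_dest(cls[c].a);
        cls[c].cnt -= 1;
        Cls nc; nc.a = j; nc.h = cls[c].h; nc.cnt = 1;
        cls.push_back(nc);
      }
    }
    merge_cls();
    // aggregate counts and origin bookkeeping
    int newc[61];
    for (int i = 0; i < 61; ++i) newc[i] = 0;
    for (size_t c = 0; c < cls.size(); ++c) newc[cls[c].a] += cls[c].cnt;
    for (int i = 0; i < 61; ++i) {
      if (newc[i] > 0 && cnt61[i] == 0) origin[i] = gen;
      if (newc[i] == 0 && cnt61[i] > 0) origin[i] = LONG_MAX;
      cnt61[i] = newc[i];
    }
    // fixation
    if (cls.size() == 1 || (cls.size() > 0 && cnt61[cls[0].a] == M))
      last_fixed = cls[0].a;
    // oldest segregating ancestor
    if (cnt61[anc] == 0) {
      long best = LONG_MAX; int who = cls[0].a;
      for (int i = 0; i < 61; ++i)
        if (cnt61[i] > 0 && origin[i] < best) { best = origin[i]; who = i; }
      anc = who;
    }
    // anchor coalescence for the MRCA definition
    if (track_mrca) {
      bool same = true;
      for (size_t c = 1; c < cls.size(); ++c)
        if (cls[c].h != cls[0].h) { same = false; break; }
      if (same && cls.size() > 0) {
        mrca_state = cls[0].h;
        for (size_t c = 0; c < cls.size(); ++c) cls[c].h = cls[c].a;
        merge_cls();
      }
    }
  }

  void run(long gens) { for (long g = 0; g < gens; ++g) step(); }

  int ancestor(int def) const {
    if (def == 0) return last_fixed;
    if (def == 1) return mrca_state;
    return anc;
  }

  // multinomial sample of n copies (with replacement) from current freqs
  void sample(int n, int* out) const {
    double prem = 1.0;
    int rem = n, pos = 0;
    for (int i = 0; i < 61 && rem > 0; ++i) {
      if (cnt61[i] == 0) continue;
      double p = ((double) cnt61[i] / M) / prem;
      int k = (p >= 1.0) ? rem : (int) ::Rf_rbinom((double) rem, p);
      for (int c = 0; c < k; ++c) out[pos++] = i;
      rem -= k;
      prem -= (double) cnt61[i] / M;
    }
    while (pos < n) out[pos++] = cls[0].a;  // numerical guard
  }
};

// Stationary / lagged sampling of independent codon sites.  Each chain is
// initialised monomorphic (uniform random codon unless init_codon >= 0),
// burnt in, then sampled records_per_chain times with spacing_gens
// generations between records; the reported ancestor is recorded lag_gens
// generations before each sample is taken.
// [[Rcpp::export]]
List cpp_wf_sites(const arma::mat& R, const arma::ivec& aa, double gamma,
                  int M, int n_chains, long burn_gens, int records_per_chain,
                  long spacing_gens, long lag_gens, int n_sample,
                  int ancestry_def, int init_codon) {
  int total = n_chains * records_per_chain;
  IntegerMatrix samples(n_sample, total);
  IntegerVector ancv(total);
  WFPop pop;
  pop.setup(R, aa, gamma, M, ancestry_def == 1);
  std::vector<int> buf(n_sample);
  int col = 0;
  for (int ch = 0; ch < n_chains; ++ch) {
    int ic = init_codon >= 0 ? init_codon : (int) (unif_rand() * 61);
    if (ic > 60) ic = 60;
    pop.init(ic);
    pop.run(burn_gens);
    for (int r = 0; r < records_per_chain; ++r) {
      ancv[col] = pop.ancestor(ancestry_def);
      if (lag_gens > 0) pop.run(lag_gens);
      pop.sample(n_sample, &buf[0]);
      for (int i = 0; i < n_sample; ++i) samples(i, col) = buf[i];
      ++col;
      if (r + 1 < records_per_chain) pop.run(spacing_gens);
    }
  }
  return List::create(_["samples"] = samples, _["ancestor"] = ancv);
}

// Evolve one population per site from a given ancestral codon for a fixed
// number of generations (one phylogenetic branch), then sample; used to
// build multi-species datasets site by site.
// [[Rcpp::export]]
List cpp_wf_branch(const arma::mat& R, const arma::ivec& aa,
                   const arma::vec& gamma_site, int M, long gens,
                   int n_sample, int ancestry_def,
                   const arma::ivec& init_codons) {
  int S = init_codons.n_elem;
  IntegerMatrix samples(n_sample, S);
  IntegerVector ancv(S);
  std::vector<int> buf(n_sample);
  for (int s = 0; s < S; ++s) {
    WFPop pop;
    pop.setup(R, aa, gamma_site(s), M, ancestry_def == 1);
    pop.init(init_codons(s));
    pop.run(gens);
    ancv[s] = pop.ancestor(ancestry_def);
    pop.sample(n_sample, &buf[0]);
    for (int i = 0; i < n_sample; ++i) samples(i, s) = buf[i];
  }
  return List::create(_["samples"] = samples, _["ancestor"] = ancv);
}

// Three-population divergence simulator: per site, an ancestral population
// is burnt to stationarity under the ancestral parameters; the oldest
// segregating allele at the split is recorded as the root codon; each
// branch population then forks from the full ancestral state (standing
// variation included) and evolves under its own parameters for Tgens
// generations before sampling.
// [[Rcpp::export]]
List cpp_wf_three(const arma::mat& Ranc, const arma::ivec& aa,
                  double gamma_anc, const List& Rbranches,
                  const arma::mat& gamma_site, const arma::ivec& Tgens,
                  const arma::ivec& nsamp, int M, long burn_gens,
                  int ancestry_def, int n_sites) {
  int B = Rbranches.size();
  std::vector<arma::mat> Rb(B);
  for (int b = 0; b < B; ++b) Rb[b] = as<arma::mat>(Rbranches[b]);
  List samples(B);
  std::vector<IntegerMatrix> smp(B);
  for (int b = 0; b < B; ++b) smp[b] = IntegerMatrix(nsamp[b], n_sites);
  IntegerVector rootv(n_sites);
  IntegerMatrix tipanc(n_sites, B);
  WFPop anc, pop;
  anc.setup(Ranc, aa, gamma_anc, M, ancestry_def == 1);
  std::vector<int> buf;
  for (int s = 0; s < n_sites; ++s) {
    int ic = (int) (unif_rand() * 61);
    if (ic > 60) ic = 60;
    anc.init(ic);
    anc.run(burn_gens);
    rootv[s] = anc.ancestor(2);
    for (int b = 0; b < B; ++b) {
      pop.setup(Rb[b], aa, gamma_site(s, b), M, ancestry_def == 1);
      pop.init(0);
      pop.copy_state_from(anc);
      pop.run(Tgens[b]);
      tipanc(s, b) = pop.ancestor(ancestry_def);
      buf.resize(nsamp[b]);
      pop.sample(nsamp[b], &buf[0]);
      for (int i = 0; i < nsamp[b]; ++i) smp[b](i, s) = buf[i];
    }
  }
  for (int b = 0; b < B; ++b) samples[b] = smp[b];
  return List::create(_["samples"] = samples, _["root"] = rootv,
                      _["tip_ancestor"] = tipanc);
}

// Run replicate populations from explicit initial counts until monomorphic
// (or max_gens); returns the codon that fixed (-1 if still polymorphic).
// anc_init sets the initial ancestral identity the hot class is defined
// against.  Pass a zero rate matrix for pure drift.
// [[Rcpp::export]]
IntegerVector cpp_wf_fix(const arma::mat& R, const arma::ivec& aa,
                         double gamma, int M, const arma::ivec& init_counts,
                         int anc_init, long max_gens, int reps) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    WFPop pop;
    pop.setup(R, aa, gamma, M, false);
    pop.init(anc_init);
    // overwrite state with the requested initial counts
    pop.cls.clear();
    for (int i = 0; i < 61; ++i) {
      pop.cnt61[i] = init_counts(i);
      pop.origin[i] = init_counts(i) > 0 ? (i == anc_init ? -1L : 0L) : LONG_MAX;
      if (init_counts(i) > 0) {
        Cls c; c.a = i; c.h = i; c.cnt = init_counts(i);
        pop.cls.push_back(c);
      }
    }
    out[r] = -1;
    for (long g = 0; g < max_gens; ++g) {
      pop.step();
      if (pop.cls.size() == 1 && pop.Ucopy[pop.cls[0].a] <= 0.0) {
        out[r] = pop.cls[0].a;
        break;
      }
    }
  }
  return out;
}
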