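#include <RcppArmadillo.h>
#include "dfemap.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Population-scaled mutation rate matrix (codon HKY85): off-diagonal entry
// (theta/2) kappa^[transition] / C for single-nucleotide neighbours, with C
// normalising the mean exit rate under the uniform codon distribution to
// theta/2.  nb and ts are 0/1 neighbour and transition indicator matrices.
static arma::mat mut_matrix_arma(double theta, double kappa,
                                 const arma::mat& nb, const arma::mat& ts) {
  arma::mat S = nb % (1.0 + (kappa - 1.0) * ts);
  double C = arma::accu(S) / S.n_rows;
  arma::mat R = (theta / (2.0 * C)) * S;
  R.diag() = -arma::sum(R, 1);
  return R;
}

// [[Rcpp::export]]
arma::mat cpp_mut_matrix(double theta, double kappa,
                         const arma::mat& nb, const arma::mat& ts) {
  return mut_matrix_arma(theta, kappa, nb, ts);
}

// Ancestor-tailored parent-independent (PIMS) rates from a parent-dependent
// generator R.  Off-ancestor rates: row A of the resolvent (I - m R)^-1 is
// the expected occupancy of a neutral lineage started at A after an
// Exp(mean m) coalescent path; rescaled so the off-ancestor total equals
// exit_scale * (-R[A,A]), the population-scaled (diffusion, 2 P Ne mu)
// total mutation rate away from A.  The ancestral allele's own rate is the
// scaled back-mutation flux into A, averaged over the occupancy of the
// non-ancestral states: in the two-allele sub-model this reproduces the
// exact stationary Beta law, and a parent-independent input is a fixed
// point of the construction.
static arma::mat pims_theta_arma(const arma::mat& R, double kernel_mean,
                                 double exit_scale) {
  const arma::uword K = R.n_rows;
  arma::mat res = arma::solve(arma::eye(K, K) - kernel_mean * R,
                              arma::eye(K, K));
  arma::mat Theta(K, K);
  for (arma::uword A = 0; A < K; ++A) {
    arma::rowvec q = res.row(A);
    if (q.min() <= 0.0)
      stop("resolvent produced a non-positive occupancy; generator invalid");
    double offmass = arma::accu(q) - q(A);
    double c = exit_scale * (-R(A, A)) / offmass;
    arma::rowvec th = c * q;
    double back = 0.0;
    for (arma::uword j = 0; j < K; ++j)
      if (j != A) back += (q(j) / offmass) * R(j, A);
    th(A) = exit_scale * back;
    Theta.row(A) = th;
  }
  return Theta;
}

// [[Rcpp::export]]
arma::mat cpp_pims_theta(const arma::mat& R, double kernel_mean,
                         double exit_scale) {
  return pims_theta_arma(R, kernel_mean, exit_scale);
}

// Log conditional sample likelihood log Pr(x | A, gamma) for one count
// pattern under every candidate ancestral codon A and each gamma level:
// Dirichlet-multinomial (ancestor-tailored PIMS rates) times the hot-or-not
// ancestral-conditioning 1F1 factor.  idx/cnt give the non-zero entries of
// the count vector (0-based codon indices).
static void tip_loglik_one(const arma::uvec& idx, const arma::vec& cnt,
                           const arma::mat& ThetaMat, const arma::ivec& aa,
                           const arma::vec& gammas, arma::mat& out,
                           arma::uword col0) {
  const arma::uword K = ThetaMat.n_rows, G = gammas.n_elem, m = idx.n_elem;
  double n = arma::accu(cnt);
  double lmult = std::lgamma(n + 1.0);
  for (arma::uword j = 0; j < m; ++j) lmult -= std::lgamma(cnt(j) + 1.0);
  for (arma::uword A = 0; A < K; ++A) {
    const arma::rowvec th = ThetaMat.row(A);
    double Theta = arma::accu(th);
    double ThetaA = 0.0;
    for (arma::uword k = 0; k < K; ++k)
      if (aa(k) == aa(A)) ThetaA += th(k);
    double ldm = lmult + std::lgamma(Theta) - std::lgamma(Theta + n);
    double XA = 0.0, xA = 0.0;
    for (arma::uword j = 0; j < m; ++j) {
      ldm += std::lgamma(th(idx(j)) + cnt(j)) - std::lgamma(th(idx(j)));
      if (aa(idx(j)) == aa(A)) XA += cnt(j);
      if (idx(j) == A) xA = cnt(j);
    }
    double XH = n - XA, TH = Theta - ThetaA;
    // within-cold-class ancestral weight: the ancestral allele itself (not
    // just its amino-acid class) is favoured by the neutral within-class
    // lottery, contributing (theta_A + x_A) Theta_A / ((Theta_A + X_A) theta_A)
    double lallele = std::log((th(A) + xA) * ThetaA) -
      std::log((ThetaA + XA) * th(A));
    for (arma::uword g = 0; g < G; ++g)
      out(A, col0 + g) = ldm + lallele + log_hotnot(XH, TH, n, Theta, gammas(g));
  }
}

// [[Rcpp::export]]
arma::mat cpp_tip_loglik(const arma::uvec& idx, const arma::vec& cnt,
                         const arma::mat& ThetaMat, const arma::ivec& aa,
                         const arma::vec& gammas) {
  arma::mat out(ThetaMat.n_rows, gammas.n_elem);
  tip_loglik_one(idx, cnt, ThetaMat, aa, gammas, out, 0);
  return out;
}

// Batch version over U count patterns (columns of a K x U matrix); returns a
// K x (U*G) matrix with pattern-major blocks of G columns.
// [[Rcpp::export]]
arma::mat cpp_tip_loglik_pats(const arma::mat& counts, const arma::mat& ThetaMat,
                              const arma::ivec& aa, const arma::vec& gammas) {
  const arma::uword K = ThetaMat.n_rows, U = counts.n_cols, G = gammas.n_elem;
  arma::mat out(K, U * G);
  for (arma::uword u = 0; u < U; ++u) {
    arma::uvec idx = arma::find(counts.col(u) > 0);
    arma::vec cnt = counts.col(u);
    tip_loglik_one(idx, cnt(idx), ThetaMat, aa, gammas, out, u * G);
  }
  return out;
}

// Whole-dataset log-likelihood of the single-population validation model:
// independent codon sites, one sample pattern and one ancestral codon per
// site.  Tbranch < 0 means the ancestor is the tip ancestor itself (known
// ancestry); Tbranch >= 0 sums over the tip ancestor with a phylogenetic
// transition matrix exp(Q * Tbranch) from the known root codon.
// counts: K x U unique patterns; pat/anc/wt: per unique (pattern, ancestor)
// pair, with multiplicity wt.
// [[Rcpp::export]]
double cpp_popgen_loglik(const arma::mat& counts, const arma::uvec& pat,
                         const arma::uvec& anc, const arma::vec& wt,
                         double theta, double kappa, double gamma,
                         double Tbranch, const arma::mat& nb,
                         const arma::mat& ts, const arma::ivec& aa,
                         double kernel_mean, double exit_scale) {
  const arma::uword K = nb.n_rows, U = counts.n_cols, P = pat.n_elem;
  arma::mat R = mut_matrix_arma(theta, kappa, nb, ts);
  arma::mat ThetaMat = pims_theta_arma(R, kernel_mean, exit_scale);
  arma::vec gv(1); gv(0) = gamma;
  double ll = 0.0;
  if (Tbranch < 0.0) {
    // known tip ancestry: evaluate only the needed (pattern, ancestor) pairs
    for (arma::uword p = 0; p < P; ++p) {
      arma::uword u = pat(p), A = anc(p);
      arma::uvec idx = arma::find(counts.col(u) > 0);
      arma::vec cntu = counts.col(u);
      arma::vec cnt = cntu(idx);
      double n = arma::accu(cnt);
      double lmult = std::lgamma(n + 1.0);
      for (arma::uword j = 0; j < idx.n_elem; ++j)
        lmult -= std::lgamma(cnt(j) + 1.0);
      const arma::rowvec th = ThetaMat.row(A);
      double Theta = arma::accu(th);
      double ThetaA = 0.0;
      for (arma::uword k = 0; k < K; ++k)
        if (aa(k) == aa(A)) ThetaA += th(k);
      double ldm = lmult + std::lgamma(Theta) - std::lgamma(Theta + n);
      double XA = 0.0, xA = 0.0;
      for (arma::uword j = 0; j < idx.n_elem; ++j) {
        ldm += std::lgamma(th(idx(j)) + cnt(j)) - std::lgamma(th(idx(j)));
        if (aa(idx(j)) == aa(A)) XA += cnt(j);
        if (idx(j) == A) xA = cnt(j);
      }
      double lallele = std::log((th(A) + xA) * ThetaA) -
        std::log((ThetaA + XA) * th(A));
      ll += wt(p) * (ldm + lallele +
                     log_hotnot(n - XA, Theta - ThetaA, n, Theta, gamma));
    }
  } else {
    // amino-acid-changing entries get the omega multiplier
    arma::mat Q = R;
    for (arma::uword i = 0; i < K; ++i)
      for (arma::uword j = 0; j < K; ++j)
        if (i != j && aa(i) != aa(j)) Q(i, j) *= omega_gamma(gamma);
    Q.diag().zeros();
    Q.diag() = -arma::sum(Q, 1);
    arma::mat Ptr = arma::expmat_sym(Q * Tbranch);
    arma::mat tip(K, U);
    for (arma::uword u = 0; u < U; ++u) {
      arma::uvec idx = arma::find(counts.col(u) > 0);
      arma::vec cnt = counts.col(u);
      arma::mat one(K, 1);
      tip_loglik_one(idx, cnt(idx), ThetaMat, aa, gv, one, 0);
      tip.col(u) = one.col(0);
    }
    for (arma::uword p = 0; p < P; ++p) {
      arma::vec lv = tip.col(pat(p));
      double mx = lv.max();
      double s = arma::dot(Ptr.row(anc(p)).t(), arma::exp(lv - mx));
      ll += wt(p) * (mx + std::log(s));
    }
  }
  return ll;
}
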