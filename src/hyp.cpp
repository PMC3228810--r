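#include <Rcpp.h>
#include <cmath>
#include "dfemap.h"

// Log-scale evaluation of the confluent hypergeometric function 1F1(a; b; z)
// in the parameter region the hot-or-not sampling model needs: a >= 0,
// b >= a, z in roughly [-600, 600].  All series below have non-negative
// terms, so plain summation with periodic rescaling is stable; negative
// arguments go through the Kummer transform 1F1(a;b;z) = e^z 1F1(b-a;b;-z).

static const double SCALE_HI = 1e280;
static const double REL_TOL = 1e-17;
static const int KMAX = 200000;

double log1f1(double a, double b, double z) {
  if (z == 0.0) return 0.0;
  if (z < 0.0) return z + log1f1(b - a, b, -z);
  double term = 1.0, sum = 1.0, logoff = 0.0;
  for (int k = 0; k < KMAX; ++k) {
    term *= (a + k) * z / ((b + k) * (k + 1.0));
    sum += term;
    if (sum > SCALE_HI) {
      term /= SCALE_HI; sum /= SCALE_HI; logoff += std::log(SCALE_HI);
    }
    if (k > z && term < sum * REL_TOL) break;
  }
  return logoff + std::log(sum);
}

// log(1F1(c; b; w) - 1) for w > 0, c > 0
double log1f1m1(double c, double b, double w) {
  double term = c / b * w;
  double sum = term, logoff = 0.0;
  for (int k = 1; k < KMAX; ++k) {
    term *= (c + k) * w / ((b + k) * (k + 1.0));
    sum += term;
    if (sum > SCALE_HI) {
      term /= SCALE_HI; sum /= SCALE_HI; logoff += std::log(SCALE_HI);
    }
    if (k > w && term < sum * REL_TOL) break;
  }
  return logoff + std::log(sum);
}

// log(e^z - 1F1(a; b; z)) for z > 0 and a < b.  Term-wise the difference is
// sum_k (1 - (a)_k/(b)_k) z^k / k!, every term non-negative.
double logediff(double a, double b, double z) {
  double u = 1.0, r = 1.0, sum = 0.0, logoff = 0.0;
  for (int k = 1; k < KMAX; ++k) {
    u *= z / k;
    r *= (a + k - 1.0) / (b + k - 1.0);
    sum += u * (1.0 - r);
    if (sum > SCALE_HI) {
      u /= SCALE_HI; sum /= SCALE_HI; logoff += std::log(SCALE_HI);
    }
    if (k > z && u < sum * REL_TOL) break;
  }
  return logoff + std::log(sum);
}

// Log of the ancestral-conditioning factor of the hot-or-not sampling
// distribution: [1F1(X_H+Theta_H; n+Theta; g) - e^g] /
//               [1F1(Theta_H;     Theta;   g) - e^g],
// with the g -> 0 removable singularity evaluated by its limit.
double log_hotnot(double XH, double TH, double n, double T, double gamma) {
  double XA = n - XH, TA = T - TH;
  if (gamma == 0.0)
    return std::log(T * (XA + TA)) - std::log(TA * (n + T));
  if (gamma > 0.0)
    return logediff(XH + TH, n + T, gamma) - logediff(TH, T, gamma);
  return log1f1m1(XA + TA, n + T, -gamma) - log1f1m1(TA, T, -gamma);
}

// Relative fixation rate omega(gamma) = gamma / (1 - exp(-gamma)).
double omega_gamma(double gamma) {
  if (gamma == 0.0) return 1.0;
  if (std::fabs(gamma) < 1e-8) return 1.0 + gamma / 2.0;
  return gamma / (1.0 - std::exp(-gamma));
}

// [[Rcpp::export]]
double cpp_log1f1(double a, double b, double z) {
  return log1f1(a, b, z);
}

// [[Rcpp::export]]
double cpp_log_hotnot(double XH, double TH, double n, double T, double gamma) {
  return log_hotnot(XH, TH, n, T, gamma);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_omega(Rcpp::NumericVector gamma) {
  int m = gamma.size();
  Rcpp::NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = omega_gamma(gamma[i]);
  return out;
}
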