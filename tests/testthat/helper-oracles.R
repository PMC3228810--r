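# Independent oracles shared across test files.

# Quadrature oracle for the collapsed two-class sampling distribution:
# P(X_A = m | A) by numerical integration over the Wright-Dirichlet
# stationary law (Beta with selection tilt) and the ancestral weight
# u(F_A) = (1 - exp(g F_A)) / (1 - exp(g)), via the Beta quantile
# transform so the integrand is bounded.
quad_class_prob <- function(m, n, TA, TH, gamma) {
  uw <- function(F) if (gamma == 0) F else (1 - exp(gamma * F)) / (1 - exp(gamma))
  Ebeta <- function(g) stats::integrate(function(u) {
    F <- stats::qbeta(u, TA, TH)
    g(F)
  }, 0, 1, rel.tol = 1e-11, subdivisions = 400L)$value
  num <- Ebeta(function(F) choose(n, m) * F^m * (1 - F)^(n - m) *
                 vapply(F, uw, 1) * exp(gamma * (1 - F)))
  den <- Ebeta(function(F) vapply(F, uw, 1) * exp(gamma * (1 - F)))
  num / den
}

# closed-form counterpart used by the package (class-level collapse)
closed_class_prob <- function(m, n, TA, TH, gamma) {
  Theta <- TA + TH
  exp(lchoose(n, m) + lbeta(TA + m, TH + n - m) - lbeta(TA, TH) +
        dfemap:::cpp_log_hotnot(n - m, TH, n, Theta, gamma))
}

# theoretical distribution of the ancestral-amino-acid class count in a
# sample of size n, averaged over a uniform ancestral codon
theory_class_count <- function(theta, kappa, gamma, n, kernel_mean = 2) {
  sp <- dfemap:::default_space()
  mut <- mutation_rate_matrix(theta, kappa)
  Tm <- dfemap:::pims_theta_matrix(mut, kernel_mean)
  p <- numeric(n + 1)
  for (A in 1:61) {
    th <- Tm[A, ]
    Theta <- sum(th)
    cold <- sp$aa_index == sp$aa_index[A]
    TA <- sum(th[cold])
    TH <- Theta - TA
    for (m in 0:n)
      p[m + 1] <- p[m + 1] + closed_class_prob(m, n, TA, TH, gamma) / 61
  }
  p
}

# empirical counterpart from the Wright-Fisher simulator
simulated_class_count <- function(theta, kappa, gamma, n, n_sites, M = 600,
                                  chains = max(1L, n_sites %/% 100L)) {
  sp <- dfemap:::default_space()
  res <- simulate_site(theta, kappa, gamma, n, n_sites, M = M, chains = chains)
  aa_s <- matrix(sp$aa_index[res$samples], n, n_sites)
  anc_aa <- sp$aa_index[res$ancestral]
  XA <- colSums(aa_s == matrix(anc_aa, n, n_sites, byrow = TRUE))
  tabulate(XA + 1, n + 1) / n_sites
}

# brute-force site likelihood for a star tree: explicit sum over the root
# codon, no pruning recursion
brute_force_site <- function(tree, tip_partials, Ps) {
  edge_sp <- dfemap:::star_branches(tree)
  tot <- 0
  for (s0 in 1:61) {
    term <- 1 / 61
    for (e in seq_len(nrow(tree$edge))) {
      s <- edge_sp[e]
      term <- term * sum(Ps[[e]][s0, ] * exp(tip_partials[[s]]))
    }
    tot <- tot + term
  }
  log(tot)
}

make_monomorphic_sample <- function(codon, n) {
  cnt <- integer(61)
  cnt[codon_index(codon)] <- n
  site_sample(cnt)
}
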