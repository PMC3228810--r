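#' Allele counts at one codon site in one population sample
#'
#' @param counts named integer vector (names are codons) or a full
#'   length-61 count vector in state-space order.
#' @param species_id optional label.
#' @param space a [codon_space()].
#' @return object of class `site_sample`: list with the length-61 integer
#'   `counts` vector and sample size `n`.
#' @export
site_sample <- function(counts, species_id = NA_character_,
                        space = default_space()) {
  K <- length(space$codons)
  x <- integer(K)
  if (!is.null(names(counts))) {
    idx <- codon_index(names(counts), space)
    if (anyNA(idx)) stop("stop codon or unknown codon in sample counts")
    x[idx] <- as.integer(counts)
  } else {
    stopifnot(length(counts) == K)
    x <- as.integer(counts)
  }
  if (any(x < 0) || sum(x) < 1L) stop("counts must be non-negative, n >= 1")
  structure(list(counts = x, n = sum(x), species_id = species_id),
            class = "site_sample")
}

#' Log of the confluent hypergeometric function 1F1(a; b; z)
#'
#' Log-scale evaluation accurate over the parameter region the sampling
#' model uses (`a > 0`, `b >= a`, `z` in roughly \[-600, 600\]); negative
#' arguments are routed through the Kummer transform
#' `1F1(a;b;z) = exp(z) 1F1(b-a;b;-z)` so every series summed has
#' non-negative terms.
#'
#' @param a,b,z numeric scalars.
#' @return `log(1F1(a; b; z))`.
#' @export
log_1f1 <- function(a, b, z) {
  stopifnot(is.finite(a), is.finite(b), is.finite(z), a > 0, b >= a)
  cpp_log1f1(a, b, z)
}

#' Ancestor-tailored parent-independent mutation rates
#'
#' Approximates the parent-dependent codon mutation process by a
#' parent-independent (PIMS) one tailored to the ancestral background A: the
#' per-allele rate is proportional to the expected occupancy of a neutral
#' lineage started at A after an exponentially distributed coalescent path
#' (the resolvent of the neutral generator), rescaled so that the
#' off-ancestor total equals the population-scaled (2*P*Ne*mu) mutation rate
#' away from A.  The resulting vector parameterises the Wright-Dirichlet
#' stationary law used by the conditional sample likelihood.
#'
#' @param mut a [mutation_rate_matrix()].
#' @param ancestor codon string or index of the ancestral allele.
#' @param kernel_mean mean of the exponential coalescent-path kernel in
#'   P*Ne generations (default 2: two lineages separated by an average
#'   pairwise coalescent time accumulate mutations along both).
#' @return object of class `pims_rates`: list with `theta` (length-61
#'   positive rates), `ancestor` (index), and total `Theta`.
#' @export
pims_rates_for_ancestor <- function(mut, ancestor, kernel_mean = 2) {
  stopifnot(inherits(mut, "mutation_matrix"))
  A <- if (is.character(ancestor)) codon_index(ancestor, mut$space) else as.integer(ancestor)
  stopifnot(length(A) == 1L, !is.na(A), A >= 1, A <= nrow(mut$rates))
  Theta <- pims_theta_matrix(mut, kernel_mean)
  th <- Theta[A, ]
  structure(list(theta = th, ancestor = A, Theta = sum(th)),
            class = "pims_rates")
}

# all 61 ancestor-tailored rows at once (one resolvent solve)
pims_theta_matrix <- function(mut, kernel_mean = 2) {
  cpp_pims_theta(mut$rates, kernel_mean, 2)
}

#' Conditional sample likelihood given the ancestral allele
#'
#' Probability of the observed allele counts at a codon site given the
#' ancestral codon A, the selection coefficient gamma of derived
#' amino-acid-changing ("hot") alleles, and ancestor-tailored PIMS rates:
#' a Dirichlet-multinomial times the hot-or-not ancestral-conditioning
#' factor
#' \deqn{\frac{{}_1F_1(X_H+\Theta_H;\, n+\Theta;\, \gamma) - e^\gamma}
#'            {{}_1F_1(\Theta_H;\, \Theta;\, \gamma) - e^\gamma},}
#' where \eqn{X_A,\Theta_A} are the sample count and total mutation rate of
#' alleles encoding the ancestral amino acid and \eqn{X_H = n - X_A},
#' \eqn{\Theta_H = \Theta - \Theta_A}.  At gamma = 0 the factor is evaluated
#' by its limit \eqn{\Theta(X_A+\Theta_A) / (\Theta_A (n+\Theta))}.
#'
#' @param x a [site_sample()].
#' @param ancestor codon string or index.
#' @param gamma selection coefficient.
#' @param rates a [pims_rates_for_ancestor()] tailored to `ancestor`; built
#'   from `mut` if missing.
#' @param mut a [mutation_rate_matrix()] (used when `rates` is missing).
#' @param log return the log likelihood.
#' @param space a [codon_space()].
#' @return scalar probability (or log probability).
#' @export
conditional_sample_likelihood <- function(x, ancestor, gamma, rates = NULL,
                                          mut = NULL, log = FALSE,
                                          space = default_space()) {
  stopifnot(inherits(x, "site_sample"))
  A <- if (is.character(ancestor)) codon_index(ancestor, space) else as.integer(ancestor)
  if (is.null(rates)) {
    if (is.null(mut)) stop("supply either tailored rates or a mutation matrix")
    rates <- pims_rates_for_ancestor(mut, A)
  }
  if (rates$ancestor != A) stop("rates are tailored to a different ancestor")
  th <- rates$theta
  n <- x$n
  idx <- which(x$counts > 0)
  cnt <- x$counts[idx]
  Theta <- sum(th)
  cold <- space$aa_index == space$aa_index[A]
  ThetaA <- sum(th[cold])
  XA <- sum(cnt[cold[idx]])
  xA <- x$counts[A]
  ldm <- lgamma(n + 1) - sum(lgamma(cnt + 1)) +
    lgamma(Theta) - lgamma(Theta + n) +
    sum(lgamma(th[idx] + cnt) - lgamma(th[idx]))
  # within-cold-class weight: the ancestral allele itself is favoured by the
  # neutral within-class lottery
  lallele <- log((th[A] + xA) * ThetaA) - log((ThetaA + XA) * th[A])
  ll <- ldm + lallele + cpp_log_hotnot(n - XA, Theta - ThetaA, n, Theta,
                                       as.numeric(gamma))
  if (log) ll else exp(ll)
}
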