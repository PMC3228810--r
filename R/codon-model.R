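#' Population-scaled codon mutation rate matrix
#'
#' Codon-level analogue of the HKY85 nucleotide model.  The rate from codon i
#' to a single-nucleotide neighbour j is `(theta/2) * kappa^[transition] / C`,
#' zero for non-neighbours, and the diagonal is set so rows sum to zero.  The
#' normaliser C is chosen so that the mean total mutation rate under the
#' uniform codon distribution equals `theta/2` per P*Ne generations.
#' Mutations into stop codons do not exist in the state space and do not
#' enter C.
#'
#' @param theta population-scaled per-codon mutation rate, 2*P*Ne*mu.
#' @param kappa transition:transversion ratio.
#' @param space a [codon_space()].
#' @return An object of class `mutation_matrix`: list with the 61 x 61 `rates`
#'   generator, `theta`, `kappa` and the normaliser `C`.
#' @examples
#' mut <- mutation_rate_matrix(0.1, 2)
#' mean(-diag(mut$rates))   # theta / 2
#' @export
mutation_rate_matrix <- function(theta, kappa, space = default_space()) {
  if (!is.numeric(theta) || theta <= 0) stop("theta must be positive")
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be positive")
  S <- space$neighbor * (1 + (kappa - 1) * space$transition)
  C <- sum(S) / nrow(S)
  rates <- theta / (2 * C) * S
  diag(rates) <- -rowSums(rates)
  structure(list(rates = rates, theta = theta, kappa = kappa, normalizer = C,
                 space = space),
            class = "mutation_matrix")
}

#' Relative fixation rate of a selected mutation
#'
#' `omega(gamma) = gamma / (1 - exp(-gamma))`, the rate of substitution of a
#' mutation with population-scaled selection coefficient gamma relative to a
#' neutral mutation; equals the dN/dS rate multiplier of phylogenetic codon
#' models.  The removable singularity at gamma = 0 evaluates to 1.
#'
#' @param gamma numeric vector of population-scaled selection coefficients
#'   (2*P*Ne*s).
#' @return numeric vector of rate multipliers.
#' @examples
#' omega(0)        # 1
#' omega(2)        # 2.3130...
#' omega(-500)     # effectively 0: inviable
#' @export
omega <- function(gamma) {
  stopifnot(is.numeric(gamma), all(is.finite(gamma)))
  cpp_omega(as.numeric(gamma))
}

#' Phylogenetic substitution rate matrix under recurrent selection
#'
#' Multiplies the amino-acid-changing entries of the mutation generator by
#' `omega(gamma)`; synonymous entries are untouched.  The resulting process
#' is the Nielsen-Yang codon substitution model with uniform stationary
#' distribution over the 61 sense codons (the mutation process carries no
#' base-composition parameters, and under recurrent selection the
#' equilibrium frequencies are independent of gamma).  Time is measured in
#' units of P*Ne generations.
#'
#' @param mut a [mutation_rate_matrix()].
#' @param gamma population-scaled selection coefficient of amino-acid-changing
#'   mutations.
#' @return An object of class `substitution_model`: list with the 61 x 61
#'   rate matrix `Q`, `omega`, `gamma`, and the stationary distribution `pi`
#'   (uniform).
#' @export
substitution_rate_matrix <- function(mut, gamma) {
  stopifnot(inherits(mut, "mutation_matrix"), is.numeric(gamma),
            length(gamma) == 1L, is.finite(gamma))
  sp <- mut$space
  w <- omega(gamma)
  nonsyn <- outer(sp$aa_index, sp$aa_index, "!=")
  Q <- mut$rates
  diag(Q) <- 0
  Q[nonsyn] <- Q[nonsyn] * w
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, omega = w, gamma = gamma,
                 pi = rep(1 / nrow(Q), nrow(Q)), space = sp),
            class = "substitution_model")
}

#' Transition probability matrix over a branch
#'
#' Exponentiates the substitution rate matrix: `P(v) = exp(Q v)`.  Q is
#' symmetric (reversible with respect to the uniform stationary
#' distribution), so the exponential is computed from a symmetric
#' eigendecomposition.
#'
#' @param model a [substitution_rate_matrix()] or a plain symmetric rate
#'   matrix.
#' @param v branch length in P*Ne generations; must be non-negative.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, v) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (v < 0) stop("negative branch length")
  Q <- if (inherits(model, "substitution_model")) model$Q else model
  e <- eigen(Q, symmetric = TRUE)
  P <- e$vectors %*% (exp(v * e$values) * t(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
  }

# eigendecomposition reused across branch-length scalings: P(t) for
# Q = theta * A is V exp(theta * t * D) V'
eigen_cache_expm <- function(eA, t) {
  P <- eA$vectors %*% (exp(t * eA$values) * t(eA$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}
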