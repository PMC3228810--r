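#' Tip partial likelihood vector for a population sample
#'
#' The extended pruning algorithm replaces the 0/1 tip indicators of
#' classical phylogenetic likelihood with the conditional sample likelihood:
#' entry s is the probability of the observed allele counts given that codon
#' s was ancestral in the sampled population.  Even a single sequence gives
#' a non-degenerate vector, because the sequence may carry a derived allele.
#'
#' @param sample a [site_sample()].
#' @param mut the branch/locus [mutation_rate_matrix()].
#' @param gamma selection coefficient at this site on this branch.
#' @param theta_matrix optional precomputed 61 x 61 ancestor-tailored PIMS
#'   rate matrix (row A = rates tailored to ancestor A); computed from `mut`
#'   if missing.
#' @return length-61 vector of log likelihoods, one per candidate ancestor.
#' @export
tip_partial <- function(sample, mut, gamma, theta_matrix = NULL) {
  stopifnot(inherits(sample, "site_sample"))
  sp <- mut$space
  if (is.null(theta_matrix)) theta_matrix <- pims_theta_matrix(mut)
  idx <- which(sample$counts > 0)
  drop(cpp_tip_loglik(idx - 1L, as.numeric(sample$counts[idx]), theta_matrix,
                      sp$aa_index, as.numeric(gamma)))
}

#' Site log-likelihood by pruning
#'
#' Felsenstein's pruning recursion over a rooted (or trifurcating-root,
#' i.e. unrooted) tree whose tips carry population samples: tip partials are
#' conditional sample likelihood vectors, internal nodes combine children
#' through per-branch transition matrices, and the root sums over the
#' ancestral codon under `root_prior`.  Per-node log-scaling guards against
#' underflow.
#'
#' @param tree an `ape::phylo` object.
#' @param tip_partials named list (by tip label) of length-61 log-likelihood
#'   vectors.
#' @param transition_matrices list of 61 x 61 matrices, one per row of
#'   `tree$edge` (the matrix for the branch above the child node of that
#'   edge).
#' @param root_prior probability vector over the 61 codons at the root
#'   (default uniform, the stationary distribution of the recurrent
#'   selection process).
#' @return the site log-likelihood.
#' @export
prune_site <- function(tree, tip_partials, transition_matrices,
                       root_prior = NULL) {
  K <- length(tip_partials[[1]])
  if (is.null(root_prior)) root_prior <- rep(1 / K, K)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  logv <- matrix(NA_real_, K, nnode)  # scaled partials (linear scale)
  off <- numeric(nnode)               # log-scale offsets
  # tip partials
  for (i in seq_len(ntip)) {
    lab <- tree$tip.label[i]
    lv <- tip_partials[[lab]]
    if (is.null(lv)) stop("missing tip partial for ", lab)
    if (all(!is.finite(lv))) stop("all-zero partial: inconsistent inputs")
    m <- max(lv)
    logv[, i] <- exp(lv - m)
    off[i] <- m
  }
  # postorder: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  ed <- po$edge
  for (k in seq_len(nrow(ed))) {
    e <- perm[k]
    par <- ed[k, 1]; chi <- ed[k, 2]
    if (anyNA(logv[, chi])) stop("tree edges out of order")
    if (anyNA(logv[, par])) { logv[, par] <- 1; off[par] <- 0 }
    w <- transition_matrices[[e]] %*% logv[, chi]
    if (all(w == 0)) stop("all-zero partial: inconsistent inputs")
    logv[, par] <- logv[, par] * w
    m <- max(logv[, par])
    logv[, par] <- logv[, par] / m
    off[par] <- off[par] + off[chi] + log(m)
  }
  lik <- sum(root_prior * logv[, root])
  log(lik) + off[root]
}

# verify that every edge of the tree hangs a tip directly off the root and
# return the edge -> tip-label map (the unrooted star used for the
# three-taxon analysis)
star_branches <- function(tree) {
  ed <- tree$edge
  ntip <- length(tree$tip.label)
  if (tree$Nnode != 1L || any(ed[, 1] != ntip + 1L) || any(ed[, 2] > ntip))
    stop("tree must be a star: every species adjacent to one internal node")
  tree$tip.label[ed[, 2]]
}

#' Locus log-likelihood
#'
#' Sum of [prune_site()] over the codon sites of a locus, with per-branch
#' mutation parameters and a per-branch, per-site selection coefficient.
#' Sites are independent.
#'
#' @param locus a `locus_dataset` (see [read_locus()] or
#'   [simulate_dataset()]).
#' @param tree star `ape::phylo` whose tip labels are the species.
#' @param branch_params named list (by species) of lists with elements
#'   `theta`, `kappa` and `T` (branch length in P*Ne generations).
#' @param gamma either a single selection coefficient, or a named list (by
#'   species) of per-site vectors.
#' @param kernel_mean coalescent kernel mean for the PIMS approximation.
#' @param space a [codon_space()].
#' @return scalar log-likelihood.
#' @export
locus_log_likelihood <- function(locus, tree, branch_params, gamma = 0,
                                 kernel_mean = 2, space = default_space()) {
  L <- locus$n_codons
  if (L == 0L) return(0)
  edge_sp <- star_branches(tree)
  K <- length(space$codons)
  per_site_gamma <- function(spp) {
    if (is.list(gamma)) gamma[[spp]] else rep(gamma, L)
  }
  # per-branch machinery
  machinery <- lapply(tree$tip.label, function(spp) {
    bp <- branch_params[[spp]]
    if (is.null(bp)) stop("missing branch parameters for ", spp)
    mut <- mutation_rate_matrix(bp$theta, bp$kappa, space)
    list(mut = mut, Tm = pims_theta_matrix(mut, kernel_mean), T = bp$T,
         g = per_site_gamma(spp))
  })
  names(machinery) <- tree$tip.label
  total <- 0
  for (j in seq_len(L)) {
    tps <- list()
    Ps <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      spp <- edge_sp[e]
      mc <- machinery[[spp]]
      cnts <- species_site_counts(locus, spp, j, K)
      smp <- site_sample(cnts, species_id = spp, space = space)
      tps[[spp]] <- tip_partial(smp, mc$mut, mc$g[j], mc$Tm)
      Q <- substitution_rate_matrix(mc$mut, mc$g[j])
      Ps[[e]] <- transition_probabilities(Q, mc$T)
    }
    total <- total + prune_site(tree, tps, Ps)
  }
  total
}

# length-61 count vector for one species at one site
species_site_counts <- function(locus, species, j, K = 61L) {
  m <- locus$species[[species]]
  if (is.null(m)) stop("species not in locus: ", species)
  tabulate(m[, j], nbins = K)
}
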