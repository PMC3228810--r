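#' Simulate codon sites under the Wright-Fisher hot-or-not model
#'
#' Forward haploid Wright-Fisher simulation of independent codon sites with
#' recurrent selection: derived alleles encoding an amino acid different
#' from the tracked ancestral allele share the population-scaled advantage
#' gamma.  M gene copies represent one unit of P*Ne generations; per-copy
#' mutation probabilities are the population-scaled rates divided by M, so
#' the diffusion limit matches the Wright-Dirichlet theory of the
#' likelihood.  The ancestral identity is reported under one of three
#' operational definitions; the selection regime itself re-anchors on the
#' oldest segregating allele, the definition under which the conditional
#' sampling theory holds.
#'
#' @param theta population-scaled per-codon mutation rate.
#' @param kappa transition:transversion ratio.
#' @param gamma population-scaled selection coefficient.
#' @param n sample size (gene copies drawn multinomially at the end).
#' @param n_sites number of sites to return.
#' @param M population size in gene copies.
#' @param burn burn-in generations per chain (default `20 * M`).
#' @param ancestry_definition `"oldest"` (oldest segregating allele, the
#'   theory's definition), `"last_fixed"`, or `"mrca"` (allele at the most
#'   recent whole-population common-ancestor checkpoint).
#' @param lag generations between recording the ancestral identity and
#'   sampling (e.g. `10 * M` records the ancestor 10 P*Ne generations
#'   before sampling).
#' @param chains number of independent chains; when smaller than
#'   `n_sites`, consecutive sites on a chain are taken `spacing`
#'   generations apart (cheaper, mildly autocorrelated).
#' @param spacing generations between records on one chain.
#' @param space a [codon_space()].
#' @return list with `samples` (n x n_sites matrix of 1-based codon
#'   indices) and `ancestral` (length n_sites, 1-based codon index of the
#'   recorded ancestor).
#' @export
simulate_site <- function(theta, kappa, gamma, n, n_sites = 1, M = 2000,
                          burn = 20 * M,
                          ancestry_definition = c("oldest", "last_fixed", "mrca"),
                          lag = 0, chains = n_sites,
                          spacing = ceiling(M / 2),
                          space = default_space()) {
  ancestry_definition <- match.arg(ancestry_definition)
  def <- match(ancestry_definition, c("last_fixed", "mrca", "oldest")) - 1L
  mut <- mutation_rate_matrix(theta, kappa, space)
  records <- ceiling(n_sites / chains)
  res <- cpp_wf_sites(mut$rates, space$aa_index, gamma, M, chains, burn,
                      records, spacing, lag, n, def, -1L)
  keep <- seq_len(n_sites)
  list(samples = res$samples[, keep, drop = FALSE] + 1L,
       ancestral = res$ancestor[keep] + 1L)
}

#' Fixation outcomes from explicit starting frequencies
#'
#' Runs replicate Wright-Fisher populations from given initial allele
#' counts until fixation and reports the fixed codon; used to check the
#' simulator against diffusion theory (neutral fixation probability equals
#' initial frequency; selected fixation probability follows
#' `(1 - exp(-gamma q)) / (1 - exp(-gamma))`).
#'
#' @param counts named vector of initial copy numbers (names are codons);
#'   must sum to `M`.
#' @param ancestor codon the hot class is defined against.
#' @param gamma selection coefficient.
#' @param M population size in copies.
#' @param theta mutation rate (0 disables mutation so fixation is final).
#' @param kappa transition:transversion ratio.
#' @param reps replicates.
#' @param max_gens cap on generations per replicate.
#' @param space a [codon_space()].
#' @return character vector of fixed codons (`NA` if unresolved).
#' @export
wf_fixation <- function(counts, ancestor, gamma, M = sum(counts), theta = 0,
                        kappa = 1, reps = 1000, max_gens = 100L * M,
                        space = default_space()) {
  stopifnot(sum(counts) == M)
  init <- integer(length(space$codons))
  init[codon_index(names(counts), space)] <- as.integer(counts)
  R <- if (theta > 0) mutation_rate_matrix(theta, kappa, space)$rates
  else matrix(0, length(space$codons), length(space$codons))
  A <- codon_index(ancestor, space)
  fx <- cpp_wf_fix(R, space$aa_index, gamma, M, init, A - 1L, max_gens, reps)
  out <- rep(NA_character_, reps)
  out[fx >= 0] <- space$codons[fx[fx >= 0] + 1L]
  out
}

#' Draw validation parameters
#'
#' Log-uniform draws of theta and kappa over the validation ranges
#' (theta 0.02-0.2 per codon, kappa 0.05-20) and a normal draw of gamma
#' centred on zero with standard deviation `gamma_sd`.
#'
#' @param gamma_sd standard deviation of the gamma draw (default 10).
#' @return list with `theta`, `kappa`, `gamma`.
#' @export
draw_validation_params <- function(gamma_sd = 10) {
  list(theta = exp(stats::runif(1, log(0.02), log(0.2))),
       kappa = exp(stats::runif(1, log(0.05), log(20))),
       gamma = stats::rnorm(1, 0, gamma_sd))
}

#' Simulate a codon-alignment dataset with known truth
#'
#' Generates validation datasets under three scenarios:
#' \describe{
#'   \item{known_ancestor}{one population sampled at stationarity; the true
#'     ancestral codon (oldest segregating allele) is recorded at sampling
#'     time, testing the conditional allele-frequency model alone.}
#'   \item{lagged_ancestor}{the ancestral codon is recorded `lag_PNe` P*Ne
#'     generations before sampling, additionally testing the phylogenetic
#'     transition model and the extended pruning over tip ancestry.}
#'   \item{three_taxon}{a uniform root codon per site; three populations
#'     evolve independently along branches of length `T` P*Ne generations
#'     with branch-specific parameters, and are sampled at the tips.}
#' }
#'
#' @param scenario one of `"known_ancestor"`, `"lagged_ancestor"`,
#'   `"three_taxon"`.
#' @param n_seqs sequences per population (vector per species for
#'   `three_taxon`).
#' @param L locus length in codons.
#' @param theta,kappa,gamma parameters of the single population for the
#'   first two scenarios; `gamma` may be a per-site vector.
#' @param branch_params for `three_taxon`: named list per species of lists
#'   with `theta`, `kappa`, `T`, and `gamma` (scalar or per-site).
#' @param ancestral for `three_taxon`: list with `theta`, `kappa`, `gamma`
#'   of the stationary ancestral population the branches fork from
#'   (default: the first branch's mutation parameters, neutral selection).
#'   Branch populations inherit the full ancestral state, standing
#'   variation included; the recorded root codon is the oldest segregating
#'   allele at the split.
#' @param M population size in gene copies.
#' @param burn burn-in generations.
#' @param lag_PNe ancestor-recording lag for `lagged_ancestor`, in P*Ne
#'   generations (default 10).
#' @param locus_id identifier stored in the dataset.
#' @param space a [codon_space()].
#' @return object of class `sim_dataset`: list with `locus` (a
#'   `locus_dataset` whose species matrices hold 1-based codon indices),
#'   `truth` (data.frame per codon: the generating gamma and ancestral
#'   codon per branch), and `params`.
#' @export
simulate_dataset <- function(scenario = c("known_ancestor", "lagged_ancestor",
                                          "three_taxon"),
                             n_seqs = 30, L = 250, theta = 0.1, kappa = 2,
                             gamma = 0, branch_params = NULL,
                             ancestral = NULL, M = 1000,
                             burn = 20 * M, lag_PNe = 10,
                             locus_id = "locus1", space = default_space()) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("known_ancestor", "lagged_ancestor")) {
    gvec <- rep_len(gamma, L)
    if (length(unique(gvec)) > 1L) {
      # per-site gamma: simulate each distinct value separately
      samples <- matrix(0L, n_seqs, L)
      anc <- integer(L)
      for (g in unique(gvec)) {
        jj <- which(gvec == g)
        res <- simulate_site(theta, kappa, g, n_seqs, length(jj), M, burn,
                             ancestry_definition = "oldest",
                             lag = if (scenario == "lagged_ancestor") round(lag_PNe * M) else 0,
                             space = space)
        samples[, jj] <- res$samples
        anc[jj] <- res$ancestral
      }
    } else {
      res <- simulate_site(theta, kappa, gvec[1], n_seqs, L, M, burn,
                           ancestry_definition = "oldest",
                           lag = if (scenario == "lagged_ancestor") round(lag_PNe * M) else 0,
                           space = space)
      samples <- res$samples
      anc <- res$ancestral
    }
    locus <- new_locus_dataset(locus_id, list(pop = samples), space)
    truth <- data.frame(codon = seq_len(L), gamma = gvec,
                        ancestral = space$codons[anc])
    params <- list(scenario = scenario, theta = theta, kappa = kappa,
                   gamma = gamma, M = M, burn = burn,
                   lag_PNe = if (scenario == "lagged_ancestor") lag_PNe else 0)
  } else {
    stopifnot(!is.null(branch_params))
    spp <- names(branch_params)
    n_seqs <- rep_len(n_seqs, length(spp))
    names(n_seqs) <- spp
    if (is.null(ancestral))
      ancestral <- list(theta = branch_params[[1]]$theta,
                        kappa = branch_params[[1]]$kappa, gamma = 0)
    mut_anc <- mutation_rate_matrix(ancestral$theta, ancestral$kappa, space)
    Rbr <- lapply(branch_params, function(bp)
      mutation_rate_matrix(bp$theta, bp$kappa, space)$rates)
    gmat <- vapply(branch_params, function(bp) rep_len(bp$gamma, L),
                   numeric(L))
    Tg <- vapply(branch_params, function(bp) as.integer(round(bp$T * M)),
                 integer(1))
    res <- cpp_wf_three(mut_anc$rates, space$aa_index, ancestral$gamma,
                        unname(Rbr), gmat, Tg, as.integer(n_seqs), M,
                        burn, 2L, L)
    mats <- list()
    truth <- data.frame(codon = seq_len(L),
                        root = space$codons[res$root + 1L])
    for (b in seq_along(spp)) {
      s <- spp[b]
      mats[[s]] <- res$samples[[b]] + 1L
      truth[[paste0("gamma_", s)]] <- gmat[, b]
      truth[[paste0("ancestral_", s)]] <- space$codons[res$tip_ancestor[, b] + 1L]
    }
    locus <- new_locus_dataset(locus_id, mats, space)
    params <- list(scenario = scenario, branch_params = branch_params,
                   ancestral = ancestral, M = M, burn = burn)
  }
  structure(list(locus = locus, truth = truth, params = params,
                 scenario = scenario),
            class = "sim_dataset")
}
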