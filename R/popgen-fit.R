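#' Bayesian fit of the single-population codon model
#'
#' Posterior sampling of (theta, kappa, gamma) for one population sample of
#' codon sites with known ancestry, the design used to validate the
#' conditional allele-frequency model: all sites share one selection
#' coefficient, and the ancestral codon of each site is either known at
#' sampling time (`T = NULL`) or was recorded `T` P*Ne generations earlier,
#' in which case the likelihood sums over the tip ancestor through the
#' phylogenetic transition matrix (one-branch extended pruning).
#'
#' Priors: log-uniform on theta and kappa truncated to
#' `[1e-4, 1e4]` (for propriety), normal with standard deviation
#' `gamma_prior_sd` on gamma.  Sampling is componentwise random-walk
#' Metropolis with log-scale walks for theta and kappa; proposal scales
#' adapt towards ~30% acceptance during burn-in only.
#'
#' @param samples n x L matrix of 1-based codon indices (one row per
#'   sequence), or a `sim_dataset`.
#' @param ancestral length-L vector of 1-based ancestral codon indices (or
#'   codon strings); taken from the dataset truth when `samples` is a
#'   `sim_dataset`.
#' @param T branch length (P*Ne generations) separating the recorded
#'   ancestor from the sampled population; `NULL` for known tip ancestry.
#' @param iterations,burn_in,thin MCMC schedule (totals include burn-in).
#' @param gamma_prior_sd standard deviation of the normal prior on gamma.
#' @param kernel_mean coalescent kernel mean of the PIMS approximation.
#' @param init optional named list of starting values.
#' @param space a [codon_space()].
#' @return object of class `popgen_fit`: list with `samples` (retained
#'   draws of theta, kappa, gamma), `estimates` (mean and 95% interval per
#'   parameter), `accept` rates and the call configuration.
#' @export
popgen_fit <- function(samples, ancestral = NULL, T = NULL,
                       iterations = 6000, burn_in = 1500, thin = 2,
                       gamma_prior_sd = 10, kernel_mean = 2, init = NULL,
                       space = default_space()) {
  if (inherits(samples, "sim_dataset")) {
    ds <- samples
    samples <- ds$locus$species[[1]]
    ancestral <- codon_index(ds$truth$ancestral, space)
    if (is.null(T) && identical(ds$scenario, "lagged_ancestor"))
      T <- ds$params$lag_PNe
  }
  if (is.character(ancestral)) ancestral <- codon_index(ancestral, space)
  L <- ncol(samples)
  stopifnot(length(ancestral) == L, !anyNA(ancestral))
  K <- length(space$codons)
  # unique (pattern, ancestor) pairs with multiplicity
  cnts <- apply(samples, 2, tabulate, nbins = K)        # K x L
  key <- apply(cnts, 2, paste, collapse = ",")
  upat <- match(key, unique(key))
  counts <- cnts[, !duplicated(key), drop = FALSE]
  pairkey <- paste(upat, ancestral)
  uu <- !duplicated(pairkey)
  pat <- upat[uu]; anc <- ancestral[uu]
  wt <- as.numeric(table(factor(pairkey, levels = pairkey[uu])))
  nb <- space$neighbor; ts <- space$transition
  Tb <- if (is.null(T)) -1 else as.numeric(T)
  loglik <- function(th, ka, ga) {
    cpp_popgen_loglik(counts, pat - 1L, anc - 1L, wt, th, ka, ga, Tb,
                      nb, ts, space$aa_index, kernel_mean, 2)
  }
  logprior <- function(lth, lka, ga) {
    if (abs(lth) > log(1e4) || abs(lka) > log(1e4)) return(-Inf)
    stats::dnorm(ga, 0, gamma_prior_sd, log = TRUE)
  }
  # crude initial values
  pseg <- mean(apply(samples, 2, function(v) length(unique(v)) > 1))
  st <- list(theta = max(0.01, pseg / log(nrow(samples) + 1)), kappa = 1,
             gamma = 0)
  if (!is.null(init)) st[names(init)] <- init
  lth <- log(st$theta); lka <- log(st$kappa); ga <- st$gamma
  lp <- loglik(exp(lth), exp(lka), ga) + logprior(lth, lka, ga)
  scales <- c(0.25, 0.4, 1.5)
  acc <- n_try <- c(theta = 0, kappa = 0, gamma = 0)
  keep <- seq(burn_in + thin, iterations, by = thin)
  out <- matrix(NA_real_, length(keep), 3,
                dimnames = list(NULL, c("theta", "kappa", "gamma")))
  row <- 0L
  for (it in seq_len(iterations)) {
    for (par in 1:3) {
      prop <- c(lth, lka, ga)
      prop[par] <- prop[par] + stats::rnorm(1, 0, scales[par])
      lpp <- logprior(prop[1], prop[2], prop[3])
      if (is.finite(lpp)) lpp <- lpp + loglik(exp(prop[1]), exp(prop[2]), prop[3])
      n_try[par] <- n_try[par] + 1
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        lth <- prop[1]; lka <- prop[2]; ga <- prop[3]; lp <- lpp
        acc[par] <- acc[par] + 1
      }
      # light adaptation during burn-in
      if (it <= burn_in && it %% 50 == 0) {
        r <- acc[par] / max(1, n_try[par])
        scales[par] <- scales[par] * exp(0.5 * (r - 0.3))
        acc[par] <- n_try[par] <- 0
      }
    }
    if (it %in% keep) {
      row <- row + 1L
      out[row, ] <- c(exp(lth), exp(lka), ga)
    }
  }
  est <- t(apply(out, 2, posterior_point_and_interval))
  structure(list(samples = out, estimates = est,
                 accept = acc / pmax(1, n_try),
                 config = list(iterations = iterations, burn_in = burn_in,
                               thin = thin, T = T,
                               gamma_prior_sd = gamma_prior_sd)),
            class = "popgen_fit")
}

#' @export
print.popgen_fit <- function(x, ...) {
  cat("Single-population codon model fit (",
      nrow(x$samples), " retained draws)\n", sep = "")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Credible-interval coverage over simulated datasets
#'
#' Simulates `n_datasets` independent datasets with parameters drawn by
#' [draw_validation_params()], fits each with [popgen_fit()], and reports
#' the fraction of datasets whose 95% credible interval covers the true
#' value, per parameter.
#'
#' @param n_datasets number of replicate datasets.
#' @param scenario `"known_ancestor"` or `"lagged_ancestor"`.
#' @param n_seqs,L dataset dimensions.
#' @param M simulator population size.
#' @param iterations,burn_in MCMC schedule per fit.
#' @param gamma_sd standard deviation of the generating (and prior) gamma
#'   distribution.
#' @param quiet suppress progress output.
#' @return list with `coverage` (named fraction per parameter), `table`
#'   (per-dataset truth, estimates and coverage flags).
#' @export
validation_coverage <- function(n_datasets = 20,
                                scenario = c("known_ancestor", "lagged_ancestor"),
                                n_seqs = 30, L = 250, M = 1000,
                                iterations = 4000, burn_in = 1000,
                                gamma_sd = 10, quiet = TRUE) {
  scenario <- match.arg(scenario)
  rows <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    pr <- draw_validation_params(gamma_sd)
    ds <- simulate_dataset(scenario, n_seqs = n_seqs, L = L,
                           theta = pr$theta, kappa = pr$kappa,
                           gamma = pr$gamma, M = M)
    fit <- popgen_fit(ds, iterations = iterations, burn_in = burn_in,
                      gamma_prior_sd = gamma_sd)
    e <- fit$estimates
    rows[[d]] <- data.frame(
      dataset = d, parameter = rownames(e),
      truth = c(pr$theta, pr$kappa, pr$gamma),
      mean = e[, "mean"], lower = e[, "lower"], upper = e[, "upper"],
      covered = c(pr$theta, pr$kappa, pr$gamma) >= e[, "lower"] &
        c(pr$theta, pr$kappa, pr$gamma) <= e[, "upper"])
    if (!quiet) message("dataset ", d, " done")
  }
  tab <- do.call(rbind, rows)
  cov <- tapply(tab$covered, tab$parameter, mean)
  list(coverage = cov[c("theta", "kappa", "gamma")], table = tab)
}
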