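# numerically safe log-sum-exp
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Random-walk Metropolis step on the log scale
#'
#' Proposes `x' = x * exp(N(0, scale))` and accepts with the Metropolis
#' ratio for a target specified on the log-x scale (the Jacobian of the log
#' transform is absorbed by passing `logpost` as the density of log x).
#'
#' @param x current (positive) value.
#' @param logpost function of log(x) returning the log target density.
#' @param scale random-walk standard deviation on the log scale.
#' @param lp_cur optional cached `logpost(log(x))`.
#' @return list with `x`, `accept`, and the current log posterior `lp`.
#' @export
mh_logwalk_step <- function(x, logpost, scale, lp_cur = NULL) {
  lx <- log(x)
  if (is.null(lp_cur)) lp_cur <- logpost(lx)
  lxp <- lx + stats::rnorm(1, 0, scale)
  lp_prop <- logpost(lxp)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur)
    list(x = exp(lxp), accept = TRUE, lp = lp_prop)
  else list(x = x, accept = FALSE, lp = lp_cur)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Metropolis-Hastings step for a probability simplex
#'
#' Proposes from a Dirichlet distribution centred on the current value
#' (concentration `conc`, with a small floor keeping all proposal
#' parameters away from zero) and accepts with the full Hastings ratio.
#'
#' @param lam current probability vector.
#' @param logpost function of the vector returning the log target density.
#' @param conc proposal concentration; larger is more local.
#' @param floor_ concentration floor per component.
#' @param lp_cur optional cached log target at `lam`.
#' @return list with `lam`, `accept`, `lp`.
#' @export
mh_dirichlet_step <- function(lam, logpost, conc = 400, floor_ = 0.5,
                              lp_cur = NULL) {
  if (is.null(lp_cur)) lp_cur <- logpost(lam)
  a_fwd <- conc * lam + floor_
  prop <- rdirichlet1(a_fwd)
  a_bwd <- conc * prop + floor_
  lp_prop <- logpost(prop)
  lacc <- lp_prop - lp_cur +
    ldirichlet(lam, a_bwd) - ldirichlet(prop, a_fwd)
  if (is.finite(lacc) && log(stats::runif(1)) < lacc)
    list(lam = prop, accept = TRUE, lp = lp_prop)
  else list(lam = lam, accept = FALSE, lp = lp_cur)
}

#' Posterior mean and 95% credible interval
#'
#' Point estimates are posterior means; interval bounds are the empirical
#' 2.5% and 97.5% quantiles (type-7 interpolation, the R default).
#'
#' @param samples numeric vector, or matrix/data.frame of posterior draws.
#' @param parameter column name or index when `samples` is a matrix.
#' @return named numeric vector `c(mean, lower, upper)`.
#' @export
posterior_point_and_interval <- function(samples, parameter = NULL) {
  x <- if (!is.null(parameter)) as.matrix(samples)[, parameter] else samples
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least two retained samples")
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

#' Lognormal summary of the mutation-rate hierarchy
#'
#' The per-locus population-scaled mutation rates theta (per codon) follow
#' a lognormal distribution with log-scale parameters `mu` and `sigma`.
#' This converts those hyperparameters to the implied mean and standard
#' deviation of theta per kilobase of coding sequence.
#'
#' @param mu,sigma log-scale mean and standard deviation of theta per
#'   codon.
#' @param bases_per_codon conversion constant (3).
#' @return named vector `c(mean_per_kb, sd_per_kb)`.
#' @export
theta_lognormal_summary <- function(mu, sigma, bases_per_codon = 3) {
  m <- exp(mu + sigma^2 / 2) / bases_per_codon * 1000
  s <- m * sqrt(exp(sigma^2) - 1)
  c(mean_per_kb = m, sd_per_kb = s)
}

#' Split-chain potential scale reduction factor
#'
#' Classic split-Rhat: each chain is halved, and the ratio of pooled to
#' within-half variance (with the usual finite-sample correction) is
#' returned.  Values near 1 indicate the halves agree.
#'
#' @param x numeric vector (one chain) or matrix with one column per chain.
#' @return scalar Rhat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n2 <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n2), j], x[n2 + seq_len(n2), j])))
  m <- ncol(halves); n <- nrow(halves)
  mu <- colMeans(halves)
  B <- n * stats::var(mu)
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
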