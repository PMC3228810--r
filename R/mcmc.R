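#' Configuration for the joint model fit
#'
#' Collects the prior configuration, selection-class grid, and chain
#' schedule of [dfemap()].  Defaults follow the published analysis
#' protocol: a symmetric Dirichlet(1) prior on the DFE weights, a
#' Uniform(0,1) prior on the smoothing parameter p, improper log-uniform
#' priors on kappa and T (truncated to `kappa_T_range` for propriety),
#' a lognormal prior on each locus theta with hyperparameters
#' (`mu_theta`: improper uniform; `sigma_theta^2`: lognormal with log-scale
#' mean 0 and variance 4), and a chain of 2,000,000 iterations thinned
#' every 40 after a burn-in of 20,000 iterations, run twice.  Short runs
#' for testing simply override `iterations`, `burn_in`, `thin`, `chains`.
#'
#' @param iterations total MCMC sweeps per chain (including burn-in).
#' @param burn_in sweeps discarded.
#' @param thin recording interval.
#' @param chains independent chains (dispersed starts).
#' @param G1 window-level selection coefficients.
#' @param G2 per-codon deviation levels (the inviable class).
#' @param alpha symmetric Dirichlet concentration for the DFE prior.
#' @param kappa_T_range truncation of the log-uniform priors on kappa and
#'   T.
#' @param sigma_theta_prior c(log-scale mean, log-scale sd) of the
#'   lognormal prior on sigma_theta^2.
#' @param kernel_mean coalescent kernel mean of the PIMS approximation.
#' @param prior_only replace the likelihood by a constant (prior recovery
#'   runs).
#' @return list of class `dfemap_config`.
#' @export
dfemap_config <- function(iterations = 2e6, burn_in = 20000, thin = 40,
                          chains = 2,
                          G1 = c(-100, -50, -10, -5, -1, 0, 1, 5, 10, 50, 100),
                          G2 = -500, alpha = 1,
                          kappa_T_range = c(1e-4, 1e4),
                          sigma_theta_prior = c(0, 2),
                          kernel_mean = 2, prior_only = FALSE) {
  stopifnot(iterations > burn_in, thin >= 1)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 chains = chains, G1 = G1, G2 = G2, alpha = alpha,
                 kappa_T_range = kappa_T_range,
                 sigma_theta_prior = sigma_theta_prior,
                 kernel_mean = kernel_mean, prior_only = prior_only),
            class = "dfemap_config")
}

# ---- internal machinery ----------------------------------------------------

# per-(branch, locus) pattern tables
prep_locus <- function(locus, branches, K) {
  lapply(branches, function(b) {
    m <- locus$species[[b]]
    if (is.null(m)) stop("locus ", locus$locus_id, " lacks species ", b)
    cnts <- apply(m, 2, tabulate, nbins = K)
    key <- apply(cnts, 2, paste, collapse = ",")
    pat <- match(key, unique(key))
    list(pat = pat, counts = cnts[, !duplicated(key), drop = FALSE])
  })
}

# eigendecompositions of the unit-theta substitution generators, one per level
branch_eigens <- function(kappa, levels, space) {
  mut1 <- mutation_rate_matrix(1, kappa, space)
  lapply(levels, function(g) eigen(substitution_rate_matrix(mut1, g)$Q,
                                   symmetric = TRUE))
}

# full per-(branch, locus) cache: tip partials and root-ward messages
build_cache <- function(pl, theta, kappa, Tb, eigs, levels, space, kernel_mean) {
  K <- length(space$codons)
  G <- length(levels)
  U <- ncol(pl$counts)
  mut <- mutation_rate_matrix(theta, kappa, space)
  ThetaMat <- cpp_pims_theta(mut$rates, kernel_mean, 2)
  TP <- cpp_tip_loglik_pats(pl$counts, ThetaMat, space$aa_index, levels)
  cache <- list(TP = TP, ThetaMat = ThetaMat, U = U)
  add_messages(cache, theta, Tb, eigs, G)
}

# (re)compute W = P %*% tip-partials for every pattern and level
add_messages <- function(cache, theta, Tb, eigs, G) {
  U <- cache$U
  K <- nrow(cache$TP)
  W <- matrix(0, K, U * G)
  off <- numeric(U * G)
  for (g in seq_len(G)) {
    P <- eigen_cache_expm(eigs[[g]], theta * Tb)
    cols <- (seq_len(U) - 1L) * G + g
    tp <- cache$TP[, cols, drop = FALSE]
    m <- apply(tp, 2, max)
    W[, cols] <- P %*% exp(sweep(tp, 2, m))
    off[cols] <- m
  }
  cache$W <- W
  cache$off <- off
  cache
}

# column indices into W for given per-site levels
wcols <- function(pat, lev, G) (pat - 1L) * G + lev

# context of branch b at locus l: product of the other branches' messages
branch_context <- function(caches_l, pls_l, fields_l, b, branches, G, K, L) {
  ctx <- matrix(1, K, L)
  ctxoff <- numeric(L)
  for (b2 in setdiff(branches, b)) {
    ci <- wcols(pls_l[[b2]]$pat, field_level_index(fields_l[[b2]]), G)
    ctx <- ctx * caches_l[[b2]]$W[, ci, drop = FALSE]
    ctxoff <- ctxoff + caches_l[[b2]]$off[ci]
  }
  list(ctx = ctx, off = ctxoff)
}

# per-site per-level log-likelihood table for one branch given the context
branch_LL <- function(cache, pat, ctx, G, K) {
  L <- length(pat)
  LL <- matrix(0, L, G)
  for (g in seq_len(G)) {
    ci <- wcols(pat, rep(g, L), G)
    LL[, g] <- log(colSums(ctx$ctx * cache$W[, ci, drop = FALSE])) -
      log(K) + ctx$off + cache$off[ci]
  }
  LL
}

# locus log-likelihood for one branch's current field given the context
branch_loglik_cur <- function(cache, pat, levidx, ctx, G, K) {
  ci <- wcols(pat, levidx, G)
  sum(log(colSums(ctx$ctx * cache$W[, ci, drop = FALSE])) - log(K) +
        ctx$off + cache$off[ci])
}

# one collapsed Gibbs sweep over junctions, then window levels, then
# deviation flags
update_field_gibbs <- function(field, LL, lambda1, lambda2, p) {
  L <- field$L
  n1 <- length(lambda1); n2 <- length(lambda2)
  l1n <- log(lambda1) - log(sum(lambda1))
  junction <- field$junction
  dev <- field$dev
  mask <- dev == 0L
  CS <- apply(LL[, seq_len(n1), drop = FALSE] * mask, 2, cumsum)
  CS <- rbind(0, CS)
  seg <- function(a, b) CS[b + 1L, ] - CS[a, ]
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      # window containing i under junctions excluding i itself
      a <- i
      while (a > 1 && !junction[a - 1]) a <- a - 1
      b <- i + 1
      while (b < L && !junction[b]) b <- b + 1
      m_split <- lse(l1n + seg(a, i)) + lse(l1n + seg(i + 1, b))
      m_merge <- lse(l1n + seg(a, b))
      if (p <= 0) junction[i] <- FALSE
      else if (p >= 1) junction[i] <- TRUE
      else {
        lo <- log(p) + m_split - (lse(c(log(p) + m_split,
                                        log1p(-p) + m_merge)))
        junction[i] <- log(stats::runif(1)) < lo
      }
    }
  }
  win_id <- cumsum(c(1L, as.integer(junction)))
  nw <- win_id[L]
  starts <- which(c(TRUE, junction))
  ends <- c(starts[-1] - 1L, L)
  win_gamma <- integer(nw)
  for (w in seq_len(nw)) {
    lw <- l1n + seg(starts[w], ends[w])
    win_gamma[w] <- sample.int(n1, 1, prob = exp(lw - max(lw)))
  }
  # deviation flags
  gw <- win_gamma[win_id]
  logL1 <- log(sum(lambda1))
  Wt <- cbind(logL1 + LL[cbind(seq_len(L), gw)],
              matrix(log(lambda2), L, n2, byrow = TRUE) +
                LL[, n1 + seq_len(n2), drop = FALSE])
  mx <- do.call(pmax, as.data.frame(Wt))
  Pw <- exp(Wt - mx)
  Pw <- Pw / rowSums(Pw)
  u <- stats::runif(L)
  dev <- integer(L)
  acc <- Pw[, 1]
  remaining <- u > acc
  for (h in seq_len(n2)) {
    hit <- remaining & u <= acc + Pw[, 1 + h]
    dev[hit] <- h
    acc <- acc + Pw[, 1 + h]
    remaining <- remaining & !hit
  }
  new_window_field(junction, win_gamma, dev, field$classes)
}

# log-probability of a branch's fields given lambda (for the lambda update)
fields_loglam <- function(fields_b, lambda1, lambda2) {
  L1 <- sum(lambda1)
  tot <- 0
  for (f in fields_b) {
    tot <- tot + sum(log(lambda1[f$win_gamma])) - length(f$win_gamma) * log(L1)
    nd <- sum(f$dev > 0)
    tot <- tot + (f$L - nd) * log(L1)
    if (nd > 0) tot <- tot + sum(log(lambda2[f$dev[f$dev > 0]]))
  }
  tot
}

# ---- the fitting function --------------------------------------------------

#' Fit the joint polymorphism-divergence selection model
#'
#' Samples the joint posterior of the full hierarchical model for codon
#' alignments from species related by an unrooted star phylogeny (each
#' species' population hangs off the single internal node): per-branch
#' transition:transversion ratio kappa, branch length T, sliding-window
#' smoothing parameter p and DFE weights lambda; per-(branch, locus)
#' mutation rates theta with a shared lognormal hierarchy (mu_theta,
#' sigma_theta); and per-(branch, locus) selection fields (window
#' junctions, window selection coefficients, per-codon inviability
#' deviations).
#'
#' Each sweep updates junction indicators, window coefficients and
#' deviation flags by (collapsed) Gibbs; p by its Beta full conditional;
#' lambda by Dirichlet-proposal Metropolis-Hastings; theta, kappa, T by
#' log-scale random walks; mu_theta by its conjugate normal draw; and
#' sigma_theta by Metropolis-Hastings.  Per-(branch, locus, level) tip
#' partial vectors and root-ward messages are cached and invalidated only
#' on theta/kappa/T changes.
#'
#' @param loci a `locus_dataset` or list of them; every locus must contain
#'   every species of the tree.
#' @param tree star `ape::phylo` (e.g. `ape::read.tree(text =
#'   "(melanogaster,simulans,yakuba);")`) whose tip labels match the
#'   dataset species.
#' @param config a [dfemap_config()].
#' @param init optional named list overriding initial values (elements
#'   among `kappa`, `T`, `p`, `theta`, `mu_theta`, `sigma_theta`).
#' @param quiet suppress progress messages.
#' @return object of class `dfemap`; see [summary.dfemap()].  Components
#'   include `samples` (retained scalar draws, all chains, with a `chain`
#'   column), `lambda` (retained DFE draws per branch), `site_post`
#'   (per-branch posterior class probabilities per codon), `accept`,
#'   `rhat`, and the configuration.
#' @export
dfemap <- function(loci, tree, config = dfemap_config(), init = NULL,
                   quiet = TRUE) {
  space <- default_space()
  K <- length(space$codons)
  if (inherits(loci, "locus_dataset")) loci <- list(loci)
  branches <- tree$tip.label
  star_branches(tree)  # validates topology
  nb <- length(branches); nl <- length(loci)
  levels <- c(config$G1, config$G2)
  G <- length(levels); n1 <- length(config$G1); n2 <- length(config$G2)
  classes0 <- selection_classes(config$G1, config$G2)
  pls <- lapply(loci, prep_locus, branches = branches, K = K)
  for (l in seq_len(nl)) names(pls[[l]]) <- branches
  Ls <- vapply(loci, function(x) x$n_codons, integer(1))
  rng <- config$kappa_T_range
  chains_out <- list()
  lam_out <- list()
  post_acc <- lapply(branches, function(b)
    lapply(seq_len(nl), function(l) matrix(0, Ls[l], G)))
  names(post_acc) <- branches
  n_acc <- 0L
  accept <- c(theta = 0, kappa = 0, T = 0, lambda = 0, sigma = 0)
  tries <- accept

  for (chain in seq_len(config$chains)) {
    # ---- initial state
    kappa <- stats::setNames(rep(2, nb), branches)
    Tb <- stats::setNames(rep(1, nb), branches)
    pb <- stats::setNames(rep(0.5, nb), branches)
    lambda <- lapply(branches, function(b) rep(1 / G, G))
    names(lambda) <- branches
    theta <- matrix(0.1, nb, nl, dimnames = list(branches, NULL))
    mu_theta <- mean(log(theta)); sigma_theta <- 0.5
    if (chain > 1) {   # dispersed starts
      kappa[] <- exp(stats::runif(nb, log(0.5), log(8)))
      Tb[] <- exp(stats::runif(nb, log(0.3), log(4)))
      theta[] <- exp(stats::runif(nb * nl, log(0.02), log(0.5)))
      pb[] <- stats::runif(nb, 0.05, 0.95)
    }
    if (!is.null(init)) {
      for (nm in intersect(names(init), c("kappa", "T", "p", "theta",
                                          "mu_theta", "sigma_theta"))) {
        val <- init[[nm]]
        switch(nm, kappa = {kappa[] <- val}, T = {Tb[] <- val},
               p = {pb[] <- val}, theta = {theta[] <- val},
               mu_theta = {mu_theta <- val}, sigma_theta = {sigma_theta <- val})
      }
    }
    fields <- lapply(seq_len(nl), function(l) {
      fl <- lapply(branches, function(b) {
        cl <- selection_classes(config$G1, config$G2,
                                lambda[[b]][seq_len(n1)],
                                lambda[[b]][n1 + seq_len(n2)])
        sample_field_prior(Ls[l], pb[b], cl)
      })
      names(fl) <- branches
      fl
    })
    eigs <- NULL; caches <- NULL
    if (!config$prior_only) {
      eigs <- lapply(branches, function(b) branch_eigens(kappa[b], levels, space))
      names(eigs) <- branches
      caches <- lapply(seq_len(nl), function(l) {
        cl <- lapply(branches, function(b)
          build_cache(pls[[l]][[b]], theta[b, l], kappa[b], Tb[b], eigs[[b]],
                      levels, space, config$kernel_mean))
        names(cl) <- branches
        cl
      })
    }
    scales <- list(theta = 0.3, kappa = 0.15, T = 0.15, sigma = 0.4)
    keep <- seq(config$burn_in + config$thin, config$iterations,
                by = config$thin)
    scal_names <- c("mu_theta", "sigma_theta",
                    paste0("kappa_", branches), paste0("T_", branches),
                    paste0("p_", branches),
                    paste0("theta_", rep(branches, nl), "_l",
                           rep(seq_len(nl), each = nb)))
    samp <- matrix(NA_real_, length(keep), length(scal_names),
                   dimnames = list(NULL, scal_names))
    lamsamp <- array(NA_real_, c(length(keep), nb, G),
                     dimnames = list(NULL, branches, levels))
    row <- 0L

    for (it in seq_len(config$iterations)) {
      for (l in seq_len(nl)) {
        Ll <- Ls[l]
        for (b in branches) {
          if (config$prior_only) {
            LLb <- matrix(0, Ll, G)
            cl <- selection_classes(config$G1, config$G2,
                                    lambda[[b]][seq_len(n1)],
                                    lambda[[b]][n1 + seq_len(n2)])
            fields[[l]][[b]] <- update_field_gibbs(
              fields[[l]][[b]], LLb, cl$lambda1, cl$lambda2, pb[b])
            # theta from its prior (lognormal)
            theta[b, l] <- exp(stats::rnorm(1, mu_theta, sigma_theta))
            next
          }
          ctx <- branch_context(caches[[l]], pls[[l]], fields[[l]], b,
                                branches, G, K, Ll)
          LLb <- branch_LL(caches[[l]][[b]], pls[[l]][[b]]$pat, ctx, G, K)
          fields[[l]][[b]] <- update_field_gibbs(
            fields[[l]][[b]], LLb, lambda[[b]][seq_len(n1)],
            lambda[[b]][n1 + seq_len(n2)], pb[b])
          # theta update (lognormal prior, log-scale walk)
          levidx <- field_level_index(fields[[l]][[b]])
          cur <- branch_loglik_cur(caches[[l]][[b]], pls[[l]][[b]]$pat,
                                   levidx, ctx, G, K)
          lth <- log(theta[b, l])
          lthp <- lth + stats::rnorm(1, 0, scales$theta)
          cache_p <- build_cache(pls[[l]][[b]], exp(lthp), kappa[b], Tb[b],
                                 eigs[[b]], levels, space, config$kernel_mean)
          prop <- branch_loglik_cur(cache_p, pls[[l]][[b]]$pat, levidx, ctx,
                                    G, K)
          lacc <- prop - cur +
            stats::dnorm(lthp, mu_theta, sigma_theta, log = TRUE) -
            stats::dnorm(lth, mu_theta, sigma_theta, log = TRUE)
          tries["theta"] <- tries["theta"] + 1
          if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
            theta[b, l] <- exp(lthp)
            caches[[l]][[b]] <- cache_p
            accept["theta"] <- accept["theta"] + 1
          }
        }
      }
      # branch-level scalars
      for (b in branches) {
        if (!config$prior_only) {
          # kappa
          lka <- log(kappa[b])
          lkap <- lka + stats::rnorm(1, 0, scales$kappa)
          tries["kappa"] <- tries["kappa"] + 1
          if (exp(lkap) >= rng[1] && exp(lkap) <= rng[2]) {
            eig_p <- branch_eigens(exp(lkap), levels, space)
            cur <- prop <- 0
            caches_p <- vector("list", nl)
            for (l in seq_len(nl)) {
              ctx <- branch_context(caches[[l]], pls[[l]], fields[[l]], b,
                                    branches, G, K, Ls[l])
              levidx <- field_level_index(fields[[l]][[b]])
              cur <- cur + branch_loglik_cur(caches[[l]][[b]],
                                             pls[[l]][[b]]$pat, levidx, ctx, G, K)
              caches_p[[l]] <- build_cache(pls[[l]][[b]], theta[b, l],
                                           exp(lkap), Tb[b], eig_p, levels,
                                           space, config$kernel_mean)
              prop <- prop + branch_loglik_cur(caches_p[[l]],
                                               pls[[l]][[b]]$pat, levidx, ctx, G, K)
            }
            if (is.finite(prop) && log(stats::runif(1)) < prop - cur) {
              kappa[b] <- exp(lkap)
              eigs[[b]] <- eig_p
              for (l in seq_len(nl)) caches[[l]][[b]] <- caches_p[[l]]
              accept["kappa"] <- accept["kappa"] + 1
            }
          }
          # T
          lT <- log(Tb[b])
          lTp <- lT + stats::rnorm(1, 0, scales$T)
          tries["T"] <- tries["T"] + 1
          if (exp(lTp) >= rng[1] && exp(lTp) <= rng[2]) {
            cur <- prop <- 0
            caches_p <- vector("list", nl)
            for (l in seq_len(nl)) {
              ctx <- branch_context(caches[[l]], pls[[l]], fields[[l]], b,
                                    branches, G, K, Ls[l])
              levidx <- field_level_index(fields[[l]][[b]])
              cur <- cur + branch_loglik_cur(caches[[l]][[b]],
                                             pls[[l]][[b]]$pat, levidx, ctx, G, K)
              caches_p[[l]] <- add_messages(caches[[l]][[b]], theta[b, l],
                                            exp(lTp), eigs[[b]], G)
              prop <- prop + branch_loglik_cur(caches_p[[l]],
                                               pls[[l]][[b]]$pat, levidx, ctx, G, K)
            }
            if (is.finite(prop) && log(stats::runif(1)) < prop - cur) {
              Tb[b] <- exp(lTp)
              for (l in seq_len(nl)) caches[[l]][[b]] <- caches_p[[l]]
              accept["T"] <- accept["T"] + 1
            }
          }
        } else {
          # prior-only: sample log-uniform within the truncation range
          kappa[b] <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
          Tb[b] <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
        }
        # p: Beta full conditional from junction indicators
        k_on <- sum(vapply(seq_len(nl), function(l)
          sum(fields[[l]][[b]]$junction), numeric(1)))
        k_tot <- sum(Ls - 1)
        pb[b] <- stats::rbeta(1, 1 + k_on, 1 + k_tot - k_on)
        # lambda: Dirichlet-proposal MH against the field probability
        fb <- lapply(seq_len(nl), function(l) fields[[l]][[b]])
        lam_post <- function(lam) {
          fields_loglam(fb, lam[seq_len(n1)], lam[n1 + seq_len(n2)]) +
            sum((config$alpha - 1) * log(lam))
        }
        st <- mh_dirichlet_step(lambda[[b]], lam_post, conc = 60)
        tries["lambda"] <- tries["lambda"] + 1
        if (st$accept) accept["lambda"] <- accept["lambda"] + 1
        lambda[[b]] <- st$lam
      }
      # hyperparameters
      lth_all <- log(as.numeric(theta))
      mu_theta <- stats::rnorm(1, mean(lth_all),
                               sigma_theta / sqrt(length(lth_all)))
      sig_post <- function(ls) {
        v <- exp(2 * ls)
        sum(stats::dnorm(lth_all, mu_theta, exp(ls), log = TRUE)) +
          stats::dlnorm(v, config$sigma_theta_prior[1],
                        config$sigma_theta_prior[2], log = TRUE) + log(2 * v)
      }
      stp <- mh_logwalk_step(sigma_theta, sig_post, scales$sigma)
      tries["sigma"] <- tries["sigma"] + 1
      if (stp$accept) accept["sigma"] <- accept["sigma"] + 1
      sigma_theta <- stp$x
      # record
      if (it %in% keep) {
        row <- row + 1L
        samp[row, ] <- c(mu_theta, sigma_theta, kappa, Tb, pb,
                         as.numeric(theta))
        for (b in branches) lamsamp[row, b, ] <- lambda[[b]]
        for (l in seq_len(nl)) {
          for (b in branches) {
            li <- field_level_index(fields[[l]][[b]])
            post_acc[[b]][[l]][cbind(seq_len(Ls[l]), li)] <-
              post_acc[[b]][[l]][cbind(seq_len(Ls[l]), li)] + 1
          }
        }
        n_acc <- n_acc + 1L
      }
      if (!quiet && it %% 200 == 0) message("chain ", chain, " sweep ", it)
    }
    chains_out[[chain]] <- samp
    lam_out[[chain]] <- lamsamp
  }

  samples <- do.call(rbind, lapply(seq_along(chains_out), function(ch)
    cbind(chain = ch, chains_out[[ch]])))
  lambda_draws <- do.call(abind1, lam_out)
  rhat <- if (length(chains_out) > 1 && nrow(chains_out[[1]]) >= 4) {
    vapply(colnames(chains_out[[1]]), function(v)
      split_rhat(do.call(cbind, lapply(chains_out, function(s) s[, v]))),
      numeric(1))
  } else NULL
  site_post <- lapply(post_acc, function(bl)
    lapply(bl, function(m) {
      colnames(m) <- levels
      m / max(1L, n_acc)
    }))
  structure(list(samples = samples, lambda = lambda_draws, rhat = rhat,
                 site_post = site_post, accept = accept / pmax(1, tries),
                 config = config, tree = tree, branches = branches,
                 levels = levels,
                 loci = vapply(loci, function(x) x$locus_id, character(1)),
                 n_codons = Ls),
            class = "dfemap")
}

abind1 <- function(...) {
  args <- list(...)
  n <- sum(vapply(args, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(n, dim(args[[1]])[2:3]),
               dimnames = c(list(NULL), dimnames(args[[1]])[2:3]))
  at <- 0
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
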