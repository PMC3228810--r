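#' @export
print.dfemap <- function(x, ...) {
  cat("Joint polymorphism-divergence selection model fit\n")
  cat("  lineages: ", paste(x$branches, collapse = ", "), "\n", sep = "")
  cat("  loci: ", length(x$loci), " (", sum(x$n_codons), " codons)\n", sep = "")
  cat("  retained draws: ", nrow(x$samples), " across ",
      length(unique(x$samples[, "chain"])), " chain(s)\n", sep = "")
  if (!is.null(x$rhat))
    cat("  max split-Rhat: ", round(max(x$rhat, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Posterior summaries of a joint model fit
#'
#' @param object a [dfemap()] fit.
#' @param ... unused.
#' @return list with `estimates` (posterior mean and 95% interval per
#'   scalar parameter), `dfe` (per-branch posterior mean and interval of
#'   the DFE weights), `substitutions` (per-branch substitution DFE and
#'   A+/D+/D0/D- decomposition at the posterior mean DFE), and
#'   `theta_per_kb` (lognormal hierarchy summary).
#' @export
summary.dfemap <- function(object, ...) {
  sc <- object$samples[, setdiff(colnames(object$samples), "chain"),
                       drop = FALSE]
  est <- t(apply(sc, 2, posterior_point_and_interval))
  dfe <- lapply(object$branches, function(b) {
    d <- object$lambda[, b, ]
    t(apply(d, 2, posterior_point_and_interval))
  })
  names(dfe) <- object$branches
  subs <- lapply(object$branches, function(b) {
    lam <- colMeans(object$lambda[, b, ])
    names(lam) <- object$levels
    sd <- substitution_dfe(lam)
    list(substitution_dfe = sd, classes = classify_substitutions(sd))
  })
  names(subs) <- object$branches
  th <- theta_lognormal_summary(est["mu_theta", "mean"],
                                est["sigma_theta", "mean"])
  out <- list(estimates = est, dfe = dfe, substitutions = subs,
              theta_per_kb = th, rhat = object$rhat,
              accept = object$accept)
  class(out) <- "summary.dfemap"
  out
}

#' @export
print.summary.dfemap <- function(x, ...) {
  cat("Parameter estimates (posterior mean, 95% credible interval):\n")
  print(round(x$estimates, 4))
  cat("\nMutation-rate hierarchy: theta mean ",
      round(x$theta_per_kb["mean_per_kb"], 1), " per kb, sd ",
      round(x$theta_per_kb["sd_per_kb"], 1), " per kb\n", sep = "")
  for (b in names(x$dfe)) {
    cat("\nDFE (", b, "):\n", sep = "")
    print(round(x$dfe[[b]], 4))
    cat("substitution classes: ")
    print(round(x$substitutions[[b]]$classes, 4))
  }
  invisible(x)
}

#' @export
coef.dfemap <- function(object, ...) {
  sc <- object$samples[, setdiff(colnames(object$samples), "chain"),
                       drop = FALSE]
  colMeans(sc)
}

#' Plot the inferred distribution of fitness effects
#'
#' Bar plot of the posterior mean DFE of new non-synonymous mutations (or
#' of amino-acid substitutions) per lineage, with 95% credible bars.
#'
#' @param x a [dfemap()] fit.
#' @param type `"mutations"` or `"substitutions"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dfemap <- function(x, type = c("mutations", "substitutions"), ...) {
  type <- match.arg(type)
  nb <- length(x$branches)
  means <- sapply(x$branches, function(b) colMeans(x$lambda[, b, ]))
  if (type == "substitutions")
    means <- apply(means, 2, function(lam) {
      names(lam) <- x$levels
      substitution_dfe(lam)[as.character(x$levels)]
    })
  bp <- graphics::barplot(t(means), beside = TRUE,
                          names.arg = x$levels,
                          legend.text = x$branches,
                          xlab = "selection coefficient",
                          ylab = if (type == "mutations")
                            "frequency of new mutations"
                          else "frequency of substitutions", ...)
  if (type == "mutations") {
    for (i in seq_len(nb)) {
      ci <- apply(x$lambda[, x$branches[i], ], 2,
                  stats::quantile, c(0.025, 0.975))
      graphics::segments(bp[i, ], ci[1, ], bp[i, ], ci[2, ])
    }
  }
  invisible(bp)
}

#' Simulate datasets from a fitted model
#'
#' Draws new datasets at the posterior-mean parameters (three-taxon
#' scenario, one simulated locus per `nsim`), using the posterior mean
#' theta of the first locus and the per-branch posterior mean DFE to draw
#' site selection coefficients from prior selection fields.
#'
#' @param object a [dfemap()] fit.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param L codons per simulated locus.
#' @param n_seqs sequences per species.
#' @param M simulator population size.
#' @param ... unused.
#' @return list of `sim_dataset` objects.
#' @export
simulate.dfemap <- function(object, nsim = 1, seed = NULL, L = NULL,
                            n_seqs = 10, M = 500, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(L)) L <- object$n_codons[1]
  cf <- coef(object)
  n1 <- length(object$config$G1)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    bp <- lapply(object$branches, function(b) {
      lam <- colMeans(object$lambda[, b, ])
      cl <- selection_classes(object$config$G1, object$config$G2,
                              lam[seq_len(n1)] / sum(lam),
                              lam[-seq_len(n1)] / sum(lam))
      fld <- sample_field_prior(L, cf[paste0("p_", b)], cl)
      list(theta = cf[paste0("theta_", b, "_l1")],
           kappa = cf[paste0("kappa_", b)],
           T = cf[paste0("T_", b)],
           gamma = fld$gamma)
    })
    names(bp) <- object$branches
    out[[s]] <- simulate_dataset("three_taxon", n_seqs = n_seqs, L = L,
                                 branch_params = bp, M = M,
                                 locus_id = paste0("sim", s))
  }
  out
}

#' Write fit outputs to a directory
#'
#' Writes `samples.tsv.gz` (retained scalar draws), `lambda.tsv.gz` (DFE
#' draws), `site_posteriors.tsv.gz` (per locus, branch and codon the
#' posterior probability of each selection level; codon indices are
#' 1-based), `dfe.tsv` (posterior mean and 95% interval of the DFE per
#' branch) and `run_log.txt` (acceptance rates and split-Rhat).
#'
#' @param fit a [dfemap()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dfemap_outputs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f, gz = TRUE) {
    path <- file.path(dir, f)
    con <- if (gz) gzfile(path, "w") else file(path, "w")
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wtsv(as.data.frame(fit$samples), "samples.tsv.gz")
  lam <- do.call(rbind, lapply(fit$branches, function(b) {
    d <- as.data.frame(fit$lambda[, b, ])
    names(d) <- paste0("lambda_", fit$levels)
    cbind(branch = b, iter = seq_len(nrow(d)), d)
  }))
  wtsv(lam, "lambda.tsv.gz")
  sp <- do.call(rbind, lapply(fit$branches, function(b) {
    do.call(rbind, lapply(seq_along(fit$loci), function(l) {
      m <- fit$site_post[[b]][[l]]
      d <- as.data.frame(m)
      names(d) <- paste0("pr_", colnames(m))
      cbind(locus = fit$loci[l], branch = b,
            codon_index = seq_len(nrow(m)), d)
    }))
  }))
  wtsv(sp, "site_posteriors.tsv.gz")
  dfe <- do.call(rbind, lapply(fit$branches, function(b) {
    e <- t(apply(fit$lambda[, b, ], 2, posterior_point_and_interval))
    data.frame(branch = b, level = fit$levels, mean = e[, "mean"],
               lower = e[, "lower"], upper = e[, "upper"])
  }))
  wtsv(dfe, "dfe.tsv", gz = FALSE)
  log_lines <- c(
    paste("acceptance:", paste(names(fit$accept),
                               round(fit$accept, 3), collapse = ", ")),
    if (!is.null(fit$rhat))
      paste("max split-Rhat:", round(max(fit$rhat, na.rm = TRUE), 3)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Summarise a completed fit directory
#'
#' Re-derives the headline summaries from the TSV outputs of
#' [write_dfemap_outputs()]: the per-branch DFE (checked to sum to 1), the
#' substitution DFE and its A+/D+/D0/D- decomposition, per-gene rankings
#' by the posterior probability of positive selection with per-codon
#' tracks, and spatial correlation of the class posteriors at a few lags.
#'
#' @param out_dir directory written by [write_dfemap_outputs()].
#' @param lags codon distances for the spatial correlation table.
#' @return list of summaries.
#' @export
summarize_run <- function(out_dir, lags = c(1, 2, 5, 10)) {
  need <- c("dfe.tsv", "site_posteriors.tsv.gz")
  for (f in need)
    if (!file.exists(file.path(out_dir, f))) stop("missing output: ", f)
  dfe <- utils::read.delim(file.path(out_dir, "dfe.tsv"))
  sp <- utils::read.delim(gzfile(file.path(out_dir, "site_posteriors.tsv.gz")))
  if (nrow(sp) == 0L) stop("empty site-posterior file")
  prcols <- grep("^pr_", names(sp), value = TRUE)
  levels <- as.numeric(sub("^pr_", "", prcols))
  branches <- unique(dfe$branch)
  out <- list()
  for (b in branches) {
    lam <- dfe$mean[dfe$branch == b]
    names(lam) <- dfe$level[dfe$branch == b]
    sdfe <- substitution_dfe(lam / sum(lam))
    spb <- sp[sp$branch == b, , drop = FALSE]
    post <- as.matrix(spb[, prcols])
    colnames(post) <- levels
    sums <- posterior_site_summaries(post)
    genes <- data.frame(locus = unique(spb$locus))
    genes$pr_positive <- tapply(sums$site$pr_positive, spb$locus,
                                mean)[genes$locus]
    genes <- genes[order(-genes$pr_positive), ]
    genes$rank <- seq_len(nrow(genes))
    cors <- sapply(lags, function(d)
      class_probability_correlation(post, lag = d, locus = spb$locus))
    colnames(cors) <- paste0("lag", lags)
    out[[b]] <- list(dfe = lam, substitution_dfe = sdfe,
                     classes = classify_substitutions(sdfe),
                     gene_ranking = genes, site = sums$site,
                     spatial_correlation = cors)
  }
  out
}
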