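#' Discrete selection-coefficient classes and DFE weights
#'
#' The distribution of fitness effects (DFE) is modelled non-parametrically
#' over a discrete grid of population-scaled selection coefficients.  Class
#' G1 holds the levels a sliding window may take; class G2 holds levels that
#' individual codons may take independently of their window (by default the
#' single "effectively inviable" level -500, so inviability is spatially
#' independent while viable sites keep the window's spatial dependency).
#' `lambda1[i]` is the marginal probability that a codon takes its window's
#' coefficient and the window has coefficient `G1[i]`; `lambda2[i]` that it
#' deviates to `G2[i]`.  Together the lambdas sum to 1.
#'
#' @param G1 window-level selection coefficients.
#' @param G2 per-codon deviation levels.
#' @param lambda1,lambda2 non-negative weights summing to 1 overall
#'   (default uniform over all levels).
#' @return object of class `selection_classes`.
#' @export
selection_classes <- function(G1 = c(-100, -50, -10, -5, -1, 0, 1, 5, 10, 50, 100),
                              G2 = -500,
                              lambda1 = NULL, lambda2 = NULL) {
  n1 <- length(G1); n2 <- length(G2)
  if (is.null(lambda1) && is.null(lambda2)) {
    lambda1 <- rep(1 / (n1 + n2), n1)
    lambda2 <- rep(1 / (n1 + n2), n2)
  }
  stopifnot(length(lambda1) == n1, length(lambda2) == n2,
            all(lambda1 >= 0), all(lambda2 >= 0))
  if (abs(sum(lambda1) + sum(lambda2) - 1) > 1e-8)
    stop("lambda1 and lambda2 must sum to 1")
  structure(list(G1 = G1, G2 = G2, lambda1 = lambda1, lambda2 = lambda2,
                 levels = c(G1, G2)),
            class = "selection_classes")
}

#' Draw an intragenic selection field from its prior
#'
#' Generative sliding-window model for a locus of L codons: junctions
#' between adjacent codons are i.i.d. Bernoulli(p) (so window lengths are
#' geometric with mean 1/p); each window draws its coefficient from G1 with
#' weights `lambda1`; each codon independently deviates with probability
#' `sum(lambda2)` to a G2 level drawn with weights `lambda2`.
#'
#' @param L number of codons.
#' @param p smoothing parameter: probability a window ends between two
#'   adjacent codons. `p = 1` gives sitewise, `p = 0` genewise selection.
#' @param classes a [selection_classes()].
#' @return object of class `window_field`: list with `junction`
#'   (logical L-1), `win_id` (integer L), `win_gamma` (G1 index per
#'   window), `dev` (integer L: 0 or G2 index), and the per-codon
#'   coefficient vector `gamma`.
#' @export
sample_field_prior <- function(L, p, classes = selection_classes()) {
  stopifnot(L >= 1, p >= 0, p <= 1)
  l1 <- classes$lambda1; l2 <- classes$lambda2
  junction <- if (L > 1) stats::runif(L - 1) < p else logical(0)
  win_id <- cumsum(c(1L, as.integer(junction)))
  nw <- win_id[L]
  win_gamma <- sample.int(length(l1), nw, replace = TRUE, prob = l1)
  pdev <- sum(l2)
  dev <- integer(L)
  hit <- stats::runif(L) < pdev
  if (any(hit))
    dev[hit] <- sample.int(length(l2), sum(hit), replace = TRUE, prob = l2)
  new_window_field(junction, win_gamma, dev, classes)
}

new_window_field <- function(junction, win_gamma, dev, classes) {
  L <- length(dev)
  win_id <- cumsum(c(1L, as.integer(junction)))
  g <- classes$G1[win_gamma[win_id]]
  g[dev > 0] <- classes$G2[dev[dev > 0]]
  structure(list(junction = junction, win_id = win_id, win_gamma = win_gamma,
                 dev = dev, gamma = g, L = L, classes = classes),
            class = "window_field")
}

# index into c(G1, G2) per codon
field_level_index <- function(field) {
  cl <- field$classes
  idx <- field$win_gamma[field$win_id]
  idx[field$dev > 0] <- length(cl$G1) + field$dev[field$dev > 0]
  idx
}

#' Log prior probability of a selection field
#'
#' Exact density of the generative model of [sample_field_prior()].
#'
#' @param field a `window_field`.
#' @param p smoothing parameter.
#' @param classes a [selection_classes()] (defaults to the field's own).
#' @return log prior probability.
#' @export
field_log_prior <- function(field, p, classes = field$classes) {
  l1 <- classes$lambda1; l2 <- classes$lambda2
  L1 <- sum(l1)
  k_on <- sum(field$junction); k_off <- length(field$junction) - k_on
  lp <- 0
  if (k_on > 0) lp <- lp + k_on * log(p)
  if (k_off > 0) lp <- lp + k_off * log1p(-p)
  lp <- lp + sum(log(l1[field$win_gamma] / L1))
  ndev <- sum(field$dev > 0)
  lp <- lp + (field$L - ndev) * log(L1)
  if (ndev > 0) lp <- lp + sum(log(l2[field$dev[field$dev > 0]]))
  lp
}

#' DFE of amino-acid substitutions
#'
#' Converts the DFE of new non-synonymous mutations (weights `lambda` over
#' selection levels) into the DFE of amino-acid substitutions by weighting
#' each level by its relative fixation rate `omega(gamma)` and normalising.
#'
#' @param classes a [selection_classes()], or a numeric vector of weights
#'   named by selection coefficient.
#' @return named numeric vector of substitution frequencies per level.
#' @export
substitution_dfe <- function(classes) {
  if (inherits(classes, "selection_classes")) {
    lev <- classes$levels
    lam <- c(classes$lambda1, classes$lambda2)
  } else {
    lev <- as.numeric(names(classes))
    lam <- as.numeric(classes)
  }
  w <- lam * omega(lev)
  if (sum(w) < 1e-100) stop("degenerate DFE: no fixation mass")
  out <- w / sum(w)
  names(out) <- lev
  out
}

#' Decompose substitutions into selection and drift classes
#'
#' Splits the substitution DFE into: A+ (beneficial substitutions in excess
#' of the neutral rate, attributable to positive selection: proportion
#' `(omega-1)/omega` of each gamma > 0 level), D+ (beneficial substitutions
#' expected under neutrality, `1/omega`), D0 (neutral, gamma = 0), and D-
#' (deleterious, gamma < 0).
#'
#' @param sdfe output of [substitution_dfe()].
#' @return named numeric vector with components `Aplus`, `Dplus`, `D0`,
#'   `Dminus`, summing to 1.
#' @export
classify_substitutions <- function(sdfe) {
  lev <- as.numeric(names(sdfe))
  w <- omega(lev)
  pos <- lev > 0
  out <- c(
    Aplus  = sum(sdfe[pos] * (w[pos] - 1) / w[pos]),
    Dplus  = sum(sdfe[pos] / w[pos]),
    D0     = sum(sdfe[lev == 0]),
    Dminus = sum(sdfe[lev < 0])
  )
  out
}

#' Per-codon and per-gene summaries of site selection posteriors
#'
#' From a table of per-codon posterior probabilities over the selection
#' levels: the probability of positive selection Pr(gamma > 0), the
#' probability of viability Pr(gamma > inviable), the mean coefficient
#' given viability, per-gene (unweighted mean over codons) versions, and
#' positive-selection calls at the 50% posterior threshold (the prior odds
#' are set by the estimated DFE, so 50% posterior probability already
#' represents strong evidence).
#'
#' @param post matrix or data.frame, rows = codons, columns = selection
#'   levels (column names coercible to the numeric levels).
#' @param inviable levels at or below this value count as inviable
#'   (default -500).
#' @return list with `site` (data.frame: pr_positive, pr_viable,
#'   mean_gamma_viable, positive_call) and `gene` (one-row means).
#' @export
posterior_site_summaries <- function(post, inviable = -500) {
  post <- as.matrix(post)
  if (nrow(post) == 0L) stop("empty posterior table")
  lev <- as.numeric(colnames(post))
  if (anyNA(lev)) stop("column names must be the selection levels")
  pr_pos <- rowSums(post[, lev > 0, drop = FALSE])
  viable <- lev > inviable
  pr_via <- rowSums(post[, viable, drop = FALSE])
  mg <- as.vector(post[, viable, drop = FALSE] %*% lev[viable]) / pr_via
  site <- data.frame(pr_positive = pr_pos, pr_viable = pr_via,
                     mean_gamma_viable = mg,
                     positive_call = pr_pos > 0.5)
  gene <- data.frame(pr_positive = mean(pr_pos), pr_viable = mean(pr_via),
                     mean_gamma_viable = mean(mg, na.rm = TRUE))
  list(site = site, gene = gene)
}

#' Correlation of selection-class posteriors across sites or lineages
#'
#' Product-moment correlation of per-level posterior probabilities, either
#' between pairs of codons a fixed distance apart within loci (spatial
#' autocorrelation of the selection field) or between matched codons of two
#' lineages.
#'
#' @param post matrix of per-codon class probabilities (rows = codons).
#' @param post2 optional second matrix (matched rows) for the cross-lineage
#'   mode; when supplied `lag` is ignored.
#' @param lag codon distance for the spatial mode (0 returns 1 at every
#'   level with variance).
#' @param locus optional vector of locus ids; pairs never span loci.
#' @return named numeric vector: correlation per selection level (`NA`
#'   where a level has zero variance).
#' @export
class_probability_correlation <- function(post, post2 = NULL, lag = 1,
                                          locus = NULL) {
  post <- as.matrix(post)
  if (!is.null(post2)) {
    post2 <- as.matrix(post2)
    stopifnot(nrow(post) == nrow(post2))
    out <- vapply(seq_len(ncol(post)), function(k) {
      a <- post[, k]; b <- post2[, k]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
    names(out) <- colnames(post)
    return(out)
  }
  if (is.null(locus)) locus <- rep(1L, nrow(post))
  ii <- seq_len(nrow(post) - lag)
  if (lag > 0) ii <- ii[locus[ii] == locus[ii + lag]]
  if (lag == 0) ii <- seq_len(nrow(post))
  if (length(ii) < 3) stop("need at least 3 site pairs")
  out <- vapply(seq_len(ncol(post)), function(k) {
    a <- post[ii, k]; b <- post[ii + lag, k]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  names(out) <- colnames(post)
  out
}

#' DFE stratified by derived-allele sample frequency
#'
#' Bins codon sites by the sample count of derived amino acids after
#' resampling every site to a common sample size: sites with n larger than
#' `target_n` are down-sampled hypergeometrically (without replacement),
#' sites with smaller n are resampled binomially.  Reports the average
#' posterior class probabilities per bin.
#'
#' @param post matrix of per-codon class probabilities.
#' @param derived_count per-site count of sampled copies carrying a derived
#'   amino acid (`NA` sites are skipped).
#' @param n per-site sample sizes.
#' @param target_n common sample size for binning (default 24).
#' @return list with `bins` (derived count 0..target_n), `dfe` (matrix bins
#'   x levels of mean class probabilities) and `n_sites` per bin.
#' @export
dfe_by_derived_frequency <- function(post, derived_count, n, target_n = 24) {
  post <- as.matrix(post)
  stopifnot(length(derived_count) == nrow(post), length(n) == nrow(post))
  keep <- !is.na(derived_count)
  post <- post[keep, , drop = FALSE]
  d <- derived_count[keep]; nn <- n[keep]
  res <- integer(length(d))
  for (i in seq_along(d)) {
    res[i] <- if (nn[i] == target_n) d[i]
    else if (nn[i] > target_n) stats::rhyper(1, d[i], nn[i] - d[i], target_n)
    else stats::rbinom(1, target_n, d[i] / nn[i])
  }
  bins <- 0:target_n
  dfe <- matrix(NA_real_, length(bins), ncol(post),
                dimnames = list(bins, colnames(post)))
  cnt <- integer(length(bins))
  for (b in seq_along(bins)) {
    sel <- res == bins[b]
    cnt[b] <- sum(sel)
    if (cnt[b] > 0) dfe[b, ] <- colMeans(post[sel, , drop = FALSE])
  }
  list(bins = bins, dfe = dfe, n_sites = cnt)
}
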