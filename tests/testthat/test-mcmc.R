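test_that("posterior point and interval use the mean and type-7 quantiles", {
  expect_equal(posterior_point_and_interval(1:100),
               c(mean = 50.5, lower = 3.475, upper = 97.525))
  expect_equal(unname(posterior_point_and_interval(rep(2.5, 10))),
               c(2.5, 2.5, 2.5))
  expect_error(posterior_point_and_interval(1), "two retained samples")
  m <- cbind(a = 1:100, b = 101:200)
  expect_equal(posterior_point_and_interval(m, "b")[["mean"]], 150.5)
})

test_that("lognormal theta hierarchy reproduces per-kb moments", {
  s <- theta_lognormal_summary(-2.43, 0.400)
  expect_equal(unname(s["mean_per_kb"]), 31.7, tolerance = 0.01 * 31.7)
  expect_equal(unname(s["sd_per_kb"]), 13.2, tolerance = 0.01 * 13.2)
})

test_that("log-walk MH kernel preserves a lognormal target", {
  set.seed(61)
  target <- function(lx) stats::dnorm(lx, -1, 0.7, log = TRUE)
  x <- 1
  draws <- numeric(20000)
  for (i in seq_along(draws)) {
    st <- mh_logwalk_step(x, target, 0.8)
    x <- st$x
    draws[i] <- x
  }
  # chi-square on deciles of the target distribution
  q <- stats::qlnorm(seq(0.1, 0.9, 0.1), -1, 0.7)
  obs <- table(cut(draws, c(0, q, Inf)))
  expect_gt(stats::chisq.test(obs, p = rep(0.1, 10))$p.value, 0.001)
})

test_that("Dirichlet MH kernel preserves a Dirichlet target", {
  set.seed(62)
  alpha <- c(3, 5, 2)
  target <- function(l) sum((alpha - 1) * log(l))
  lam <- rep(1 / 3, 3)
  draws <- matrix(0, 20000, 3)
  for (i in seq_len(nrow(draws))) {
    st <- mh_dirichlet_step(lam, target, conc = 25)
    lam <- st$lam
    draws[i, ] <- lam
  }
  expect_lt(max(abs(colMeans(draws) - alpha / sum(alpha))), 0.02)
  # thinned first-component histogram against Beta(3, 7)
  thin <- draws[seq(10, nrow(draws), 10), 1]
  q <- stats::qbeta(seq(0.125, 0.875, 0.125), 3, 7)
  obs <- table(cut(thin, c(0, q, 1)))
  expect_gt(stats::chisq.test(obs, p = rep(1 / 8, 8))$p.value, 0.001)
})

test_that("junction Gibbs matches exact enumeration at L = 2", {
  set.seed(63)
  cl <- selection_classes(G1 = c(-5, 0, 5), G2 = -500,
                          lambda1 = c(.2, .3, .1), lambda2 = .4)
  LL <- matrix(rnorm(8), 2, 4)
  p <- 0.3
  l1n <- log(cl$lambda1 / sum(cl$lambda1))
  pz1 <- p * sum(exp(l1n + LL[1, 1:3])) * sum(exp(l1n + LL[2, 1:3]))
  pz0 <- (1 - p) * sum(exp(l1n + LL[1, 1:3] + LL[2, 1:3]))
  target <- pz1 / (pz1 + pz0)
  f0 <- dfemap:::new_window_field(FALSE, 1L, c(0L, 0L), cl)
  N <- 20000
  hits <- 0
  for (i in seq_len(N)) {
    f1 <- dfemap:::update_field_gibbs(f0, LL, cl$lambda1, cl$lambda2, p)
    hits <- hits + as.integer(f1$junction[1])
  }
  se <- sqrt(target * (1 - target) / N)
  expect_lt(abs(hits / N - target), 4 * se)
})

test_that("split-Rhat flags disagreement between chain halves", {
  set.seed(64)
  expect_equal(split_rhat(rnorm(2000)), 1, tolerance = 0.05)
  drifting <- c(rnorm(1000), rnorm(1000, 5))
  expect_gt(split_rhat(drifting), 1.5)
})

test_that("single-population fit recovers generating parameters", {
  set.seed(65)
  ds <- simulate_dataset("known_ancestor", n_seqs = 30, L = 250,
                         theta = 0.08, kappa = 3, gamma = -6, M = 800)
  fit <- popgen_fit(ds, iterations = 3000, burn_in = 800)
  e <- fit$estimates
  expect_true(e["theta", "lower"] < 0.08 && 0.08 < e["theta", "upper"])
  expect_true(e["kappa", "lower"] < 3 && 3 < e["kappa", "upper"])
  expect_true(e["gamma", "lower"] < -6 && -6 < e["gamma", "upper"])
  expect_true(all(fit$accept > 0.05 & fit$accept < 0.9))
})

test_that("lagged-ancestor fit sums over tip ancestry through the branch", {
  set.seed(66)
  ds <- simulate_dataset("lagged_ancestor", n_seqs = 20, L = 150,
                         theta = 0.1, kappa = 1, gamma = 3, M = 600)
  fit <- popgen_fit(ds, iterations = 1500, burn_in = 500)
  e <- fit$estimates
  expect_true(all(is.finite(e)))
  # theta is well identified even with uncertain ancestry
  expect_true(e["theta", "lower"] < 0.1 && 0.1 < e["theta", "upper"])
})

test_that("joint fit runs, mixes and produces coherent site posteriors", {
  set.seed(67)
  tree <- ape::read.tree(text = "(A,B,C);")
  bp <- list(A = list(theta = .12, kappa = 2, T = 2, gamma = 0),
             B = list(theta = .12, kappa = 2, T = 1, gamma = 0),
             C = list(theta = .12, kappa = 2, T = 1.5, gamma = 0))
  ds <- simulate_dataset("three_taxon", n_seqs = c(6, 6, 1), L = 40,
                         branch_params = bp, M = 300)
  fit <- dfemap(ds$locus, tree,
                dfemap_config(iterations = 120, burn_in = 40, thin = 2,
                              chains = 1))
  expect_s3_class(fit, "dfemap")
  expect_true(all(is.finite(fit$samples)))
  for (b in fit$branches) {
    ps <- fit$site_post[[b]][[1]]
    expect_equal(rowSums(ps), rep(1, 40), tolerance = 1e-10)
  }
  s <- summary(fit)
  expect_true(all(is.finite(s$estimates)))
  expect_equal(sum(s$substitutions$A$substitution_dfe), 1, tolerance = 1e-10)
  cf <- coef(fit)
  expect_true(all(cf[grep("^p_", names(cf))] >= 0 &
                    cf[grep("^p_", names(cf))] <= 1))
})

test_that("prior-only runs recover the priors of p and lambda", {
  set.seed(68)
  tree <- ape::read.tree(text = "(A,B,C);")
  bp <- lapply(c(A = 1, B = 1, C = 1), function(i)
    list(theta = .1, kappa = 2, T = 1, gamma = 0))
  ds <- simulate_dataset("three_taxon", n_seqs = c(2, 2, 1), L = 30,
                         branch_params = bp, M = 100)
  fit <- dfemap(ds$locus, tree,
                dfemap_config(iterations = 6000, burn_in = 500, thin = 5,
                              chains = 1, prior_only = TRUE))
  cf <- coef(fit)
  # Uniform(0,1) prior on p: mean 1/2
  pm <- cf[grep("^p_", names(cf))]
  expect_true(all(abs(pm - 0.5) < 0.06))
  # symmetric Dirichlet(1) on lambda: mean 1/12 each
  lam <- apply(fit$lambda, 3, mean)
  expect_true(all(abs(lam - 1 / 12) < 0.045))
  # theta draws follow their lognormal hierarchy given the sampled hypers
  th <- fit$samples[, grep("^theta_", colnames(fit$samples))]
  expect_true(all(is.finite(log(th))))
})
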