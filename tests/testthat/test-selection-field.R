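test_that("selection classes validate their weights", {
  cl <- selection_classes()
  expect_length(cl$levels, 12)
  expect_equal(sum(cl$lambda1) + sum(cl$lambda2), 1)
  expect_error(selection_classes(lambda1 = rep(0.2, 11), lambda2 = 0.5),
               "sum to 1")
})

test_that("field prior draws honour the window structure", {
  set.seed(51)
  cl <- selection_classes()
  f1 <- sample_field_prior(40, 1, cl)
  expect_true(all(f1$junction))
  expect_identical(max(f1$win_id), 40L)
  f0 <- sample_field_prior(40, 0, cl)
  expect_false(any(f0$junction))
  expect_identical(max(f0$win_id), 1L)
  # mean window length 1/p: draws at the published simulans smoothing value
  p <- 0.0277
  lens <- replicate(400, {
    f <- sample_field_prior(500, p, cl)
    mean(tabulate(f$win_id))
  })
  # windows are length-censored at the locus ends; compare the junction rate
  jr <- replicate(400, mean(sample_field_prior(500, p, cl)$junction))
  expect_lt(abs(mean(jr) - p), 4 * sd(jr) / sqrt(400))
  # and the implied mean window length is close to 1/p = 36 codons
  expect_lt(abs(1 / mean(jr) - 36), 2)
})

test_that("marginal per-codon class frequencies equal lambda", {
  set.seed(52)
  lam1 <- c(0.05, 0.02, 0.08, 0.1, 0.05, 0.3, 0.05, 0.03, 0.02, 0.02, 0.03)
  lam2 <- 0.25
  cl <- selection_classes(lambda1 = lam1, lambda2 = lam2)
  f <- sample_field_prior(1e5, 0.2, cl)
  lev <- dfemap:::field_level_index(f)
  emp <- tabulate(lev, 12) / 1e5
  lam <- c(lam1, lam2)
  se <- sqrt(lam * (1 - lam) / 1e5)
  # windows induce correlation between codons; allow a wide multiple of the
  # i.i.d. multinomial error
  expect_true(all(abs(emp - lam) < 12 * se))
})

test_that("field log prior is exact (enumeration at L = 2) and factorises at p = 1", {
  cl <- selection_classes(G1 = c(-5, 0, 5), G2 = -500,
                          lambda1 = c(.2, .3, .1), lambda2 = .4)
  p <- 0.3
  tot <- 0
  for (z in c(FALSE, TRUE)) {
    nw <- if (z) 2L else 1L
    wgs <- as.matrix(expand.grid(rep(list(1:3), nw)))
    for (r in seq_len(nrow(wgs))) for (d1 in 0:1) for (d2 in 0:1) {
      f <- dfemap:::new_window_field(z, wgs[r, ], c(d1, d2), cl)
      tot <- tot + exp(field_log_prior(f, p))
    }
  }
  expect_equal(tot, 1, tolerance = 1e-12)
  # L = 1: undeviated class i has prior lambda1_i
  f1 <- dfemap:::new_window_field(logical(0), 2L, 0L, cl)
  expect_equal(field_log_prior(f1, p), log(0.3), tolerance = 1e-12)
  # p = 1: prior factorises over codons (window level stays latent for a
  # deviated codon, so its categorical term remains)
  f2 <- dfemap:::new_window_field(c(TRUE, TRUE), c(1L, 3L, 2L), c(0L, 1L, 0L), cl)
  L1 <- 0.6
  expected <- log(0.2 / L1) + log(L1) +      # codon 1: window class 1, kept
    log(0.1 / L1) + log(0.4) +               # codon 2: latent window, deviated
    log(0.3 / L1) + log(L1)                  # codon 3: window class 2, kept
  expect_equal(field_log_prior(f2, 1), expected, tolerance = 1e-12)
})

test_that("substitution DFE matches closed forms", {
  lam <- c(`0` = 1)
  expect_equal(unname(substitution_dfe(lam)), 1)
  lam3 <- c(`-1` = 1, `0` = 1, `1` = 1) / 3
  e <- exp(1)
  expect_equal(unname(substitution_dfe(lam3)),
               c(1 / (2 * e), (e - 1) / (2 * e), 0.5), tolerance = 1e-12)
  lam4 <- c(`-500` = 0.5, `0` = 0.5)
  sd4 <- substitution_dfe(lam4)
  expect_lt(sd4["-500"], 1e-200)
  expect_error(substitution_dfe(c(`-500` = 1)), "degenerate")
})

test_that("substitution decomposition splits drift from selection", {
  expect_equal(unname(classify_substitutions(substitution_dfe(c(`0` = 1)))),
               c(0, 0, 1, 0))
  cs <- classify_substitutions(substitution_dfe(c(`1` = 1)))
  expect_equal(unname(cs["Aplus"]), exp(-1), tolerance = 1e-12)
  expect_equal(sum(cs), 1, tolerance = 1e-12)
  expect_equal(unname(classify_substitutions(substitution_dfe(c(`-1` = 1)))["Dminus"]), 1)
  # no positive mass -> A+ and D+ exactly zero
  cs2 <- classify_substitutions(substitution_dfe(c(`-5` = .3, `-1` = .4, `0` = .3)))
  expect_identical(unname(cs2["Aplus"]), 0)
  expect_identical(unname(cs2["Dplus"]), 0)
  # mass conservation for a spread DFE
  lam <- c(`-100` = .1, `-10` = .2, `0` = .3, `1` = .2, `10` = .15, `100` = .05)
  expect_equal(sum(classify_substitutions(substitution_dfe(lam))), 1,
               tolerance = 1e-12)
})

test_that("posterior site summaries follow their definitions", {
  lev <- c(-500, -1, 0, 5, 10)
  post <- rbind(c(0, 0, 0, 0, 1),
                c(0.5, 0, 0, 0.5, 0),
                rep(1 / 5, 5))
  colnames(post) <- lev
  s <- posterior_site_summaries(post)
  expect_equal(s$site$pr_positive, c(1, 0.5, 2 / 5))
  expect_equal(s$site$pr_viable, c(1, 0.5, 4 / 5))
  expect_equal(s$site$mean_gamma_viable[1], 10)
  expect_equal(s$site$mean_gamma_viable[2], 5)
  expect_identical(s$site$positive_call, c(TRUE, FALSE, FALSE))
  expect_equal(s$gene$pr_positive, mean(c(1, .5, .4)))
  expect_error(posterior_site_summaries(post[0, , drop = FALSE]), "empty")
})

test_that("class-probability correlations behave at lag zero and under shuffling", {
  set.seed(55)
  post <- matrix(runif(300), 100, 3, dimnames = list(NULL, c(-1, 0, 1)))
  c0 <- class_probability_correlation(post, lag = 0)
  expect_equal(unname(c0), rep(1, 3), tolerance = 1e-12)
  c1 <- class_probability_correlation(post[sample(100), ], lag = 1)
  expect_true(all(abs(c1) < 3 / sqrt(99)))
  # smoother fields decay more slowly
  cl <- selection_classes()
  field_post <- function(p) {
    f <- sample_field_prior(3000, p, cl)
    m <- matrix(0, 3000, 12, dimnames = list(NULL, cl$levels))
    m[cbind(1:3000, dfemap:::field_level_index(f))] <- 1
    m
  }
  s_smooth <- class_probability_correlation(field_post(0.01), lag = 5)
  s_rough <- class_probability_correlation(field_post(0.5), lag = 5)
  expect_gt(mean(s_smooth[1:11], na.rm = TRUE), mean(s_rough[1:11], na.rm = TRUE))
  # zero-variance level reported missing
  post2 <- cbind(post, `5` = rep(0.2, 100))
  expect_true(is.na(class_probability_correlation(post2, lag = 1)["5"]))
})

test_that("derived-frequency stratification resamples to a common n", {
  set.seed(56)
  post <- matrix(rep(c(0.7, 0.3), each = 50), 50, 2,
                 dimnames = list(NULL, c(0, 5)))
  # already at target n: deterministic binning
  r <- dfe_by_derived_frequency(post, derived_count = rep(3, 50),
                                n = rep(24, 50), target_n = 24)
  expect_identical(r$n_sites[r$bins == 3], 50L)
  # hypergeometric downsampling has the right mean
  d <- replicate(4000, {
    rr <- dfe_by_derived_frequency(post[1, , drop = FALSE], 24, 48, 24)
    rr$bins[which(rr$n_sites == 1)]
  })
  expect_equal(mean(d), 12, tolerance = 0.15)
  # binomial upsampling: n = 12, derived 6 -> Binomial(24, 0.5)
  b <- replicate(4000, {
    rr <- dfe_by_derived_frequency(post[1, , drop = FALSE], 6, 12, 24)
    rr$bins[which(rr$n_sites == 1)]
  })
  expect_equal(mean(b), 12, tolerance = 0.2)
  expect_equal(var(b), 24 * 0.25, tolerance = 0.5)
  # NA sites skipped
  r2 <- dfe_by_derived_frequency(post, c(NA, rep(3, 49)), rep(24, 50))
  expect_identical(sum(r2$n_sites), 49L)
})
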