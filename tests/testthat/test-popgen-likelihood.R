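test_that("log 1F1 matches high-precision reference values", {
  # references computed with 40-digit arbitrary-precision arithmetic
  expect_equal(log_1f1(2.5, 7.1, -400), -10.82772180249128, tolerance = 1e-11)
  expect_equal(log_1f1(3.2, 35.4, 250), 161.0206395410667, tolerance = 1e-11)
  expect_equal(log_1f1(0.7, 1.9, 600), 592.0244341463769, tolerance = 1e-11)
  expect_equal(log_1f1(0.7, 1.9, -600), -4.431694570354326, tolerance = 1e-11)
  expect_identical(log_1f1(1.3, 4.2, 0), 0)
  expect_equal(exp(log_1f1(1, 2, 1)), exp(1) - 1, tolerance = 1e-12)
  expect_error(log_1f1(-1, 2, 1), "a > 0")
  expect_error(log_1f1(3, 2, 1), "b >= a")
})

test_that("ancestor-tailored PIMS rates keep a parent-independent model fixed", {
  set.seed(3)
  K <- 61
  r <- runif(K, 0.001, 0.01)
  M <- matrix(r, K, K, byrow = TRUE)   # rate to j is r_j from any background
  diag(M) <- 0; diag(M) <- -rowSums(M)
  Tm <- dfemap:::cpp_pims_theta(M, 2, 2)
  for (A in c(1L, 17L, 61L)) {
    expect_equal(Tm[A, -A], 2 * r[-A], tolerance = 1e-12)
    expect_equal(Tm[A, A], 2 * r[A], tolerance = 1e-12)
  }
})

test_that("resolvent occupancy matches Monte-Carlo averaging on a 2-state toy", {
  # states A,B with asymmetric rates; occupancy of B after Exp(2) time
  rAB <- 0.13; rBA <- 0.05
  M2 <- matrix(c(-rAB, rAB, rBA, -rBA), 2, 2, byrow = TRUE)
  res <- solve(diag(2) - 2 * M2)
  set.seed(4)
  tt <- rexp(1e6, rate = 1 / 2)
  # closed-form two-state transition probability at time t
  lam <- rAB + rBA
  pAB <- (rAB / lam) * (1 - exp(-lam * tt))
  expect_lt(abs(res[1, 2] - mean(pAB)), 5 * sd(pAB) / sqrt(1e6))
  # and the tailored rate for neighbours reproduces the population-scaled rate
  mut <- mutation_rate_matrix(0.08, 1)
  pr <- pims_rates_for_ancestor(mut, "ATG")
  nbrs <- which(codon_space()$neighbor[codon_index("ATG"), ] == 1L)
  off <- mut$rates[codon_index("ATG"), nbrs]
  expect_equal(sum(pr$theta[-codon_index("ATG")]), 2 * sum(off),
               tolerance = 1e-10)
  # neighbours carry nearly all the mass; non-neighbour rates much smaller
  expect_gt(min(pr$theta[nbrs]), 50 * max(pr$theta[-c(nbrs, codon_index("ATG"))]))
  expect_true(all(pr$theta > 0))
})

test_that("conditional sample likelihood is a proper distribution at n = 1 and 2", {
  mut <- mutation_rate_matrix(0.3, 2)
  for (anc in c("ATG", "CTA")) {          # Met (no synonyms) and Leu (many)
    rates <- pims_rates_for_ancestor(mut, anc)
    tot1 <- 0
    for (i in 1:61) {
      cnt <- integer(61); cnt[i] <- 1L
      tot1 <- tot1 + conditional_sample_likelihood(site_sample(cnt), anc,
                                                   1.5, rates)
    }
    expect_equal(tot1, 1, tolerance = 1e-8)
    tot2 <- 0
    for (i in 1:61) for (j in i:61) {
      cnt <- integer(61); cnt[i] <- cnt[i] + 1L; cnt[j] <- cnt[j] + 1L
      tot2 <- tot2 + conditional_sample_likelihood(site_sample(cnt), anc,
                                                   -3, rates)
    }
    expect_equal(tot2, 1, tolerance = 1e-8)
  }
})

test_that("gamma -> 0 is continuous and the class collapse matches quadrature", {
  mut <- mutation_rate_matrix(0.3, 2)
  rates <- pims_rates_for_ancestor(mut, "ATG")
  cnt <- integer(61); cnt[codon_index("ATG")] <- 20L; cnt[codon_index("ATA")] <- 4L
  s <- site_sample(cnt)
  l0 <- conditional_sample_likelihood(s, "ATG", 0, rates, log = TRUE)
  expect_equal(conditional_sample_likelihood(s, "ATG", 1e-6, rates, log = TRUE),
               l0, tolerance = 1e-5)
  expect_equal(conditional_sample_likelihood(s, "ATG", -1e-6, rates, log = TRUE),
               l0, tolerance = 1e-5)
  # collapsed two-class system vs adaptive quadrature
  for (g in c(1.5, 0, -3, 8, -40)) {
    for (m in c(0, 1, 2)) {
      expect_equal(closed_class_prob(m, 2, 0.3, 0.12, g),
                   quad_class_prob(m, 2, 0.3, 0.12, g), tolerance = 1e-8)
    }
  }
})

test_that("likelihood favours hot samples more as gamma grows", {
  mut <- mutation_rate_matrix(0.3, 2)
  rates <- pims_rates_for_ancestor(mut, "ATG")
  hot <- integer(61); hot[codon_index("ATG")] <- 8L; hot[codon_index("GTG")] <- 4L
  cold <- integer(61); cold[codon_index("ATG")] <- 12L
  lr <- vapply(c(-5, -1, 0, 1, 5), function(g)
    conditional_sample_likelihood(site_sample(hot), "ATG", g, rates, log = TRUE) -
      conditional_sample_likelihood(site_sample(cold), "ATG", g, rates, log = TRUE),
    numeric(1))
  expect_true(all(diff(lr) > 0))
})

test_that("relabelling synonymous codons of the ancestor leaves class totals invariant", {
  mut <- mutation_rate_matrix(0.25, 2)
  sp <- codon_space()
  rates <- pims_rates_for_ancestor(mut, "CTA")
  A <- codon_index("CTA")
  partners <- setdiff(which(sp$aa_index == sp$aa_index[A]), A)
  i <- partners[1]; j <- partners[2]
  cnt <- integer(61); cnt[A] <- 10L; cnt[i] <- 3L
  l1 <- conditional_sample_likelihood(site_sample(cnt), A, -2, rates, log = TRUE)
  # swap which synonymous partner carries the copies, swapping rates to match
  th2 <- rates$theta; th2[c(i, j)] <- th2[c(j, i)]
  rates2 <- structure(list(theta = th2, ancestor = A, Theta = sum(th2)),
                      class = "pims_rates")
  cnt2 <- integer(61); cnt2[A] <- 10L; cnt2[j] <- 3L
  l2 <- conditional_sample_likelihood(site_sample(cnt2), A, -2, rates2, log = TRUE)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("Wright-Fisher sampling distributions match theory at selected parameters", {
  set.seed(1301)
  for (pars in list(c(0.3, 2, -5), c(0.3, 1, 5))) {
    emp <- simulated_class_count(pars[1], pars[2], pars[3], n = 10,
                                 n_sites = 1e5, M = 600, chains = 500)
    th <- theory_class_count(pars[1], pars[2], pars[3], n = 10)
    expect_lt(0.5 * sum(abs(emp - th)), 0.02)
  }
})
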