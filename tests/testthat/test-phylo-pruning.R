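test_that("tip partials reduce to indicators in the zero-mutation limit", {
  obs <- codon_index("ATG")
  tiny <- mutation_rate_matrix(1e-8, 2)
  tp <- tip_partial(make_monomorphic_sample("ATG", 1), tiny, 0)
  p <- exp(tp - max(tp))
  expect_identical(which.max(p), obs)
  expect_lt(max(p[-obs]), 1e-6)
  # at realistic theta the vector is non-degenerate but still peaks at the
  # observed codon
  mut <- mutation_rate_matrix(0.3, 2)
  tp2 <- tip_partial(make_monomorphic_sample("ATG", 1), mut, 0)
  expect_identical(which.max(tp2), obs)
  expect_gt(exp(max(tp2[-obs]) - tp2[obs]), 1e-6)
})

test_that("an all-derived sample gains support from a hot ancestor as gamma rises", {
  # under recurrent positive selection, derived amino acids are driven to
  # high frequency, so a sample monomorphic for a non-ancestral amino acid
  # becomes relatively more probable the larger gamma is; the cold
  # (same-amino-acid) ancestor is still always the better explanation
  mut <- mutation_rate_matrix(0.3, 2)
  s <- make_monomorphic_sample("ATG", 24)
  cold <- codon_index("ATG")
  hot <- codon_index("GTG")   # different amino acid: sample is all-hot for it
  r <- vapply(c(-10, 0, 10), function(g) {
    tp <- tip_partial(s, mut, g)
    tp[hot] - tp[cold]
  }, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 0))
})

test_that("pruning equals brute-force summation over root states on 3-taxon trees", {
  set.seed(31)
  tree <- ape::read.tree(text = "(A:1,B:0.5,C:2);")
  muts <- list(A = mutation_rate_matrix(0.12, 2.5),
               B = mutation_rate_matrix(0.05, 1.2),
               C = mutation_rate_matrix(0.2, 3))
  gs <- list(A = 1.2, B = -4, C = 0)
  Ts <- c(A = 1, B = 0.5, C = 2)
  obs <- c(A = "ATG", B = "ATA", C = "CTA")
  edge_sp <- dfemap:::star_branches(tree)
  tp <- lapply(names(obs), function(s)
    tip_partial(make_monomorphic_sample(obs[s], 1), muts[[s]], gs[[s]]))
  names(tp) <- names(obs)
  Ps <- lapply(seq_len(3), function(e) {
    s <- edge_sp[e]
    transition_probabilities(substitution_rate_matrix(muts[[s]], gs[[s]]), Ts[s])
  })
  expect_equal(prune_site(tree, tp, Ps), brute_force_site(tree, tp, Ps),
               tolerance = 1e-10)
  # symmetry: swapping two tips with identical parameters and samples
  tree2 <- ape::read.tree(text = "(A:1,B:1,C:2);")
  tpx <- list(A = tp$A, B = tp$A, C = tp$C)
  Px <- list(Ps[[1]], Ps[[1]], Ps[[3]])
  ll1 <- prune_site(tree2, tpx, Px)
  tpy <- list(A = tp$A, B = tp$A, C = tp$C)
  ll2 <- prune_site(tree2, tpy, list(Px[[2]], Px[[1]], Px[[3]]))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("degenerate trees behave: single tip at v = 0 gives 1/61", {
  tree <- ape::read.tree(text = "(A:0,B:0);")
  tiny <- mutation_rate_matrix(1e-10, 1)
  tp <- tip_partial(make_monomorphic_sample("ATG", 1), tiny, 0)
  P0 <- diag(61)
  # two-tip star with both tips observing the same codon at v = 0 collapses
  # to the root prior mass on that codon times the indicator products
  ll <- prune_site(tree, list(A = tp, B = tp), list(P0, P0))
  expect_equal(ll, log(1 / 61), tolerance = 1e-4)
  expect_error(prune_site(tree, list(A = rep(-Inf, 61), B = tp),
                          list(P0, P0)), "all-zero")
})

test_that("likelihood is invariant to re-rooting along a branch in the neutral case", {
  mut <- mutation_rate_matrix(0.15, 2)
  Q <- substitution_rate_matrix(mut, 0)
  tp <- list(A = tip_partial(make_monomorphic_sample("ATG", 3), mut, 0),
             B = tip_partial(make_monomorphic_sample("ATA", 2), mut, 0),
             C = tip_partial(make_monomorphic_sample("CTA", 1), mut, 0))
  star <- ape::read.tree(text = "(A:1,B:1,C:2);")
  Ps_star <- lapply(c(1, 1, 2), function(v) transition_probabilities(Q, v))
  ll_star <- prune_site(star, tp, Ps_star)
  # root placed midway along the branch to A
  rooted <- ape::read.tree(text = "(A:0.4,(B:1,C:2):0.6);")
  ed <- rooted$edge
  lens <- rooted$edge.length
  Ps_root <- lapply(lens, function(v) transition_probabilities(Q, v))
  ll_root <- prune_site(rooted, tp, Ps_root)
  expect_equal(ll_star, ll_root, tolerance = 1e-10)
})

test_that("infinitely long branches decouple the tips", {
  mut <- mutation_rate_matrix(0.2, 1.5)
  Q <- substitution_rate_matrix(mut, 0)
  tree <- ape::read.tree(text = "(A:1,B:1,C:1);")
  tp <- list(A = tip_partial(make_monomorphic_sample("ATG", 2), mut, 0),
             B = tip_partial(make_monomorphic_sample("GGG", 2), mut, 0),
             C = tip_partial(make_monomorphic_sample("CCA", 1), mut, 0))
  Pinf <- transition_probabilities(Q, 1e5)
  ll <- prune_site(tree, tp, list(Pinf, Pinf, Pinf))
  expect_equal(ll, sum(vapply(tp, function(v) log(mean(exp(v))), numeric(1))),
               tolerance = 1e-6)
})

test_that("locus log-likelihood sums independent sites", {
  set.seed(33)
  tree <- ape::read.tree(text = "(A,B,C);")
  bp <- list(A = list(theta = .1, kappa = 2, T = 1, gamma = 0),
             B = list(theta = .1, kappa = 2, T = .5, gamma = 0),
             C = list(theta = .1, kappa = 2, T = 1.5, gamma = 0))
  ds <- simulate_dataset("three_taxon", n_seqs = c(3, 3, 1), L = 4,
                         branch_params = bp, M = 150)
  bpp <- lapply(bp, function(x) x[c("theta", "kappa", "T")])
  ll <- locus_log_likelihood(ds$locus, tree, bpp, gamma = 0)
  expect_true(is.finite(ll))
  # additivity: restrict to single columns and sum
  parts <- vapply(1:4, function(j) {
    sub <- ds$locus
    sub$species <- lapply(sub$species, function(m) m[, j, drop = FALSE])
    sub$n_codons <- 1L
    locus_log_likelihood(sub, tree, bpp, gamma = 0)
  }, numeric(1))
  expect_equal(ll, sum(parts), tolerance = 1e-10)
  # empty locus
  empty <- ds$locus
  empty$species <- lapply(empty$species, function(m) m[, 0, drop = FALSE])
  empty$n_codons <- 0L
  expect_identical(locus_log_likelihood(empty, tree, bpp, gamma = 0), 0)
})
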