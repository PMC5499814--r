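# independent matrix exponential: scaling and squaring with a plain
# Taylor series, used as the oracle for the pruning likelihood
.expm_series <- function(M, order = 40, squarings = 8) {
  n <- nrow(M)
  A <- M / 2^squarings
  S <- diag(n); Fk <- diag(n)
  for (k in seq_len(order)) {
    Fk <- Fk %*% A / k
    S <- S + Fk
  }
  for (i in seq_len(squarings)) S <- S %*% S
  S
}

test_that("the GY94 generator has the stated structure", {
  g <- build_generator(kappa = 1, omega = 1, pi = rep(1 / 61, 61))
  expect_equal(max(abs(rowSums(g))), 0, tolerance = 1e-12)
  ty <- posiselect:::codon_tables()$type
  expect_true(all(g[ty == 0 & row(g) != col(g)] == 0))
  expect_true(all(g[ty > 0] > 0))

  # detailed balance and unit expected rate under skewed frequencies
  set.seed(2)
  pi <- rexp(61); pi <- pi / sum(pi)
  g2 <- build_generator(kappa = 3, omega = 0.4, pi = pi)
  flux <- pi * g2
  expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-14)
  expect_equal(-sum(pi * diag(g2)), 1, tolerance = 1e-12)
  expect_error(build_generator(2, 0.5, rep(1, 61)), "sum to 1")
})

test_that("transition probabilities behave like a Markov semigroup", {
  set.seed(5)
  pi <- rexp(61); pi <- pi / sum(pi)
  g <- build_generator(kappa = 2, omega = 0.3, pi = pi)
  expect_equal(transition_probs(g, 0), diag(61), tolerance = 1e-10,
               ignore_attr = TRUE)
  P <- transition_probs(g, 0.3)
  expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-10)
  expect_equal(transition_probs(g, 0.1) %*% transition_probs(g, 0.2), P,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(transition_probs(g, 150),
               matrix(pi, 61, 61, byrow = TRUE), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("pruning collapses to stationary probabilities on zero trees", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  st <- matrix(rep(posiselect:::codon_states("ATG"), 3), 3, 1,
               dimnames = list(c("A", "B", "C"), NULL))
  ll <- branch_site_loglik(st, tr, "A", p0 = 0.5, p1 = 0.4, omega0 = 0.2,
                           omega2 = 2, kappa = 2, pi = rep(1 / 61, 61))
  expect_equal(ll, log(1 / 61), tolerance = 1e-9)
  # duplicated column doubles the log-likelihood exactly
  ll2 <- branch_site_loglik(cbind(st, st), tr, "A", p0 = 0.5, p1 = 0.4,
                            omega0 = 0.2, omega2 = 2, kappa = 2,
                            pi = rep(1 / 61, 61))
  expect_equal(ll2, 2 * ll, tolerance = 1e-12)
})

test_that("two-taxon likelihood equals the series-expm oracle to 1e-8", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.3);")
  pi <- rep(1 / 61, 61)
  for (codons in list(c("ATG", "AAA"), c("TGG", "TGG"), c("GAT", "CAT"))) {
    sA <- posiselect:::codon_states(codons[1])
    sB <- posiselect:::codon_states(codons[2])
    st <- matrix(c(sA, sB), 2, 1, dimnames = list(c("A", "B"), NULL))
    for (w in c(0.2, 1, 3)) {
      ll <- branch_site_loglik(st, tr, "A", p0 = 1 - 1e-12, p1 = 5e-13,
                               omega0 = w, omega2 = 1, kappa = 2, pi = pi)
      Q <- build_generator(2, w, pi, normalize = FALSE)
      P <- .expm_series(Q * 0.5)
      oracle <- log(sum(pi[sA] * P[sA, sB]))
      expect_equal(ll, oracle, tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to leaf order and tree rotation", {
  fam <- fixture_family(seed = 2, root_length = 60)
  tx <- fam$transcripts
  aln <- codon_align(list(transcripts = tx))
  st <- aln$states
  tr <- default_mammal_tree()
  args <- list(p0 = 0.6, p1 = 0.3, omega0 = 0.2, omega2 = 3, kappa = 2)
  ll1 <- do.call(branch_site_loglik, c(list(st, tr, "human"), args,
                                       list(pi = rep(1 / 61, 61))))
  ll2 <- do.call(branch_site_loglik,
                 c(list(st[rev(rownames(st)), ], tr, "human"), args,
                   list(pi = rep(1 / 61, 61))))
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  ll3 <- do.call(branch_site_loglik, c(list(st, tr2, "human"), args,
                                       list(pi = rep(1 / 61, 61))))
  expect_equal(ll1, ll2, tolerance = 1e-9)
  expect_equal(ll1, ll3, tolerance = 1e-9)
})

test_that("chi-square quantiles map to the textbook p-values", {
  expect_equal(lrt(0, 3.841459 / 2)$p_value, 0.05, tolerance = 1e-6)
  expect_equal(lrt(0, 6.634897 / 2)$p_value, 0.01, tolerance = 1e-6)
  r <- lrt(-100, -100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # clamping: a slightly "worse" alternative is treated as stat 0
  expect_equal(lrt(-99.9, -100)$statistic, 0)
})

test_that("site posteriors normalize and vanish when p2 is zero", {
  fam <- fixture_family(seed = 3, root_length = 60)
  aln <- codon_align(list(transcripts = fam$transcripts))
  mask <- filter_columns(aln)
  st <- aln$states[, mask$keep, drop = FALSE]
  fit <- fit_branch_site(st, default_mammal_tree(), "human", "alternative")
  post <- site_posteriors(fit)
  expect_length(post, sum(mask$keep))
  expect_true(all(post >= 0 & post <= 1))
  # posteriors over the 4 classes sum to 1 at every pattern
  w <- posiselect:::mixture_weights(fit$p0, fit$p1)
  norm <- colSums(w * fit$class_lik / rep(colSums(w * fit$class_lik),
                                          each = 4))
  expect_equal(unname(norm), rep(1, ncol(fit$class_lik)), tolerance = 1e-12)
  # p2a = p2b = 0 forces all posteriors to 0
  fit0 <- fit
  fit0$p0 <- 0.7; fit0$p1 <- 0.3
  expect_true(all(site_posteriors(fit0) == 0))
})

test_that("alternative fit nests the null on arbitrary inputs", {
  for (seed in 1:3) {
    fam <- fixture_family(seed = seed, root_length = 80)
    aln <- codon_align(list(transcripts = fam$transcripts))
    mask <- filter_columns(aln)
    st <- aln$states[, mask$keep, drop = FALSE]
    fit <- fit_branch_site(st, default_mammal_tree(), "human",
                           "alternative")
    expect_gte(fit$lnL, fit$null$lnL - 1e-6)
  }
})

test_that("M0 recovers the generating omega on single-ratio data", {
  # simulate under a one-class scheme with omega = 0.35; no indels so the
  # alignment is exact and conservation filtering is skipped
  sc <- list(omega_values = 0.35, probabilities = 1, label = "custom",
             fg_fraction = 0, fg_omega = NA)
  set.seed(10)
  cfg <- simulation_config(root_length = 400, scheme = sc,
                           indels = indel_model(subst_indel_ratio = 1e12))
  sim <- evolve(cfg, "g1")
  aln <- codon_align(list(transcripts = sim$transcripts))
  fit <- fit_branch_site(aln$states, default_mammal_tree(), "human", "m0")
  expect_gt(fit$omega, 0.35 * 0.7)
  expect_lt(fit$omega, 0.35 * 1.4)
  expect_gt(fit$kappa, 2 * 0.7)
  expect_lt(fit$kappa, 2 * 1.4)
})
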