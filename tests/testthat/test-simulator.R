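test_that("the baseline omega distribution has the stated mean and no
          positive selection", {
  b <- baseline_omega_distribution()
  expect_equal(sum(b$omega * b$prob), 0.21222, tolerance = 1e-9)
  expect_true(all(b$omega <= 1))
  expect_true(all(b$omega > 0))
  expect_equal(sum(b$prob), 1)
})

test_that("schemes A-E solve the mixture-mean equation", {
  # hand-solved example: f=0.01, target 0.9, baseline mean 0.21222
  sA <- build_scheme("A")
  expect_equal(sA$fg_omega, 68.99022, tolerance = 1e-5)
  fr <- c(A = 0.01, B = 0.03, C = 0.05, D = 0.07, E = 0.09)
  for (lab in names(fr)) {
    s <- build_scheme(lab)
    expect_equal(s$fg_fraction, unname(fr[lab]))
    expect_equal(scheme_mean_omega(s), 0.9, tolerance = 1e-9)
    expect_gte(s$fg_omega, 1)
  }
  sN <- build_scheme("N")
  expect_equal(scheme_mean_omega(sN), 0.21222, tolerance = 1e-9)
  expect_true(is.na(sN$fg_omega))
  # infeasible mixture: target too low for the requested fraction
  expect_error(build_scheme("custom", fg_fraction = 0.9, target_mean = 0.3),
               "infeasible")
})

test_that("indel lengths are geometric with the printed moments", {
  m <- indel_model(q = 0.35)
  expect_equal(m$mean, 1 / 0.65, tolerance = 1e-12)  # 1.54 codons
  expect_equal(m$sd, sqrt(0.35) / 0.65, tolerance = 1e-12)  # 0.91 codons
  expect_equal(round(m$mean, 2), 1.54)
  expect_equal(round(m$sd, 2), 0.91)
  set.seed(1)
  x <- sample_indel_length(m, 1e5)
  expect_true(all(x >= 1))
  se <- m$sd / sqrt(length(x))
  expect_lt(abs(mean(x) - m$mean), 3 * se)
  # q -> 0 degenerates to length 1
  expect_true(all(sample_indel_length(indel_model(q = 1e-12), 100) == 1))
})

test_that("zero-length trees copy the root to every leaf", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  set.seed(2)
  cfg <- simulation_config(tree = tr, root_length = 50)
  sim <- evolve(cfg)
  expect_equal(length(unique(sim$transcripts$cds)), 1L)
  expect_equal(unname(sim$counts), c(0, 0, 0))
})

test_that("realized substitutions match the branch-length expectation", {
  # one informative branch, one-class scheme at omega 1, no indels:
  # substitution count ~ Poisson(root_length * t)
  tr <- ape::read.tree(text = "(A:0.4,B:0);")
  sc1 <- list(omega_values = 1, probabilities = 1, label = "custom",
              fg_fraction = 0, fg_omega = NA)
  set.seed(3)
  cfg <- simulation_config(tree = tr, root_length = 2500, kappa = 1,
                           scheme = sc1,
                           indels = indel_model(subst_indel_ratio = 1e12),
                           branch_scale = 1)
  sim <- evolve(cfg)
  lambda <- 2500 * 0.4
  expect_lt(abs(sim$counts[["n_sub"]] - lambda), 3 * sqrt(lambda))
})

test_that("the substitution:indel event ratio approaches 43", {
  set.seed(4)
  tot <- c(0, 0)
  for (r in 1:12) {
    sim <- evolve(simulation_config(root_length = 150))
    tot <- tot + c(sim$counts[["n_sub"]],
                   sim$counts[["n_ins"]] + sim$counts[["n_del"]])
  }
  # binomial 3-SE band around the event-rate ratio 1:43
  p <- 1 / 44
  n <- sum(tot)
  phat <- tot[2] / n
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("identical seeds give byte-identical families", {
  set.seed(7)
  s1 <- evolve(simulation_config(root_length = 80))
  set.seed(7)
  s2 <- evolve(simulation_config(root_length = 80))
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$counts, s2$counts)
})

test_that("selected sites carry the foreground annotation to the leaves", {
  set.seed(8)
  sE <- build_scheme("E")  # 9% selected: plenty at this length
  cfg <- simulation_config(root_length = 300, tested_branch = "human",
                           tested_scheme = sE)
  sim <- evolve(cfg, return_alignment = TRUE)
  sel <- vapply(sim$site_info, function(d) sum(d$selected), numeric(1))
  expect_true(all(sel > 0))
  expect_lt(abs(mean(sim$site_info$human$selected) - 0.09), 0.06)
  # true alignment: every leaf recoverable from its row
  aln <- sim$alignment
  for (s in rownames(aln)) {
    obs <- aln[s, !is.na(aln[s, ])]
    expect_equal(paste(sense_codons()[obs], collapse = ""),
                 sim$transcripts$cds[sim$transcripts$species == s])
  }
})

test_that("an empty validation run returns an empty summary", {
  v <- run_validation("N", "terminal", n_reps = 0, seed = 1)
  expect_equal(v$summary$n, 0)
  expect_null(v$table)
})
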