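test_that("pruning equals exhaustive state enumeration on small trees", {
  models <- list(
    substitution_model("JC69"),
    substitution_model("HKY85", base_freqs = c(.35, .2, .15, .3), kappa = 4,
                       alpha = 0.6),
    substitution_model("GTR", base_freqs = c(.3, .25, .2, .25),
                       rates = c(1.5, 4, .8, 1.2, 6, 1), p_inv = 0.2)
  )
  trees <- list(
    read_tree("((A:0.12,B:0.3):0.05,(C:0.2,D:0.08):0.11);"),
    read_tree("((A:0.1,B:0.2):0.07,(C:0.15,D:0.3):0.04,E:0.22);")
  )
  for (tr in trees) {
    a <- rand_aln(length(tr$tip.label), 12, seed = 11, p_missing = 0.1)
    rownames(a) <- tr$tip.label
    a <- aln(unclass(a))
    for (m in models) {
      expect_equal(log_likelihood(tr, a, m), enum_log_likelihood(tr, a, m),
                   tolerance = 1e-10)
    }
  }
})

test_that("identical sequences at vanishing distance give ln(1/4) per site", {
  a <- aln(c(A = strrep("A", 50), B = strrep("A", 50)))
  tr <- read_tree("(A:1e-9,B:1e-9);")
  m <- substitution_model("JC69")
  expect_equal(log_likelihood(tr, a, m), 50 * log(1 / 4), tolerance = 1e-4)
})

test_that("log-likelihood is invariant under re-rooting (pulley principle)", {
  tr <- rand_tree(7, seed = 21)
  a <- rand_aln(7, 80, seed = 22)
  m <- substitution_model("HKY85", base_freqs = c(.3, .2, .2, .3), kappa = 3,
                          alpha = 0.8)
  base <- log_likelihood(tr, a, m)
  for (og in c("t2", "t5")) {
    rerooted <- ape::root(tr, og, resolve.root = TRUE)
    expect_equal(log_likelihood(rerooted, a, m), base, tolerance = 1e-8)
  }
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  tr <- rand_tree(6, seed = 31)
  a <- rand_aln(6, 150, seed = 32)
  m <- substitution_model("HKY85", base_freqs = c(.3, .2, .2, .3), kappa = 3,
                          alpha = 0.6, p_inv = 0.1)
  fit <- phangorn::pml(tr, phangorn::phyDat(unclass(a)),
                       bf = c(.3, .2, .2, .3), Q = c(1, 3, 1, 1, 3, 1),
                       k = 4, shape = 0.6, inv = 0.1)
  expect_equal(log_likelihood(tr, a, m), fit$logLik, tolerance = 1e-6)
})

test_that("site-wise log-likelihoods sum to the total", {
  tr <- rand_tree(5, seed = 41)
  a <- rand_aln(5, 60, seed = 42, p_missing = 0.05)
  m <- substitution_model("GTR", base_freqs = c(.3, .25, .2, .25),
                          rates = c(1.5, 4, .8, 1.2, 6, 1), alpha = 0.9)
  sw <- sitewise_lnL(tr, a, m)
  expect_length(sw, 60)
  expect_equal(sum(sw), log_likelihood(tr, a, m), tolerance = 1e-8)
})

test_that("branch-length optimization recovers a known divergence", {
  true_t <- 0.1
  tr <- read_tree(sprintf("(A:%f,B:%f);", true_t / 2, true_t / 2))
  m <- substitution_model("JC69")
  a <- simulate_alignment(tr, m, 20000, seed = 51)
  fit <- optimize_branch_lengths(read_tree("(A:0.5,B:0.5);"), a, m)
  t_hat <- sum(fit$edge.length)
  p <- 0.75 * (1 - exp(-4 * true_t / 3))
  se_t <- sqrt(p * (1 - p) / 20000) / abs(0.75 * 4 / 3 * exp(-4 * true_t / 3))
  expect_lt(abs(t_hat - true_t), 3 * se_t)
})

test_that("branch-length optimization is monotone and stable at the optimum", {
  tr <- rand_tree(6, seed = 61)
  a <- rand_aln(6, 120, seed = 62)
  m <- substitution_model("K80", kappa = 2)
  start_lnL <- log_likelihood(tr, a, m)
  fit <- optimize_branch_lengths(tr, a, m)
  expect_gte(attr(fit, "lnL"), start_lnL)
  expect_true(all(fit$edge.length >= 0 & fit$edge.length <= 10))
  refit <- optimize_branch_lengths(fit, a, m)
  expect_lt(abs(attr(refit, "lnL") - attr(fit, "lnL")), 1e-4)
  for (s in 1:8) {
    tr_s <- rand_tree(5, seed = 70 + s)
    a_s <- rand_aln(5, 60, seed = 80 + s)
    f <- optimize_branch_lengths(tr_s, a_s, m)
    expect_gte(attr(f, "lnL"), log_likelihood(tr_s, a_s, m) - 1e-9)
  }
})

test_that("NNI search equals exhaustive evaluation on four taxa", {
  m <- substitution_model("JC69")
  gen <- read_tree("((A:0.2,B:0.2):0.15,(C:0.2,D:0.2):0.15);")
  a <- simulate_alignment(gen, m, 400, seed = 91)
  topos <- radsplit:::enumerate_topologies(c("A", "B", "C", "D"))
  exhaustive <- vapply(topos, function(tt) {
    tt$edge.length <- rep(0.1, nrow(tt$edge))
    attr(optimize_branch_lengths(tt, a, m), "lnL")
  }, numeric(1))
  start <- topos[[2]]
  start$edge.length <- rep(0.1, nrow(start$edge))
  found <- nni_search(start, a, m)
  expect_equal(attr(found, "lnL"), max(exhaustive), tolerance = 1e-3)
  best_topo <- topos[[which.max(exhaustive)]]
  expect_true(topo_equal(found, best_topo))
})

test_that("NNI search never decreases the likelihood and finds truth on clean data", {
  m <- substitution_model("HKY85", base_freqs = c(.3, .2, .2, .3), kappa = 3)
  truth <- read_tree(paste0("((A:0.15,B:0.15):0.1,((C:0.1,D:0.1):0.1,",
                            "(E:0.12,F:0.12):0.08):0.05);"))
  a <- simulate_alignment(ape::unroot(truth), m, 2000, seed = 101)
  start <- radsplit:::random_topology(sort(truth$tip.label))
  start$edge.length <- rep(0.1, nrow(start$edge))
  start_lnL <- attr(optimize_branch_lengths(start, a, m), "lnL")
  found <- nni_search(start, a, m)
  expect_gte(attr(found, "lnL"), start_lnL)
  expect_true(topo_equal(found, truth))
})

test_that("AIC model selection is consistent and orders nested fits sanely", {
  # nested pair with (near) identical lnL: fewer parameters wins
  gen <- substitution_model("JC69")
  tr <- read_tree("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  a <- simulate_alignment(tr, gen, 800, seed = 111)
  fits <- select_model_aic(a, candidate_set = c("JC69", "K80", "HKY85", "GTR"))
  ids <- vapply(fits, `[[`, character(1), "model_id")
  lnls <- vapply(fits, `[[`, numeric(1), "lnL")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_false(is.unsorted(aics))
  # richer models can only improve lnL
  expect_gte(lnls[ids == "GTR"] + 1e-3, lnls[ids == "JC69"])
  ks <- vapply(fits, `[[`, numeric(1), "n_params")
  expect_equal(aics, 2 * ks - 2 * lnls)
  # strong rate heterogeneity: a +G model must beat every no-G model
  gen_g <- substitution_model("GTR", base_freqs = c(.3, .25, .2, .25),
                              rates = c(1.5, 4, .8, 1.2, 6, 1), alpha = 0.3)
  tr2 <- rand_tree(6, seed = 112, mean_bl = 0.3)
  a2 <- simulate_alignment(tr2, gen_g, 1500, seed = 113)
  fits2 <- select_model_aic(a2)
  best <- fits2[[1]]$model_id
  expect_match(best, "\\+G")
})
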