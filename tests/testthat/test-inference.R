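test_that("the exponential log prior has its closed form", {
  st <- mcmc_settings(prior_rate = 2)
  expect_equal(log_prior(rate_params(0, 0), st, "2param"), 2 * log(2))
  expect_equal(log_prior(rate_params(0.5, 0.25), st, "2param"),
               2 * log(2) - 2 * 0.75)
  expect_equal(log_prior(rate_params(0.5, 0.25, 0.1), st, "3param"),
               3 * log(2) - 2 * 0.85)
  expect_identical(log_prior(list(delta = -0.1, gamma = 0.2, rho = 0), st), -Inf)
})

test_that("settings validation catches inconsistent protocols", {
  expect_error(mcmc_settings(burnin = 1000), "burnin")
  expect_error(mcmc_settings(prior_rate = 0), "prior_rate")
  expect_s3_class(mcmc_settings(n_generations = 0, burnin = 0), "mcmc_settings")
})

small_matched <- function(seed = 101, n = 20) {
  tr <- simulate_tree(n, 0.15, seed = seed)
  space <- build_state_space(1, 40, padding_fraction = 0)
  sim <- simulate_counts(tr, rate_params(0.2, 0.2), 12, space, seed = seed + 1)
  matched_data(tr, sim$tip_counts)
}

test_that("chains are deterministic under a seed, pin rho, and honor n_generations = 0", {
  m <- small_matched()
  st <- mcmc_settings(n_generations = 60, burnin = 30, seed = 7)
  d1 <- suppressWarnings(run_mcmc(m, "2param", st))
  d2 <- suppressWarnings(run_mcmc(m, "2param", st))
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 30)
  expect_true(all(d1$rho == 0))
  expect_true(all(d1$delta >= 0 & d1$gamma >= 0))
  expect_false(identical(d1$delta,
                         suppressWarnings(run_mcmc(m, "2param",
                                                   mcmc_settings(60, 30, seed = 8)))$delta))

  empty <- run_mcmc(m, "2param", mcmc_settings(n_generations = 0, burnin = 0))
  expect_equal(nrow(empty), 0)

  d3 <- suppressWarnings(run_mcmc(m, "3param", mcmc_settings(40, 20, seed = 9)))
  expect_true(any(d3$rho > 0))
})

test_that("data-free chains recover the Exp(2) prior mean", {
  st <- mcmc_settings(n_generations = 4000, burnin = 500, seed = 11)
  draws <- suppressWarnings(
    run_mcmc(NULL, "2param", st, loglik_fn = function(p) 0))
  expect_lt(abs(mean(draws$delta) - 0.5), 0.05)
  expect_lt(abs(mean(draws$gamma) - 0.5), 0.05)
})

test_that("the sampler targets the posterior computed on a dense grid", {
  # tiny 2-state problem where the posterior is tractable by quadrature
  tree <- ape::read.tree(text = "((A:1.5,B:1.5):1,C:2.5);")
  sp <- build_state_space(5, 6, padding_fraction = 0)
  m <- matched_data(tree, setNames(c(5L, 6L, 5L), tree$tip.label))
  st <- mcmc_settings(n_generations = 20000, burnin = 1000, seed = 17)
  draws <- suppressWarnings(run_mcmc(m, "2param", st, space = sp))

  f <- karyorate:::make_loglik(m, sp)
  grid <- seq(0.025, 6, by = 0.05)
  joint <- outer(grid, grid, Vectorize(function(d, g) {
    exp(f(rate_params(d, g)) - 2 * (d + g))
  }))
  marg_delta <- rowSums(joint) / sum(joint)
  breaks <- c(seq(0, 3, by = 0.25), Inf)
  grid_bin <- as.vector(tapply(marg_delta, cut(grid, breaks), sum))
  grid_bin[is.na(grid_bin)] <- 0
  mcmc_bin <- as.vector(table(cut(draws$delta, breaks))) / nrow(draws)
  expect_lt(sum(abs(grid_bin - mcmc_bin)) / 2, 0.05)
})

test_that("multi-tree pooling keeps the protocol's sample counts and spacing", {
  # single tree: all post-burn-in draws retained
  tr <- simulate_tree(12, 0.15, seed = 61)
  space <- build_state_space(1, 30, padding_fraction = 0)
  sim <- simulate_counts(tr, rate_params(0.15, 0.15), 10, space, seed = 62)
  rec <- make_records(species = names(sim$tip_counts),
                      haploid_count = as.integer(sim$tip_counts))
  st1 <- mcmc_settings(n_generations = 50, burnin = 20, seed = 5)
  single <- suppressWarnings(run_multitree(tr, rec, "2param", st1))
  expect_equal(nrow(single), 30)

  # tree set: n_trees x samples_per_tree pooled draws, evenly spaced
  trees <- c(tr, simulate_tree(12, 0.15, seed = 63), simulate_tree(12, 0.15, seed = 64))
  class(trees) <- "multiPhylo"
  rec_all <- rec  # same species names in every simulated tree
  st <- mcmc_settings(n_generations = 50, burnin = 20, seed = 5,
                      samples_per_tree = 3, n_trees = 2)
  pooled <- suppressWarnings(run_multitree(trees, rec_all, "2param", st))
  expect_equal(nrow(pooled), 6)
  expect_equal(length(unique(pooled$tree_id)), 2)
  expect_equal(sort(unique(pooled$generation)), c(30, 40, 50))

  # fewer trees than n_trees: sampled with replacement, logged
  st_over <- mcmc_settings(n_generations = 30, burnin = 10, seed = 5,
                           samples_per_tree = 2, n_trees = 5)
  expect_message(over <- suppressWarnings(run_multitree(trees, rec_all, "2param", st_over)),
                 "replacement")
  expect_equal(nrow(over), 10)

  # identical settings + seed give identical per-tree retained draws
  p2 <- suppressWarnings(run_multitree(trees, rec_all, "2param", st))
  expect_identical(pooled, p2)
})

test_that("doubling branch lengths halves posterior-mean rates", {
  # the companion claim -- that the ratio distribution is unchanged -- is
  # checked at full study scale in the acceptance suite, where the
  # per-dataset identifiability of the ratio supports a meaningful band
  tr <- simulate_tree(60, 0.1, seed = 71)
  space <- build_state_space(1, 40, padding_fraction = 0)
  sim <- simulate_counts(tr, rate_params(0.25, 0.25), 12, space, seed = 72)
  m <- matched_data(tr, sim$tip_counts)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  m2 <- matched_data(tr2, sim$tip_counts)
  st <- mcmc_settings(n_generations = 300, burnin = 150, seed = 73)
  d1 <- suppressWarnings(run_mcmc(m, "2param", st))
  d2 <- suppressWarnings(run_mcmc(m2, "2param", st))
  expect_lt(abs(mean(d2$delta) - mean(d1$delta) / 2), 0.3 * mean(d1$delta) / 2)
  expect_lt(abs(mean(d2$gamma) - mean(d1$gamma) / 2), 0.3 * mean(d1$gamma) / 2)
})
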