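test_that("pure-birth trees are ultrametric and deterministic under a seed", {
  tr2 <- simulate_tree(2, birth_rate = 1, seed = 5)
  expect_equal(length(tr2$tip.label), 2)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths[1], depths[2])

  a <- ape::write.tree(simulate_tree(50, 0.1, seed = 42))
  b <- ape::write.tree(simulate_tree(50, 0.1, seed = 42))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(50, 0.1, seed = 43))))

  expect_error(simulate_tree(1, 0.1), "n_tips")
  expect_error(simulate_tree(10, 0.1, death_rate = 0.1), "death_rate")
  expect_error(simulate_tree(10, 0.1, death_rate = 0.2), "death_rate")
})

test_that("mean root depth of pure-birth trees matches the analytic expectation", {
  # depth = sum of Exp(k * birth) waits for k = 2..n
  n <- 100
  birth <- 0.1
  expected <- sum(1 / (2:n)) / birth
  mc_sd <- sqrt(sum(1 / (2:n)^2) / birth^2)
  set.seed(1234)
  depths <- replicate(500, max(ape::node.depth.edgelength(simulate_tree(n, birth))))
  expect_lt(abs(mean(depths) - expected), 4 * mc_sd / sqrt(500))
})

test_that("depth rescaling and birth-death pruning behave", {
  tr <- simulate_tree(40, 0.2, death_rate = 0.1, seed = 9, tree_depth_target = 75)
  expect_equal(length(tr$tip.label), 40)
  expect_equal(max(ape::node.depth.edgelength(tr)), 75)
})

test_that("zero rates leave every tip at the root count with an empty log", {
  tr <- simulate_tree(20, 0.1, seed = 3)
  space <- build_state_space(1, 40, padding_fraction = 0)
  sim <- simulate_counts(tr, rate_params(0, 0, 0), 12, space, seed = 4)
  expect_true(all(sim$tip_counts == 12))
  expect_equal(nrow(sim$events), 0)
})

test_that("count simulation is deterministic and validates the root count", {
  tr <- simulate_tree(15, 0.1, seed = 8)
  space <- build_state_space(5, 20, padding_fraction = 0)
  s1 <- simulate_counts(tr, rate_params(0.3, 0.3), 10, space, seed = 11)
  s2 <- simulate_counts(tr, rate_params(0.3, 0.3), 10, space, seed = 11)
  expect_identical(s1, s2)
  expect_error(simulate_counts(tr, rate_params(0.3, 0.3), 4, space), "root_count")
})

test_that("event counts along root-to-tip paths reconcile with tip counts", {
  tr <- simulate_tree(60, 0.1, seed = 14)
  space <- build_state_space(1, 60, padding_fraction = 0)
  sim <- simulate_counts(tr, rate_params(0.25, 0.25, 0.02), 12, space, seed = 15)
  ev <- sim$events
  # per-edge net change equals count_after - count_before summed over events
  tr_clade <- ape::reorder.phylo(tr, "cladewise")
  n_tip <- length(tr_clade$tip.label)
  node_count <- rep(NA_integer_, n_tip + tr_clade$Nnode)
  node_count[n_tip + 1L] <- 12L
  for (e in seq_len(nrow(tr_clade$edge))) {
    pa <- tr_clade$edge[e, 1]; ch <- tr_clade$edge[e, 2]
    gain <- if (any(ev$edge == e)) sum(ev$count_after[ev$edge == e] - ev$count_before[ev$edge == e]) else 0L
    node_count[ch] <- node_count[pa] + gain
  }
  expect_equal(unname(node_count[seq_len(n_tip)]), unname(sim$tip_counts[tr_clade$tip.label]))
  # events never leave the state space
  expect_true(all(ev$count_after >= space$min_count & ev$count_after <= space$max_count))
})

test_that("total event count tracks (delta + gamma) x total tree length", {
  tr <- simulate_tree(200, 0.1, seed = 21)
  space <- build_state_space(1, 200, padding_fraction = 0)  # interior: bounds never bind
  lambda <- 0.4 * sum(tr$edge.length)
  set.seed(22)
  n_events <- vapply(1:25, function(i) {
    nrow(simulate_counts(tr, rate_params(0.2, 0.2), 50, space)$events)
  }, 1)
  # Poisson(lambda) mean, checked within Monte-Carlo error
  expect_lt(abs(mean(n_events) - lambda), 4 * sqrt(lambda / 25))
})

test_that("single-branch tip distribution matches the matrix exponential row", {
  # fission-only process on one branch vs the generator's expm row
  space <- build_state_space(1, 12, padding_fraction = 0)
  params <- rate_params(0, 0.4, 0)
  t_branch <- 2.5
  start <- 4L
  set.seed(31)
  ends <- vapply(1:4000, function(i) {
    karyorate:::simulate_branch(start, t_branch, params, space)$count
  }, 1L)
  emp <- tabulate(ends, nbins = 12)[space$counts] / 4000
  theo <- transition_matrix(params, space, t_branch)[as.character(start), ]
  expect_lt(sum(abs(emp - theo)) / 2, 0.02)
})

test_that("sex-system tables plant the requested fraction of fused genera", {
  tab <- simulate_sexsystem_table(20, 4, fusion_fraction = 1, seed = 1)
  expect_equal(fusion_signal(tab)$fraction, 1.0)
  tab0 <- simulate_sexsystem_table(20, 4, fusion_fraction = 0, seed = 2)
  expect_equal(fusion_signal(tab0)$fraction, 0.0)
  tab43 <- simulate_sexsystem_table(58, 4, fusion_fraction = 0.43, seed = 3)
  expect_equal(attr(tab43, "n_fused"), 25)
  res <- fusion_signal(tab43)
  expect_equal(res$n_genera_derived_fewer, 25L)
  expect_equal(res$n_genera_with_both, 58L)
  expect_error(simulate_sexsystem_table(10, 1, 0.5), "species_per_genus")
})
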