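test_that("transition matrix satisfies identity, semigroup and stationarity", {
  sp <- build_state_space(1, 8, padding_fraction = 0)
  params <- rate_params(0.3, 0.5)
  expect_equal(transition_matrix(params, sp, 0),
               diag(8), ignore_attr = TRUE)
  expect_error(transition_matrix(params, sp, -1), "t must be")

  # semigroup: P(t + s) = P(t) P(s)
  set.seed(5)
  for (i in 1:5) {
    t <- runif(1, 0.1, 5); s <- runif(1, 0.1, 5)
    expect_lt(max(abs(transition_matrix(params, sp, t + s) -
                        transition_matrix(params, sp, t) %*%
                        transition_matrix(params, sp, s))), 1e-8)
  }

  # long-time limit: all rows equal the stationary distribution
  P_inf <- transition_matrix(params, sp, 2000)
  pi0 <- stationary_oracle(rate_matrix(params, sp))
  for (i in 1:8) expect_lt(max(abs(P_inf[i, ] - pi0)), 1e-8)
})

test_that("pruning equals brute-force enumeration on small trees", {
  trees <- small_trees()
  set.seed(7)
  for (nm in names(trees)) {
    tree <- trees[[nm]]
    sp <- build_state_space(1, 4, padding_fraction = 0)
    counts <- setNames(sample(sp$counts, length(tree$tip.label), replace = TRUE),
                       tree$tip.label)
    m <- matched_data(tree, counts)
    for (i in 1:3) {
      params <- rate_params(runif(1, 0.05, 1), runif(1, 0.05, 1), runif(1, 0, 0.3))
      for (root in c("weighted_by_partials", "flat")) {
        expect_equal(log_likelihood(m, params, sp, likelihood_settings(root)),
                     oracle_loglik(tree, counts, params, sp, root),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate cases: zero rates and single tips reduce to the root prior", {
  sp <- build_state_space(1, 5, padding_fraction = 0)
  tree <- ape::read.tree(text = "(A:1,B:1,C:1);")
  m_same <- matched_data(tree, setNames(c(3L, 3L, 3L), tree$tip.label))
  expect_equal(log_likelihood(m_same, rate_params(0, 0, 0), sp,
                              likelihood_settings("flat")), log(1 / 5))
  m_diff <- matched_data(tree, setNames(c(3L, 4L, 3L), tree$tip.label))
  expect_identical(log_likelihood(m_diff, rate_params(0, 0, 0), sp), -Inf)

  # single tip attached at the root: only the root prior contributes
  tip1 <- ape::read.tree(text = "(A:0);")
  m1 <- matched_data(tip1, c(A = 2L))
  expect_equal(log_likelihood(m1, rate_params(0.4, 0.2), sp,
                              likelihood_settings("flat")), log(1 / 5))
})

test_that("tip counts outside the space name the offending tips", {
  sp <- build_state_space(1, 4, padding_fraction = 0)
  tree <- ape::read.tree(text = "(A:1,(B:1,C:1):1);")
  m <- matched_data(tree, setNames(c(2L, 9L, 3L), tree$tip.label))
  expect_error(log_likelihood(m, rate_params(0.1, 0.1), sp), "B")
})

test_that("likelihood is invariant to tip order, ladderization, and branch/rate rescaling", {
  set.seed(13)
  tree <- simulate_tree(25, 0.15, seed = 99)
  sp <- build_state_space(2, 30)
  counts <- setNames(sample(5:20, 25, replace = TRUE), tree$tip.label)
  params <- rate_params(0.3, 0.4, 0.05)
  base <- log_likelihood(matched_data(tree, counts), params, sp)

  rot <- ape::rotateConstr(tree, sample(tree$tip.label))
  expect_equal(log_likelihood(matched_data(rot, counts), params, sp), base,
               tolerance = 1e-10)
  lad <- ape::ladderize(tree)
  expect_equal(log_likelihood(matched_data(lad, counts), params, sp), base,
               tolerance = 1e-10)

  # stretching the tree by c and dividing rates by c changes nothing
  for (c_scale in c(2, 10)) {
    stretched <- tree
    stretched$edge.length <- stretched$edge.length * c_scale
    scaled <- rate_params(params$delta / c_scale, params$gamma / c_scale,
                          params$rho / c_scale)
    expect_equal(log_likelihood(matched_data(stretched, counts), scaled, sp),
                 base, tolerance = 1e-8)
  }
})

test_that("likelihood is smooth in the rates (central differences agree)", {
  tree <- simulate_tree(15, 0.15, seed = 31)
  sp <- build_state_space(3, 25)
  set.seed(32)
  counts <- setNames(sample(8:15, 15, replace = TRUE), tree$tip.label)
  m <- matched_data(tree, counts)
  f <- function(d) log_likelihood(m, rate_params(d, 0.3), sp)
  h1 <- 1e-4; h2 <- 5e-5
  d1 <- (f(0.4 + h1) - f(0.4 - h1)) / (2 * h1)
  d2 <- (f(0.4 + h2) - f(0.4 - h2)) / (2 * h2)
  expect_lt(abs(d1 - d2), 1e-3 * max(1, abs(d1)))
})

test_that("polytomies are handled natively", {
  poly <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  sp <- build_state_space(1, 4, padding_fraction = 0)
  counts <- setNames(c(1L, 2L, 2L, 3L), poly$tip.label)
  params <- rate_params(0.3, 0.5)
  expect_equal(log_likelihood(matched_data(poly, counts), params, sp),
               oracle_loglik(poly, counts, params, sp), tolerance = 1e-12)
})
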