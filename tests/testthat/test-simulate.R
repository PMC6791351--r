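test_that("initial tree size follows the retained-tip rule", {
  expect_equal(initial_tree_size(0.1), 333L)
  expect_equal(initial_tree_size(0.5), 600L)
  expect_equal(initial_tree_size(0), 300L)
  expect_equal(initial_tree_size(0.9), 3000L)
  expect_error(initial_tree_size(1), "< 1")
})

test_that("Yule trees are ultrametric, unit height, and seed-reproducible", {
  tr <- simulate_yule_tree(333, seed = 3)
  expect_equal(length(tr$tip.label), 333L)
  expect_equal(tree_height(tr), 1, tolerance = 1e-9)
  depths <- node_depths(tr)[tr$tip.label]
  expect_lt(diff(range(depths)), 1e-9)
  expect_identical(write_newick(simulate_yule_tree(50, seed = 9)),
                   write_newick(simulate_yule_tree(50, seed = 9)))
  two <- simulate_yule_tree(2, seed = 1)
  expect_equal(sort(two$edge.length), c(1, 1))
  expect_error(simulate_yule_tree(1), "n_tips")
})

test_that("Mk regime simulation matches the equal-rates transition law", {
  tr2 <- read_newick("(A:1,B:1);")
  # q = 0: no transitions anywhere
  p0 <- simulate_mk_regimes(tr2, q = 0, seed = 1)
  expect_equal(length(unique(p0$node_state)), 1L)

  # unit branch, q = 0.5: P(child != parent) = (1 - exp(-1))/2
  set.seed(42)
  n_sim <- 5000L
  flips <- replicate(n_sim, {
    p <- simulate_mk_regimes(tr2, q = 0.5)
    root <- p$node_state[3]
    c(p$node_state[1] != root, p$node_state[2] != root)
  })
  p_hat <- mean(flips)
  p_true <- (1 - exp(-1)) / 2
  se <- sqrt(p_true * (1 - p_true) / (2 * n_sim))
  expect_lt(abs(p_hat - p_true), 3 * se)

  # q -> infinity: tip states approach independent fair coins
  set.seed(43)
  s1 <- replicate(2000, simulate_mk_regimes(tr2, q = 50)$node_state[1])
  expect_lt(abs(mean(s1) - 0.5), 3 * sqrt(0.25 / 2000))

  # edges carry the parent node's state
  tr <- simulate_yule_tree(30, seed = 7)
  p <- simulate_mk_regimes(tr, 0.5, seed = 8)
  expect_equal(p$edge_state, p$node_state[tr$edge[, 1]])
})

test_that("regime balance check uses the minority share among retained tips", {
  tr <- simulate_yule_tree(10, seed = 1)
  mk_states <- function(tip_states) {
    regime_painting(tr, c(tip_states, rep(0L, tr$Nnode)))
  }
  p30 <- mk_states(c(rep(1L, 3), rep(0L, 7)))
  expect_true(regime_balance_ok(p30, tr, tr$tip.label))
  p20 <- mk_states(c(rep(1L, 2), rep(0L, 8)))
  expect_false(regime_balance_ok(p20, tr, tr$tip.label))
  p50 <- mk_states(c(rep(1L, 5), rep(0L, 5)))
  expect_false(regime_balance_ok(p50, tr, tr$tip.label))
  # balance is judged on the retained subset only
  retained <- tr$tip.label[c(1:3, 4:6)]  # 3 of 6 in state 1 -> 50%
  expect_false(regime_balance_ok(p30, tr, retained))
})

test_that("trait simulation reproduces the exact OU transition moments", {
  tr2 <- read_newick("(A:1,B:1);")
  spec <- model_spec("OU", sigma2_0 = 0.5, theta_0 = 11, alpha = 1.5,
                     root_value = 10)
  set.seed(7)
  draws <- replicate(5000, simulate_trait(tr2, NULL, spec))
  x <- as.numeric(draws)  # tips are conditionally independent (t_a = 0)
  m_true <- 11 - exp(-1.5)
  v_true <- 0.5 / 3 * (1 - exp(-3))
  expect_lt(abs(mean(x) - m_true), 3 * sqrt(v_true / length(x)))
  expect_lt(abs(var(x) - v_true), 3 * v_true * sqrt(2 / length(x)))
})

test_that("degenerate zero-length trees return the root value everywhere", {
  tr0 <- read_newick("((A:0,B:0):0,C:0);")
  spec <- model_spec("BM")
  expect_equal(unname(simulate_trait(tr0, NULL, spec, seed = 1)),
               rep(10, 3))
  expect_equal(unname(simulate_liability(tr0, seed = 1)), rep(0, 3))
})

test_that("BM tip covariance across replicates matches sigma2 x shared time", {
  tr <- simulate_yule_tree(12, seed = 21)
  spec <- model_spec("BM", sigma2_0 = 0.5)
  set.seed(22)
  reps <- replicate(4000, simulate_trait(tr, NULL, spec))
  reps <- reps[sort(rownames(reps)), ]
  emp <- cov(t(reps))
  V <- 0.5 * mrca_depths(tr)
  n <- ncol(reps)
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / n)
  expect_true(all(abs(emp - V) < 3.5 * se))
})

test_that("OU tip covariance across replicates matches the fixed-root kernel", {
  tr <- simulate_yule_tree(10, seed = 31)
  spec <- model_spec("OU")
  set.seed(32)
  reps <- replicate(4000, simulate_trait(tr, NULL, spec))
  reps <- reps[sort(rownames(reps)), ]
  emp <- cov(t(reps))
  V <- spec$sigma2_0 * ou_covariance(tr, spec$alpha)
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / ncol(reps))
  expect_true(all(abs(emp - V) < 3.5 * se))
})

test_that("OU simulation with tiny alpha reproduces BM moments", {
  tr <- simulate_yule_tree(8, seed = 41)
  ou <- model_spec("OU", sigma2_0 = 0.5, alpha = 1e-6, theta_0 = 10)
  set.seed(42)
  reps <- replicate(3000, simulate_trait(tr, NULL, ou))
  reps <- reps[sort(rownames(reps)), ]
  emp <- cov(t(reps))
  V <- 0.5 * mrca_depths(tr)
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / ncol(reps))
  expect_true(all(abs(emp - V) < 3.5 * se))
  expect_lt(max(abs(rowMeans(reps) - 10)), 3 * sqrt(max(diag(V)) / 3000) * 3)
})

test_that("liability simulation is Brownian with unit rate", {
  tr <- simulate_yule_tree(25, seed = 51)
  set.seed(52)
  reps <- replicate(3000, simulate_liability(tr))
  v <- apply(reps, 1, var)
  expect_lt(abs(mean(v) - 1), 0.1)  # marginal variance = depth = 1
  expect_identical(simulate_liability(tr, seed = 5),
                   simulate_liability(tr, seed = 5))
})
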