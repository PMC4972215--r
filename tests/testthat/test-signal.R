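test_that("parsimony transition counts match hand-computable cases", {
  tr <- tree4()
  expect_equal(parsimony_transitions(tr, c(A = 0, B = 0, C = 1, D = 1)), 1L)
  expect_equal(parsimony_transitions(tr, c(A = 0, B = 1, C = 0, D = 1)), 2L)
  expect_equal(parsimony_transitions(tr, c(A = 2, B = 2, C = 2, D = 2)), 0L)
  # polytomies handled natively (Sankoff)
  st <- star_tree(5)
  states <- setNames(c(0, 0, 1, 1, 2), st$tip.label)
  expect_equal(parsimony_transitions(st, states), 3L)
})

test_that("parsimony equals exhaustive enumeration and phangorn on random instances", {
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (rep in 1:40) {
    tr <- random_yule(6, 1000 + rep)
    states <- setNames(sample(0:3, 6, replace = TRUE), tr$tip.label)
    mine <- parsimony_transitions(tr, states)
    expect_identical(mine, exhaustive_parsimony(tr, states))
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = as.character(0:6))
    expect_equal(mine, as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("discrete signal test is seeded, conservative on constant data", {
  tr <- random_yule(20, 31)
  states <- simulate_mk_trait(tr, 7, rate = 0.005, seed = 5)
  r1 <- discrete_signal_test(tr, states, R = 199, seed = 42)
  r2 <- discrete_signal_test(tr, states, R = 199, seed = 42)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_value, r2$p_value)
  expect_length(r1$null, 199L)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)

  const <- setNames(rep(2, 20), tr$tip.label)
  rc <- discrete_signal_test(tr, const, R = 99, seed = 1)
  expect_equal(rc$observed, 0L)
  expect_equal(rc$p_value, 1)
})

test_that("low-rate discrete characters show signal (fewer transitions than null)", {
  wins <- 0L
  for (rep in 1:10) {
    tr <- random_yule(50, 600 + rep, lambda = 0.05)
    states <- simulate_mk_trait(tr, 7, rate = 0.004, seed = 700 + rep)
    if (length(unique(states)) == 1L) next
    res <- discrete_signal_test(tr, states, R = 99, seed = rep)
    if (res$observed < res$null_median) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("Blomberg's K matches the independent phytools implementation", {
  skip_if_not_installed("phytools")
  for (seed in 1:4) {
    tr <- random_yule(25, 50 + seed)
    x <- setNames(rnorm(25), tr$tip.label)
    expect_equal(blomberg_k(tr, x),
                 unname(phytools::phylosig(tr, x, method = "K")[1]),
                 tolerance = 1e-6)
  }
})

test_that("K is invariant to affine trait transforms and branch scaling", {
  tr <- random_yule(20, 77)
  x <- setNames(rnorm(20), tr$tip.label)
  k0 <- blomberg_k(tr, x)
  expect_equal(blomberg_k(tr, 3.2 * x - 5), k0)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 42
  expect_equal(blomberg_k(tr2, x), k0, tolerance = 1e-10)
  expect_error(blomberg_k(tr, setNames(rep(1, 20), tr$tip.label)), "constant")
})

test_that("white-noise traits on a deep tree give K well below 1", {
  tr <- rescale_tree_height(random_yule(40, 88), 100)
  ks <- vapply(1:50, function(i) {
    set.seed(9000 + i)
    blomberg_k(tr, setNames(rnorm(40), tr$tip.label))
  }, numeric(1))
  expect_lt(median(ks), 0.7)
})

test_that("K randomization test is seeded and detects Brownian signal", {
  tr <- rescale_tree_height(random_yule(40, 99), 100)
  x <- simulate_trait(tr, "BM", c(sigma2 = 0.01, z0 = 0), seed = 3)
  r1 <- k_significance(tr, x, R = 199, seed = 11)
  r2 <- k_significance(tr, x, R = 199, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null, r2$null)
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$K, blomberg_k(tr, x))
})
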