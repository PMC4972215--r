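test_that("Yule simulator is seed-deterministic and ultrametric", {
  t1 <- simulate_yule_tree(2, 0.5, seed = 1)
  expect_equal(ape::Ntip(t1), 2L)
  expect_true(is_ultrametric(t1))

  a <- write_newick(simulate_yule_tree(30, 0.1, seed = 9))
  b <- write_newick(simulate_yule_tree(30, 0.1, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, write_newick(simulate_yule_tree(30, 0.1, seed = 10))))
})

test_that("Mk simulator: near-zero rate freezes the root state", {
  tr <- random_yule(25, 91)
  x <- simulate_mk_trait(tr, 7, rate = 1e-10, seed = 2, root_state = 3)
  expect_true(all(x == 3))
  expect_equal(parsimony_transitions(tr, x), 0L)
})

test_that("Mk simulator reaches the uniform equilibrium on long branches", {
  st <- star_tree(3000, len = 1)
  # rate * t = 50 per pair: saturated
  x <- simulate_mk_trait(st, 4, rate = 50, seed = 3)
  tab <- table(factor(x, levels = 0:3))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("saturated discrete characters carry no phylogenetic signal", {
  ps <- vapply(1:20, function(i) {
    tr <- rescale_tree_height(random_yule(30, 300 + i), 1)
    x <- simulate_mk_trait(tr, 7, rate = 50, seed = 400 + i)
    discrete_signal_test(tr, x, R = 99, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)   # roughly uniform p-values, not skewed small
})

test_that("paper-like dataset has the study's dimensions and passes invariants", {
  ds <- make_paperlike_dataset(seed = 5)
  expect_equal(ape::Ntip(ds$tree), 77L)
  expect_true(is_ultrametric(ds$tree))
  expect_equal(tree_height(ds$tree), 150, tolerance = 1e-9)
  expect_true(all(ds$versatility >= 0 & ds$versatility <= 6))
  expect_true(all(exp(ds$log_cell_size) > 0))
  expect_true(all(is.finite(ds$log_cell_size)))
  expect_equal(sort(names(ds$log_cell_size)), sort(ds$tree$tip.label))
  expect_s3_class(ds$painting, "regime_painting")
  expect_equal(nlevels(ds$painting$regimes), 2L)
  expect_gte(nrow(ds$calibrations), 2L)
  # the genetic-distance tree shares the topology but not the clock
  expect_false(is_ultrametric(ds$gd_tree, tol = 1e-3))
  expect_equal(sort(ds$gd_tree$tip.label), sort(ds$tree$tip.label))
})

test_that("the manifest regenerates the dataset bit-identically", {
  d1 <- make_paperlike_dataset(seed = 11, n = 30)
  d2 <- make_paperlike_dataset(seed = d1$manifest$seed, n = d1$manifest$n,
                               root_age = d1$manifest$root_age)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$table, d2$table)
  expect_identical(d1$corr_trait, d2$corr_trait)

  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$seed, 11L)
  d3 <- make_paperlike_dataset(seed = man$seed, n = man$n,
                               root_age = man$root_age)
  expect_identical(write_newick(d3$tree), write_newick(d1$tree))
})

test_that("correlated trait pair recovers the generating slope sign", {
  hits <- 0L
  for (seed in 1:15) {
    ds <- make_paperlike_dataset(seed = 1000 + seed, n = 40)
    fit <- fit_pgls(ds$tree, ds$corr_trait,
                    setNames(as.numeric(ds$versatility), names(ds$versatility)))
    if (unname(fit$coefficients["slope"]) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 14L)
})
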