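test_that("exact fits: perfect line and the lambda = 0 / OLS equivalence", {
  tr <- rescale_tree_height(random_yule(20, 61), 100)
  x <- setNames(rnorm(20), tr$tip.label)
  y <- 2 * x
  ols <- fit_ols_star(tr, y, x)
  expect_equal(unname(ols$coefficients), c(0, 2), tolerance = 1e-10)
  expect_equal(ols$r_squared_ols, 1, tolerance = 1e-10)

  y2 <- setNames(0.5 * x + rnorm(20, sd = 0.3), names(x))
  p0 <- fit_pgls(tr, y2, x, lambda = 0)
  o <- fit_ols_star(tr, y2, x)
  expect_equal(p0$coefficients, o$coefficients, tolerance = 1e-8)
  expect_error(fit_pgls(tr, y2, setNames(rep(1, 20), names(x))), "singular")
})

test_that("profiled lambda is at least as good as the endpoints", {
  for (seed in 1:4) {
    tr <- rescale_tree_height(random_yule(30, 70 + seed), 100)
    x <- simulate_mk_trait(tr, 7, 0.002, seed = 80 + seed)
    y <- 0.4 * x + simulate_trait(tr, "BM", c(sigma2 = 1 / 100, z0 = 0),
                                  seed = 90 + seed)
    fit <- fit_pgls(tr, y, setNames(as.numeric(x), names(x)))
    l0 <- fit_pgls(tr, y, setNames(as.numeric(x), names(x)), lambda = 0)
    l1 <- fit_pgls(tr, y, setNames(as.numeric(x), names(x)), lambda = 1)
    expect_gte(fit$lnL, l0$lnL - 1e-8)
    expect_gte(fit$lnL, l1$lnL - 1e-8)
    expect_true(fit$lambda >= 0 && fit$lambda <= 1)
    expect_equal(fit$k, 4L)
    expect_equal(l0$k, 4L)
    expect_equal(fit_ols_star(tr, y, setNames(as.numeric(x), names(x)))$k, 3L)
  }
})

test_that("PGLS agrees with nlme::gls + corPagel", {
  skip_if_not_installed("nlme")
  tr <- rescale_tree_height(random_yule(40, 75), 100)
  x <- setNames(as.numeric(simulate_mk_trait(tr, 7, 0.002, seed = 76)),
                tr$tip.label)
  set.seed(78)
  y <- 0.5 * x + simulate_trait(tr, "BM", c(sigma2 = 1 / 200, z0 = 1), seed = 77) +
    rnorm(40, sd = 0.4)                     # i.i.d. component: interior lambda
  df <- data.frame(y = as.numeric(y), x = as.numeric(x),
                   sp = factor(tr$tip.label, levels = tr$tip.label),
                   row.names = tr$tip.label)

  # fixed lambda: likelihood and coefficients must coincide
  mine_f <- fit_pgls(tr, y, x, lambda = 0.7)
  ref_f <- nlme::gls(y ~ x, data = df,
                     correlation = ape::corPagel(0.7, tr, form = ~ sp,
                                                 fixed = TRUE),
                     method = "ML")
  expect_equal(unname(mine_f$coefficients), unname(coef(ref_f)),
               tolerance = 1e-6)
  expect_equal(mine_f$lnL, as.numeric(stats::logLik(ref_f)), tolerance = 1e-6)

  # ML lambda: estimates agree when nlme's unconstrained optimum is interior
  mine <- fit_pgls(tr, y, x)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corPagel(0.5, tr, form = ~ sp),
                   method = "ML")
  lam_ref <- unname(coef(ref$modelStruct$corStruct))
  if (lam_ref >= 0 && lam_ref <= 1) {
    expect_equal(mine$lambda, lam_ref, tolerance = 1e-2)
    expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-3)
    expect_equal(mine$lnL, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  }
})

test_that("R-squared variants hit their boundary cases", {
  tr <- rescale_tree_height(random_yule(20, 78), 100)
  x <- setNames(rnorm(20), tr$tip.label)
  y <- 3 * x
  perfect <- fit_ols_star(tr, y, x)
  expect_equal(r_squared(perfect, "ols"), 1, tolerance = 1e-10)
  expect_equal(r_squared(perfect, "gls"), 1, tolerance = 1e-10)

  # slope-free response: both variants near zero
  set.seed(79)
  flat <- fit_ols_star(tr, setNames(rnorm(20), tr$tip.label), x)
  expect_lt(abs(r_squared(flat, "ols")), 0.3)
})

test_that("independent noise gives a near-zero slope at large n", {
  tr <- rescale_tree_height(random_yule(150, 80), 100)
  set.seed(81)
  x <- setNames(rnorm(150), tr$tip.label)
  y <- setNames(rnorm(150), tr$tip.label)
  fit <- fit_ols_star(tr, y, x)
  expect_lt(abs(unname(fit$coefficients["slope"])), 0.25)
})
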