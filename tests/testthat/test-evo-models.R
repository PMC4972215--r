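test_that("white-noise fit equals the closed-form i.i.d. normal likelihood", {
  tr <- random_yule(15, 5)
  x <- setNames(rnorm(15, 3, 2), tr$tip.label)
  fit <- fit_continuous(tr, x, "WN")
  n <- 15
  s2 <- sum((x - mean(x))^2) / n
  expect_equal(fit$lnL, sum(dnorm(x, mean(x), sqrt(s2), log = TRUE)),
               tolerance = 1e-10)
  expect_equal(unname(fit$params["z0"]), mean(x), tolerance = 1e-10)
  expect_equal(fit$k, 2L)
})

test_that("BM fit on a two-tip tree matches the hand-derived bivariate normal", {
  tr <- parse_newick("(A:3,B:3);")
  x <- c(A = 1, B = 5)
  # need n >= k + 2; evaluate the likelihood identity directly instead
  m <- mean(x)
  s2 <- sum((x - m)^2) / (2 * 3)            # MLE rate, V = s2 * 3 * I
  lnl_hand <- sum(dnorm(x, m, sqrt(s2 * 3), log = TRUE))
  expect_equal(model_loglik(tr, x, "BM", list(sigma2 = s2, z0 = m)),
               lnl_hand, tolerance = 1e-10)
})

test_that("delta = 1 reduces to BM exactly and EB converges to BM as a -> 0", {
  tr <- rescale_tree_height(random_yule(20, 6), 100)
  x <- simulate_trait(tr, "BM", c(sigma2 = 0.02, z0 = 1), seed = 2)
  bm <- fit_continuous(tr, x, "BM")
  pars <- list(sigma2 = bm$params[["sigma2"]], z0 = bm$params[["z0"]])
  expect_equal(model_loglik(tr, x, "delta", c(pars, delta = 1)), bm$lnL,
               tolerance = 1e-12)
  expect_equal(model_loglik(tr, x, "EB", c(pars, a = -1e-9)), bm$lnL,
               tolerance = 1e-4)
  # fitted delta/EB can only improve on their BM special case
  expect_gte(fit_continuous(tr, x, "delta")$lnL, bm$lnL - 1e-6)
})

test_that("vcv-based likelihood equals the pruning recursion", {
  set.seed(404)
  for (rep in 1:20) {
    tr <- random_yule(6, 2000 + rep)
    x <- setNames(rnorm(6), tr$tip.label)
    s2 <- runif(1, 0.1, 2)
    z0 <- rnorm(1)
    lnl_vcv <- model_loglik(tr, x, "BM", list(sigma2 = s2, z0 = z0))
    lnl_prune <- pruning_bm_loglik(tr, x, s2, z0)
    expect_equal(lnl_vcv, lnl_prune, tolerance = 1e-6)
  }
})

test_that("OU and EB refuse non-ultrametric trees", {
  tr <- parse_newick("((A:1,B:2):1,C:4);")
  x <- c(A = 1, B = 2, C = 3)
  expect_error(fit_continuous(tr, x, "OU"), "ultrametric")
  expect_error(fit_continuous(tr, x, "EB"), "ultrametric")
})

test_that("AICc ranking and Akaike weights behave at the boundaries", {
  tr <- rescale_tree_height(random_yule(20, 7), 50)
  x <- simulate_trait(tr, "BM", c(sigma2 = 0.05, z0 = 0), seed = 3)
  f <- fit_continuous(tr, x, "BM")
  expect_equal(aicc_compare(list(f))$weight, 1)
  two <- aicc_compare(list(f, f))
  expect_equal(two$weight, c(0.5, 0.5))
  expect_equal(f$AICc, aicc(f$lnL, f$k, f$n))
  tab <- aicc_compare(lapply(c("BM", "OU", "WN"),
                             function(m) fit_continuous(tr, x, m)))
  expect_equal(sum(tab$weight), 1)
  expect_equal(min(tab$dAICc), 0)
})

test_that("trait simulation matches its target covariance", {
  tr <- tree3()
  # sigma2 = 0: every tip at the root state
  expect_equal(unname(simulate_trait(tr, "BM", c(sigma2 = 0, z0 = 4))),
               rep(4, 3))
  set.seed(11)
  draws <- replicate(8000, simulate_trait(tr, "BM", c(sigma2 = 0.7, z0 = 0)))
  emp <- cov(t(draws))
  expect_equal(emp, 0.7 * phylo_vcv(tr), tolerance = 0.05)
})

test_that("OU at large alpha reaches the stationary variance with no covariance", {
  tr <- tree3()
  alpha <- 50
  s2 <- 2
  set.seed(12)
  draws <- replicate(8000, simulate_trait(tr, "OU",
                                          c(alpha = alpha, sigma2 = s2, theta = 0)))
  emp <- cov(t(draws))
  expect_equal(unname(diag(emp)), rep(s2 / (2 * alpha), 3), tolerance = 0.06)
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.01 * s2 / (2 * alpha) + 0.003)
})

test_that("regime painting partitions branches and flags degenerate clades", {
  tr <- random_yule(12, 13)
  p <- paint_clade(tr, tr$tip.label[3])
  expect_equal(sum(p$regimes == "clade"), 1L)        # one terminal branch
  expect_equal(length(p$regimes), nrow(tr$edge))     # painted + unpainted = all
  root_kids_tips <- tr$tip.label[c(1, 12)]
  expect_error(paint_clade(tr, root_kids_tips), "whole tree")
})

test_that("degenerate multi-regime fits collapse to their single-regime versions", {
  tr <- rescale_tree_height(random_yule(18, 14), 100)
  x <- simulate_trait(tr, "BM", c(sigma2 = 0.01, z0 = 0), seed = 4)
  uni <- paint_uniform(tr)
  expect_equal(fit_multiregime(tr, x, uni, "OUM")$lnL,
               fit_multiregime(tr, x, uni, "OU1")$lnL, tolerance = 1e-6)
  expect_equal(fit_multiregime(tr, x, uni, "BMS")$lnL,
               fit_multiregime(tr, x, uni, "BM1")$lnL, tolerance = 1e-10)
  # with real regimes the richer models can only improve the likelihood
  p <- paint_clade(tr, pick_clade_tips(tr, 4, 9))
  bm1 <- fit_multiregime(tr, x, p, "BM1")
  bms <- fit_multiregime(tr, x, p, "BMS")
  ou1 <- fit_multiregime(tr, x, p, "OU1")
  oum <- fit_multiregime(tr, x, p, "OUM")
  expect_gte(bms$lnL, bm1$lnL - 1e-6)
  expect_gte(oum$lnL, ou1$lnL - 1e-6)
  expect_equal(bm1$k, 2L)
  expect_equal(ou1$k, 3L)
  expect_equal(bms$k, 3L)
  expect_equal(oum$k, 4L)
})

test_that("BMS recovers a strong rate contrast between regimes", {
  tr <- rescale_tree_height(random_yule(40, 15), 100)
  p <- paint_clade(tr, pick_clade_tips(tr, 8, 20))
  # simulate BM with a 25x faster clade by scaling painted branches
  tr_fast <- tr
  tr_fast$edge.length[p$regimes == "clade"] <-
    tr$edge.length[p$regimes == "clade"] * 25
  x <- simulate_trait(tr_fast, "BM", c(sigma2 = 0.01, z0 = 0), seed = 5)
  fit <- fit_multiregime(tr, x, p, "BMS")
  rates <- fit$params[startsWith(names(fit$params), "sigma2_")]
  expect_gt(rates[["sigma2_clade"]] / rates[["sigma2_background"]], 3)
})
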