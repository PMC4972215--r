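#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL maximized log-likelihood.
#' @param k number of free parameters (including the root state / mean).
#' @param n number of species.
#' @return numeric AICc.
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: need n >= k + 2", call. = FALSE)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.MODELS_SINGLE <- c("BM", "OU", "EB", "delta", "WN")

# Correlation structure (VCV up to sigma^2) for each single-regime model.
# C is the BM vcv in time units; Tmax its height. expm1 keeps the OU and EB
# forms numerically exact in the BM limit (alpha -> 0, a -> 0).
.model_cor <- function(model, par, C, Tmax) {
  n <- nrow(C)
  switch(model,
    BM = C,
    OU = {
      alpha <- par[["alpha"]]
      depth <- diag(C)
      d <- outer(depth, depth, "+") - 2 * C        # patristic distance
      -expm1(-2 * alpha * C) * exp(-alpha * d) / (2 * alpha)
    },
    EB = {
      a <- par[["a"]]
      expm1(a * C) / a                              # integral of exp(a t) over shared path
    },
    delta = {
      dl <- par[["delta"]]
      Tmax * (C / Tmax)^dl                          # node depths raised to power delta
    },
    WN = diag(n),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# GLS profile likelihood: for V = sigma2 * R and mean X beta, both beta and
# sigma2 have closed-form MLEs; returns the profiled lnL.
.gls_profile <- function(R, x, X = NULL) {
  n <- length(x)
  if (is.null(X)) X <- matrix(1, n, 1L)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(list(lnL = -Inf, ok = FALSE))
  logdet <- 2 * sum(log(diag(ch)))
  xi <- backsolve(ch, x, transpose = TRUE)
  Xi <- backsolve(ch, X, transpose = TRUE)
  fit <- qr(Xi)
  beta <- qr.coef(fit, xi)
  resid <- xi - Xi %*% ifelse(is.na(beta), 0, beta)
  q <- sum(resid^2)
  if (q <= 0) return(list(lnL = -Inf, ok = FALSE))
  sig2 <- q / n
  list(lnL = -0.5 * n * log(2 * pi * sig2) - 0.5 * logdet - 0.5 * n,
       sig2 = sig2, beta = drop(beta), ok = TRUE)
}

# Deterministic 1-D search: coarse grid scan, then nlminb refinement from the
# best grid point. All positive shape parameters are profiled out beforehand,
# so every model fit reduces to (at most) this 1-D problem.
.optimize_1d <- function(obj, lower, upper, n_grid = 41L, tol = 1e-8) {
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(grid, obj, numeric(1L))
  start <- grid[which.min(vals)]
  opt <- nlminb(start, obj, lower = lower, upper = upper,
                control = list(rel.tol = tol, iter.max = 500L))
  best_grid <- min(vals)
  if (opt$objective <= best_grid) {
    list(par = opt$par, objective = opt$objective,
         converged = opt$convergence == 0L)
  } else {
    list(par = start, objective = best_grid, converged = TRUE)
  }
}

#' Fit a single-regime continuous-trait evolution model by ML
#'
#' Maximizes the multivariate-normal likelihood of tip values under one of:
#' * `BM` - Brownian motion (random walk; variance grows linearly with time);
#' * `OU` - Ornstein-Uhlenbeck, a pull of strength `alpha` toward an optimum
#'   (covariances `sigma2/(2 alpha) exp(-alpha d_ij)(1 - exp(-2 alpha t_a))`,
#'   the non-stationary form rooted at the optimum);
#' * `EB` - early burst / ACDC, rate `r(t) = r0 exp(a t)` with `a < 0`
#'   decelerating (branch segments rescaled by the integral of `exp(a t)`);
#' * `delta` - node depths raised to a power `delta` (late change for
#'   `delta > 1`);
#' * `WN` - white noise: tips i.i.d. normal, no covariance structure.
#'
#' The rate `sigma2` and the root state are always profiled in closed form
#' (GLS), leaving at most one shape parameter, which is found by a
#' deterministic grid scan plus bounded quasi-Newton refinement.
#'
#' Free-parameter counts for AICc are the conventional ones: BM and WN 2,
#' OU / EB / delta 3 (shape, rate, root).
#'
#' @param phy a `"phylo"` tree; OU and EB require an ultrametric
#'   (time-calibrated) tree.
#' @param trait named numeric tip values.
#' @param model one of `"BM"`, `"OU"`, `"EB"`, `"delta"`, `"WN"`.
#' @param bounds optional named list overriding the search box of the shape
#'   parameter, e.g. `list(a = c(-10, 5))` for an accelerating EB variant
#'   (default EB box is decelerating with upper bound -1e-6) or
#'   `list(delta = c(1e-3, 3))`.
#' @return a `"trait_model_fit"` list: `model`, `params` (named vector
#'   including `sigma2` and `z0`), `lnL`, `k`, `n`, `AICc`, `converged`.
#' @export
fit_continuous <- function(phy, trait, model = .MODELS_SINGLE, bounds = NULL) {
  model <- match.arg(model)
  x <- .match_trait(phy, trait)
  n <- length(x)
  C <- phylo_vcv(phy, regularize = TRUE)
  Tmax <- max(diag(C))
  if (model %in% c("OU", "EB") && !is_ultrametric(phy, tol = 1e-4)) {
    stop(model, " requires an ultrametric tree; calibrate it first ",
         "(see calibrate_tree())", call. = FALSE)
  }
  k <- switch(model, BM = 2L, WN = 2L, OU = 3L, EB = 3L, delta = 3L)
  if (n < k + 2L) stop("need n >= k + 2 species for a finite AICc", call. = FALSE)

  shape_name <- switch(model, OU = "alpha", EB = "a", delta = "delta",
                       BM = NULL, WN = NULL)
  converged <- TRUE
  if (is.null(shape_name)) {
    pr <- .gls_profile(.model_cor(model, NULL, C, Tmax), x)
    par <- NULL
  } else {
    box <- switch(model,
      # alpha searched on the log scale; box spans essentially-BM to
      # essentially-white-noise pulls for a tree of this height
      OU = log(c(1e-7, 1e3) / Tmax),
      # decelerating EB: rate shrinks by up to 10^5 over the tree depth
      EB = c(log(1e-5) / Tmax, -1e-6),
      delta = c(1e-3, 3)
    )
    if (!is.null(bounds) && !is.null(bounds[[shape_name]])) {
      b <- bounds[[shape_name]]
      box <- if (model == "OU") log(sort(b)) else sort(b)
    }
    obj <- function(p) {
      val <- if (model == "OU") exp(p) else p
      pr <- .gls_profile(.model_cor(model, setNames(val, shape_name), C, Tmax), x)
      if (!pr$ok) 1e10 else -pr$lnL
    }
    opt <- .optimize_1d(obj, box[1L], box[2L])
    converged <- opt$converged
    par <- setNames(if (model == "OU") exp(opt$par) else opt$par, shape_name)
    pr <- .gls_profile(.model_cor(model, par, C, Tmax), x)
  }
  params <- c(par, sigma2 = pr$sig2, z0 = unname(pr$beta[1L]))
  structure(list(model = model, params = params, lnL = pr$lnL, k = k, n = n,
                 AICc = aicc(pr$lnL, k, n), converged = converged),
            class = "trait_model_fit")
}

#' Log-likelihood of a trait under a model at given parameters
#'
#' Evaluates (without any fitting) the multivariate-normal log-likelihood of
#' the tip values with covariance `sigma2 * R(model)` and a constant mean
#' `z0`. Used for likelihood cross-checks against independent implementations.
#'
#' @inheritParams fit_continuous
#' @param params named list/vector with `sigma2`, `z0`, and the model's shape
#'   parameter (`alpha`, `a` or `delta`) where applicable.
#' @return the log-likelihood (numeric scalar).
#' @export
model_loglik <- function(phy, trait, model = .MODELS_SINGLE, params) {
  model <- match.arg(model)
  x <- .match_trait(phy, trait)
  n <- length(x)
  C <- phylo_vcv(phy, regularize = TRUE)
  R <- .model_cor(model, params, C, max(diag(C)))
  V <- params[["sigma2"]] * R
  ch <- chol(V)
  e <- backsolve(ch, x - params[["z0"]], transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(e^2)
}

#' Rank model fits by AICc and attach Akaike weights
#'
#' `w_i = exp(-D_i/2) / sum_j exp(-D_j/2)` with `D_i = AICc_i - min AICc`.
#'
#' @param fits a list of `"trait_model_fit"` objects on the same data.
#' @return a data.frame (one row per model, in the given order) with columns
#'   `model`, `lnL`, `k`, `AICc`, `dAICc`, `weight`.
#' @export
aicc_compare <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "trait_model_fit")))
  n <- unique(vapply(fits, `[[`, numeric(1L), "n"))
  if (length(n) != 1L) stop("fits are not on the same data (different n)", call. = FALSE)
  a <- vapply(fits, `[[`, numeric(1L), "AICc")
  d <- a - min(a)
  w <- exp(-d / 2)
  w <- w / sum(w)
  data.frame(model = vapply(fits, `[[`, character(1L), "model"),
             lnL = vapply(fits, `[[`, numeric(1L), "lnL"),
             k = vapply(fits, `[[`, integer(1L), "k"),
             AICc = a, dAICc = d, weight = w,
             stringsAsFactors = FALSE)
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat("Trait-evolution model fit:", x$model, "\n")
  cat("  lnL =", signif(x$lnL, 6), " k =", x$k, " n =", x$n,
      " AICc =", signif(x$AICc, 6), "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 4),
                         sep = " = ", collapse = ", "), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  invisible(x)
}

#' Simulate a continuous trait under an evolution model
#'
#' One multivariate-normal draw with covariance `sigma2 * R(model)` and
#' constant mean (`z0`, or `theta` for OU if given). `sigma2 = 0` returns the
#' root state at every tip.
#'
#' @inheritParams model_loglik
#' @param seed integer seed (optional); draws are bit-reproducible given it.
#' @return named numeric vector of tip values.
#' @export
simulate_trait <- function(phy, model = .MODELS_SINGLE, params, seed = NULL) {
  model <- match.arg(model)
  n <- ape::Ntip(phy)
  pget <- function(nm) if (nm %in% names(params)) params[[nm]] else NULL
  mu <- if (model == "OU" && !is.null(pget("theta"))) pget("theta") else pget("z0")
  if (is.null(mu)) stop("params must include z0 (or theta for OU)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s2 <- params[["sigma2"]]
  if (s2 == 0) return(setNames(rep(mu, n), phy$tip.label))
  C <- phylo_vcv(phy, regularize = TRUE)
  R <- .model_cor(model, params, C, max(diag(C)))
  x <- mu + drop(crossprod(chol(s2 * R), rnorm(n)))
  setNames(x, phy$tip.label)
}

# Simulate many BM draws at once (zero mean): n x S matrix. Shared by the
# disparity null and the calibration suites.
.simulate_bm_matrix <- function(C, sigma2, S) {
  L <- chol(sigma2 * C)
  crossprod(L, matrix(rnorm(nrow(C) * S), nrow(C), S))
}
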