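#' Lineage-through-time series
#'
#' Branching times (node ages, from the root toward the present) with the
#' number of lineages after each divergence; also reports the total tree
#' length (sum of all branch lengths), the sufficient statistic of the
#' pure-birth model.
#'
#' @param phy an ultrametric `"phylo"` tree with >= 2 tips.
#' @return a `"ltt_series"` list: `times` (ages, decreasing), `lineages`
#'   (counts, reaching `Ntip`), `tree_length`, `n`.
#' @export
ltt <- function(phy) {
  if (!is_ultrametric(phy, tol = 1e-4)) {
    stop("lineage-through-time requires an ultrametric tree", call. = FALSE)
  }
  n <- ape::Ntip(phy)
  if (n < 2L) stop("need >= 2 tips", call. = FALSE)
  ages <- ape::branching.times(phy)
  # children - 1 new lineages per node (handles polytomies)
  kids <- table(factor(phy$edge[, 1L], levels = as.integer(names(ages))))
  ord <- order(ages, decreasing = TRUE)
  times <- as.numeric(ages[ord])
  increments <- as.integer(kids[ord]) - 1L
  lineages <- 1L + cumsum(increments)
  structure(list(times = times, lineages = lineages,
                 tree_length = sum(phy$edge.length), n = n),
            class = "ltt_series")
}

#' Pure-birth (Yule) speciation-rate estimate
#'
#' Maximum-likelihood speciation rate conditioned on the reconstructed tree:
#' `lambda = (n - 2) / X` with `X` the total tree length (conditioning on the
#' two lineages present at the root), `se = lambda / sqrt(n - 2)` and
#' `lnL = (n - 2) log(lambda) - lambda X`. The unconditioned variant
#' `(n - 1) / X` is available via `conditioned = FALSE`.
#'
#' @param phy an ultrametric (or clock-scaled) `"phylo"` tree, n >= 3.
#' @param conditioned condition on the root's two initial lineages (default,
#'   matching standard pure-birth tooling).
#' @return a list with `lambda`, `se`, `lnL`, `n`, `tree_length`.
#' @export
yule_rate <- function(phy, conditioned = TRUE) {
  n <- ape::Ntip(phy)
  if (n < 3L) stop("need >= 3 tips", call. = FALSE)
  X <- sum(phy$edge.length)
  if (X <= 0) stop("total tree length is zero", call. = FALSE)
  m <- if (conditioned) n - 2L else n - 1L
  lambda <- m / X
  list(lambda = lambda,
       se = lambda / sqrt(m),
       lnL = m * log(lambda) - lambda * X,
       n = n, tree_length = X)
}

#' Pybus-Harvey gamma statistic (descriptive extra)
#'
#' Standardized measure of whether internal nodes are closer to the root
#' (gamma < 0, early-burst-like) or to the tips (gamma > 0) than a constant-
#' rate pure-birth process predicts. Provided as a descriptive complement to
#' the constant-rate fit; delegates to [ape::gammaStat()].
#'
#' @param phy an ultrametric `"phylo"` tree.
#' @return numeric gamma.
#' @export
ltt_gamma <- function(phy) {
  if (!is_ultrametric(phy, tol = 1e-4)) {
    stop("gamma requires an ultrametric tree", call. = FALSE)
  }
  ape::gammaStat(phy)
}

#' @export
print.ltt_series <- function(x, ...) {
  cat("Lineage-through-time series: n =", x$n,
      " total tree length =", signif(x$tree_length, 6), "\n")
  cat("  root age =", signif(max(x$times), 6),
      " final lineage count =", x$lineages[length(x$lineages)], "\n")
  invisible(x)
}
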