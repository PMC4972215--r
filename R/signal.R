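#' Minimum parsimony transition count for a discrete trait
#'
#' The minimum number of character-state changes on the tree that explain the
#' observed tip states, treating states as unordered categories with unit
#' change cost (Fitch parsimony; computed by Sankoff dynamic programming so
#' polytomies are handled natively). A constant character returns 0.
#'
#' @param phy a `"phylo"` tree.
#' @param states named vector of discrete states (names = tip labels), or a
#'   vector in tip order; coerced to factor.
#' @param cost optional square cost matrix (rows/cols = state levels); default
#'   unit cost off-diagonal. An ordered-character analysis can be run by
#'   passing `abs(outer(levels, levels, "-"))`.
#' @return integer: the minimum number of transitions.
#' @export
parsimony_transitions <- function(phy, states, cost = NULL) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- ape::Ntip(phy)
  if (ntip < 2L) stop("need >= 2 tips", call. = FALSE)
  if (!is.null(names(states))) {
    miss <- setdiff(phy$tip.label, names(states))
    if (length(miss)) stop("states missing for tips: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    states <- states[phy$tip.label]
  } else if (length(states) != ntip) {
    stop("unnamed states vector must have one value per tip", call. = FALSE)
  }
  f <- factor(states)
  S <- nlevels(f)
  if (S == 1L) return(0L)
  if (!is.null(cost)) {
    stopifnot(is.matrix(cost), nrow(cost) == S, ncol(cost) == S)
  }
  phy <- ape::reorder.phylo(phy, "postorder")
  nnode <- ntip + phy$Nnode
  acc <- matrix(0, nnode, S)
  tip_cost <- matrix(Inf, ntip, S)
  tip_cost[cbind(seq_len(ntip), as.integer(f))] <- 0
  acc[seq_len(ntip), ] <- tip_cost
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1L]
    child <- phy$edge[e, 2L]
    cc <- acc[child, ]
    contrib <- if (is.null(cost)) {
      pmin(cc, 1 + min(cc))          # unit cost: stay, or change from best
    } else {
      apply(cost + rep(cc, each = S), 1L, min)
    }
    acc[parent, ] <- acc[parent, ] + contrib
  }
  root <- phy$edge[nrow(phy$edge), 1L]
  as.integer(round(min(acc[root, ])))
}

#' Permutation test of phylogenetic signal in a discrete trait
#'
#' The observed minimum transition count is compared against a null built by
#' shuffling tip states uniformly (without replacement) `R` times: strong
#' phylogenetic signal shows as fewer observed transitions than the null
#' median. The one-sided p-value uses the +1 finite-sample correction and
#' counts ties toward significance:
#' `p = (1 + #\{null <= observed\}) / (R + 1)`.
#'
#' @inheritParams parsimony_transitions
#' @param R number of randomizations (>= 99; the analysis default is 1000).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return a `"signal_test"` list: `statistic`, `observed`, `null` (length
#'   `R`), `null_median`, `p_value`, `R`, `seed`.
#' @export
discrete_signal_test <- function(phy, states, R = 1000, seed = NULL) {
  stopifnot(R >= 99)
  if (!is.null(names(states))) states <- states[phy$tip.label]
  obs <- parsimony_transitions(phy, states)
  if (!is.null(seed)) set.seed(seed)
  shuffled <- unname(states)              # shuffle values across tip positions
  null <- vapply(seq_len(R), function(i) {
    parsimony_transitions(phy, sample(shuffled))
  }, integer(1L))
  structure(list(statistic = "parsimony transitions",
                 observed = obs,
                 null = null,
                 null_median = median(null),
                 p_value = (1 + sum(null <= obs)) / (R + 1),
                 R = R, seed = seed),
            class = "signal_test")
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' The ratio-of-ratios statistic: the observed ratio of the non-phylogenetic
#' mean squared error `MSE0` to the phylogenetically corrected `MSE`,
#' standardized by its Brownian-motion expectation on the same tree. With
#' `C` the phylogenetic VCV, `a = (1'C^-1 x)/(1'C^-1 1)` the phylogenetic
#' mean, `MSE0 = (x-a)'(x-a)/(n-1)`, `MSE = (x-a)'C^-1(x-a)/(n-1)` and
#' expected ratio `(tr(C) - n/(1'C^-1 1))/(n-1)`:
#' `K = (MSE0/MSE) / expected`. K = 1 matches Brownian motion; K < 1 means
#' relatives resemble each other less than BM predicts.
#'
#' @param phy a `"phylo"` tree (>= 3 tips).
#' @param trait named numeric vector of tip values; must not be constant.
#' @return numeric K > 0.
#' @export
blomberg_k <- function(phy, trait) {
  n <- ape::Ntip(phy)
  if (n < 3L) stop("Blomberg's K needs >= 3 tips", call. = FALSE)
  x <- .match_trait(phy, trait)
  if (var(x) == 0) stop("K is undefined for a constant trait", call. = FALSE)
  C <- phylo_vcv(phy, regularize = TRUE)
  Ci <- chol2inv(chol(C))
  one <- rep(1, n)
  denom1 <- sum(Ci)
  a <- sum(Ci %*% x) / denom1
  e <- x - a
  mse0 <- sum(e * e) / (n - 1)
  mse <- drop(crossprod(e, Ci %*% e)) / (n - 1)
  expected <- (sum(diag(C)) - n / denom1) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization test for Blomberg's K
#'
#' Significance of phylogenetic signal in a continuous trait via the variance
#' of standardized independent contrasts: signal makes contrasts small, so the
#' null (trait values shuffled across tips `R` times) is compared one-sided,
#' `p = (1 + #\{null variance <= observed variance\}) / (R + 1)`.
#'
#' @inheritParams blomberg_k
#' @param R number of randomizations (>= 99; analysis default 1000).
#' @param seed integer seed.
#' @return a `"signal_test"` list as in [discrete_signal_test()], with the
#'   additional element `K` (the observed Blomberg's K).
#' @export
k_significance <- function(phy, trait, R = 1000, seed = NULL) {
  stopifnot(R >= 99)
  x <- .match_trait(phy, trait)
  M <- contrast_matrix(phy)
  obs <- var(drop(M %*% x))
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(R, sample(x))
  null_contrasts <- M %*% perm            # (n-1) x R, one column per shuffle
  null <- apply(null_contrasts, 2L, var)
  structure(list(statistic = "contrast variance",
                 K = blomberg_k(phy, trait),
                 observed = obs,
                 null = null,
                 null_median = median(null),
                 p_value = (1 + sum(null <= obs)) / (R + 1),
                 R = R, seed = seed),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat("Phylogenetic signal test (", x$statistic, ")\n", sep = "")
  if (!is.null(x$K)) cat("  Blomberg's K:", signif(x$K, 4), "\n")
  cat("  observed:", signif(x$observed, 6),
      "  null median:", signif(x$null_median, 6), "\n")
  cat("  P =", signif(x$p_value, 4), " (R =", x$R, "randomizations)\n")
  invisible(x)
}

#' Tabulate a signal test as a one-row report
#' @param x a `"signal_test"` object.
#' @return a one-row data.frame (statistic, observed, null_median, R, seed, p).
#' @export
signal_report_row <- function(x) {
  data.frame(statistic = x$statistic,
             observed = x$observed,
             null_median = x$null_median,
             R = x$R,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             p_value = x$p_value,
             stringsAsFactors = FALSE)
}
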