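#' Paint a clade as a selective regime
#'
#' Assigns every branch of the tree to one of two regimes: the clade spanned
#' by the given tips (e.g. the whole-genome-duplication clade) versus the
#' background. The clade's stem branch is included by default.
#'
#' @param phy a `"phylo"` tree.
#' @param clade one tip label (a single-tip "clade") or two tip labels whose
#'   MRCA defines the clade.
#' @param label regime label for the clade.
#' @param background label for all other branches (and the root).
#' @param include_stem paint the clade's stem branch with the clade label.
#' @return a `"regime_painting"` list: `regimes` (factor, one level per edge
#'   row of `phy$edge`), `root_regime`, `labels`.
#' @export
paint_clade <- function(phy, clade, label = "clade", background = "background",
                        include_stem = TRUE) {
  stopifnot(inherits(phy, "phylo"), length(clade) %in% 1:2)
  bad <- setdiff(clade, phy$tip.label)
  if (length(bad)) stop("unknown tips: ", paste(bad, collapse = ", "), call. = FALSE)
  if (label == background) stop("regime labels must differ", call. = FALSE)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  mrca <- if (length(clade) == 2L) ape::getMRCA(phy, clade) else
    which(phy$tip.label == clade)
  if (mrca == root) stop("clade spans the whole tree: painting would have a single regime",
                         call. = FALSE)
  members <- .descendant_nodes(phy, mrca)
  in_clade <- phy$edge[, 2L] %in% members |
    (include_stem & phy$edge[, 2L] == mrca)
  regimes <- factor(ifelse(in_clade, label, background),
                    levels = c(background, label))
  structure(list(regimes = regimes, root_regime = background,
                 labels = levels(regimes), mrca = mrca),
            class = "regime_painting")
}

#' A trivial one-regime painting (degenerate case)
#' @param phy a `"phylo"` tree.
#' @param label the single regime label.
#' @return a `"regime_painting"` with every branch in one regime.
#' @export
paint_uniform <- function(phy, label = "all") {
  structure(list(regimes = factor(rep(label, nrow(phy$edge)), levels = label),
                 root_regime = label, labels = label, mrca = NA_integer_),
            class = "regime_painting")
}

# All nodes (internal + tips) strictly below `node`, plus the node's subtree
# edges' children; excludes the node itself.
.descendant_nodes <- function(phy, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    kids <- phy$edge[phy$edge[, 1L] == nd, 2L]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ape::Ntip(phy)])
  }
  out
}

# Tip sets (integer indices) below each edge's child node.
.edge_tip_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  lapply(seq_len(nrow(phy$edge)), function(e) sets[[phy$edge[e, 2L]]])
}

# Per-regime shared-path matrices: C = sum_r sigma2_r * C_r reconstructs the
# BMS covariance. Rows/cols in tip order.
.regime_path_matrices <- function(phy, painting) {
  ntip <- ape::Ntip(phy)
  sets <- .edge_tip_sets(phy)
  labs <- levels(painting$regimes)
  out <- lapply(labs, function(l) matrix(0, ntip, ntip,
                                         dimnames = list(phy$tip.label, phy$tip.label)))
  names(out) <- labs
  for (e in seq_len(nrow(phy$edge))) {
    r <- as.character(painting$regimes[e])
    tips <- sets[[e]]
    out[[r]][tips, tips] <- out[[r]][tips, tips] + phy$edge.length[e]
  }
  out
}

# OU optimum weight matrix W(alpha): tips x regimes, rows summing to 1.
# Each path segment [d0, d1] (depths from the root) in regime r contributes
# exp(-alpha (T_i - d1)) - exp(-alpha (T_i - d0)); the root's weight
# exp(-alpha T_i) goes to the root regime (stationary-root convention).
.oum_weights <- function(phy, painting, alpha) {
  ntip <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(ntip)]
  sets <- .edge_tip_sets(phy)
  labs <- levels(painting$regimes)
  W <- matrix(0, ntip, length(labs), dimnames = list(phy$tip.label, labs))
  for (e in seq_len(nrow(phy$edge))) {
    r <- as.character(painting$regimes[e])
    tips <- sets[[e]]
    d0 <- depth[phy$edge[e, 1L]]
    d1 <- depth[phy$edge[e, 2L]]
    W[tips, r] <- W[tips, r] +
      exp(-alpha * (tip_depth[tips] - d1)) - exp(-alpha * (tip_depth[tips] - d0))
  }
  W[, painting$root_regime] <- W[, painting$root_regime] + exp(-alpha * tip_depth)
  W
}

#' Fit a multi-regime trait-evolution model by ML
#'
#' The four-model set used to ask whether a painted clade (e.g. WGD yeasts)
#' evolved differently from the background:
#' * `BM1` - one Brownian rate (regimes ignored; identical to `BM`);
#' * `BMS` - Brownian motion with a separate rate `sigma2_r` per regime
#'   (each branch contributes its length times its regime's rate to the
#'   covariance);
#' * `OU1` - a single Ornstein-Uhlenbeck optimum (regimes ignored);
#' * `OUM` - shared `alpha` and `sigma2`, but a separate optimum `theta_r`
#'   per regime: the expected tip value is the exposure-weighted mix of the
#'   optima along its root-to-tip path (stationary root at the root regime's
#'   optimum).
#'
#' Free-parameter counts follow the convention of the standard multi-regime
#' tooling (and are the ones under which the AICc identity reproduces
#' published tables): BM1 2, OU1 3, BMS `1 + n_regimes`,
#' OUM `2 + n_regimes`.
#'
#' @param phy an ultrametric `"phylo"` tree.
#' @param trait named numeric tip values.
#' @param painting a `"regime_painting"` from [paint_clade()] (or
#'   [paint_uniform()] for the degenerate single-regime check).
#' @param model one of `"BM1"`, `"BMS"`, `"OU1"`, `"OUM"`.
#' @return a `"trait_model_fit"` (see [fit_continuous()]); for BMS the
#'   per-regime rates are named `sigma2_<label>`, for OUM the optima
#'   `theta_<label>`.
#' @export
fit_multiregime <- function(phy, trait, painting,
                            model = c("BM1", "BMS", "OU1", "OUM")) {
  model <- match.arg(model)
  stopifnot(inherits(painting, "regime_painting"))
  if (length(painting$regimes) != nrow(phy$edge)) {
    stop("painting does not match the tree (edge count differs)", call. = FALSE)
  }
  empty <- setdiff(levels(painting$regimes), unique(as.character(painting$regimes)))
  if (length(empty)) stop("regime with no branches: ", paste(empty, collapse = ", "),
                          call. = FALSE)
  if (model %in% c("OU1", "OUM") && !is_ultrametric(phy, tol = 1e-4)) {
    stop(model, " requires an ultrametric tree", call. = FALSE)
  }

  if (model == "BM1") {
    fit <- fit_continuous(phy, trait, "BM")
    fit$model <- "BM1"
    return(fit)
  }
  if (model == "OU1") {
    fit <- fit_continuous(phy, trait, "OU")
    fit$model <- "OU1"
    return(fit)
  }

  x <- .match_trait(phy, trait)
  n <- length(x)
  labs <- levels(painting$regimes)
  nreg <- length(labs)

  if (model == "BMS") {
    k <- 1L + nreg
    if (n < k + 2L) stop("need n >= k + 2 for a finite AICc", call. = FALSE)
    Cr <- .regime_path_matrices(phy, painting)
    if (nreg == 1L) {
      pr <- .gls_profile(Cr[[1L]], x)
      params <- c(setNames(pr$sig2, paste0("sigma2_", labs)), z0 = unname(pr$beta[1L]))
      return(structure(list(model = "BMS", params = params, lnL = pr$lnL,
                            k = k, n = n, AICc = aicc(pr$lnL, k, n),
                            converged = TRUE), class = "trait_model_fit"))
    }
    # profile the base rate; optimize log rate ratios of regimes 2..nreg
    objf <- function(logrho) {
      R <- Cr[[1L]]
      for (j in seq_len(nreg - 1L)) R <- R + exp(logrho[j]) * Cr[[j + 1L]]
      pr <- .gls_profile(R, x)
      if (!pr$ok) 1e10 else -pr$lnL
    }
    if (nreg == 2L) {
      opt <- .optimize_1d(function(p) objf(p), log(1e-4), log(1e4))
      logrho <- opt$par
      converged <- opt$converged
    } else {
      opt <- nlminb(rep(0, nreg - 1L), objf, lower = log(1e-6), upper = log(1e6),
                    control = list(rel.tol = 1e-8, iter.max = 500L))
      logrho <- opt$par
      converged <- opt$convergence == 0L
    }
    R <- Cr[[1L]]
    for (j in seq_len(nreg - 1L)) R <- R + exp(logrho[j]) * Cr[[j + 1L]]
    pr <- .gls_profile(R, x)
    rates <- pr$sig2 * c(1, exp(logrho))
    params <- c(setNames(rates, paste0("sigma2_", labs)), z0 = unname(pr$beta[1L]))
    return(structure(list(model = "BMS", params = params, lnL = pr$lnL,
                          k = k, n = n, AICc = aicc(pr$lnL, k, n),
                          converged = converged), class = "trait_model_fit"))
  }

  # OUM
  k <- 2L + nreg
  if (n < k + 2L) stop("need n >= k + 2 for a finite AICc", call. = FALSE)
  C <- phylo_vcv(phy, regularize = TRUE)
  Tmax <- max(diag(C))
  prof <- function(logalpha) {
    alpha <- exp(logalpha)
    R <- .model_cor("OU", c(alpha = alpha), C, Tmax)
    W <- .oum_weights(phy, painting, alpha)
    .gls_profile(R, x, X = W)
  }
  opt <- .optimize_1d(function(p) {
    pr <- prof(p)
    if (!pr$ok) 1e10 else -pr$lnL
  }, log(1e-7 / Tmax), log(1e3 / Tmax))
  alpha <- exp(opt$par)
  pr <- prof(opt$par)
  theta <- pr$beta
  params <- c(alpha = alpha, sigma2 = pr$sig2,
              setNames(theta, paste0("theta_", labs)))
  structure(list(model = "OUM", params = params, lnL = pr$lnL, k = k, n = n,
                 AICc = aicc(pr$lnL, k, n), converged = opt$converged),
            class = "trait_model_fit")
}
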