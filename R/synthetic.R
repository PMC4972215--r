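#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Standard constant-rate construction: starting from the two lineages at the
#' root, waiting times between speciations are exponential with rate
#' `k * lambda` (k = current lineage count) and the splitting lineage is
#' chosen uniformly; after the n-th tip appears, a final `Exp(n * lambda)`
#' interval separates the last split from the present.
#'
#' @param n number of tips (>= 2).
#' @param lambda speciation rate (> 0), per unit time.
#' @param seed integer seed; the same seed yields the identical Newick string.
#' @param tip_prefix prefix for tip labels (`sp001`, `sp002`, ...).
#' @return an ultrametric `"phylo"` tree with `n` tips.
#' @export
simulate_yule_tree <- function(n, lambda, seed = NULL, tip_prefix = "sp") {
  stopifnot(n >= 2, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  max_id <- 2L * n                       # a Yule run to n tips uses 2n - 2 lineages
  birth <- numeric(max_id)
  split_time <- rep(NA_real_, max_id)
  child1 <- integer(max_id)
  active <- c(1L, 2L)
  next_id <- 3L
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + rexp(1L, k * lambda)
    who <- active[sample.int(k, 1L)]
    split_time[who] <- t
    child1[who] <- next_id
    birth[next_id] <- t
    birth[next_id + 1L] <- t
    active <- c(active[active != who], next_id, next_id + 1L)
    next_id <- next_id + 2L
  }
  present <- t + rexp(1L, n * lambda)
  counter <- new.env()
  counter$i <- 0L
  fmt <- paste0(tip_prefix, "%0", max(3L, nchar(n)), "d")
  build <- function(id) {
    if (child1[id] == 0L) {
      counter$i <- counter$i + 1L
      sprintf("%s:%.12g", sprintf(fmt, counter$i), present - birth[id])
    } else {
      sprintf("(%s,%s):%.12g",
              build(child1[id]), build(child1[id] + 1L),
              split_time[id] - birth[id])
    }
  }
  text <- sprintf("(%s,%s);", build(1L), build(2L))
  parse_newick(text)
}

#' Rescale a tree to a given height
#' @param phy a `"phylo"` tree.
#' @param height target root-to-tip height (e.g. a root age in MYA).
#' @return the tree with all branch lengths multiplied by a constant.
#' @export
rescale_tree_height <- function(phy, height) {
  stopifnot(height > 0)
  phy$edge.length <- phy$edge.length * height / tree_height(phy)
  phy
}

#' Simulate a discrete character under an equal-rates Mk model
#'
#' Continuous-time Markov chain with `n_states` states (labelled
#' `0 ... n_states - 1`), equal exchange rates `rate` between every ordered
#' state pair, evolved along each branch with the exact matrix-exponential
#' transition probabilities of the equal-rates chain
#' (`P(stay) = 1/k + (k-1)/k exp(-k q t)`), not an event-driven
#' approximation. The root state is drawn uniformly unless fixed.
#'
#' @param phy a `"phylo"` tree.
#' @param n_states number of states (default 7, the sugar-count scale).
#' @param rate per-pair transition rate q (> 0); the total rate of leaving a
#'   state is `(n_states - 1) * q`.
#' @param seed integer seed.
#' @param root_state optional fixed root state in `0:(n_states-1)`.
#' @return named integer vector of tip states.
#' @export
simulate_mk_trait <- function(phy, n_states = 7L, rate, seed = NULL,
                              root_state = NULL) {
  stopifnot(rate > 0, n_states >= 2L)
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(n_states)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  state <- integer(ntip + phy$Nnode)
  state[root] <- if (is.null(root_state)) sample.int(k, 1L) - 1L else {
    stopifnot(root_state %in% 0:(k - 1L))
    as.integer(root_state)
  }
  phy_pre <- ape::reorder.phylo(phy, "cladewise")   # parents before children
  for (e in seq_len(nrow(phy_pre$edge))) {
    parent <- phy_pre$edge[e, 1L]
    child <- phy_pre$edge[e, 2L]
    t <- phy_pre$edge.length[e]
    p_stay <- 1 / k + (k - 1) / k * exp(-k * rate * t)
    if (runif(1L) < p_stay) {
      state[child] <- state[parent]
    } else {
      others <- setdiff(0:(k - 1L), state[parent])
      state[child] <- others[sample.int(k - 1L, 1L)]
    }
  }
  setNames(state[seq_len(ntip)], phy$tip.label)
}

# Deterministic fermentation codes that decode back to exactly `v` qualifying
# sugars: the coding exercises the full vocabulary (+, s, w, -, v, ±).
.codes_from_versatility <- function(v, i) {
  codes <- rep("-", length(SUGARS))
  if (v > 0) {
    qualifying <- rep("+", v)
    qualifying[seq_len(v) %% 3L == 0L] <- "s"
    qualifying[seq_len(v) %% 5L == 0L] <- "w"
    codes[seq_len(v)] <- qualifying
  }
  neg <- which(codes == "-")
  if (length(neg)) {
    flavor <- (i + neg) %% 7L
    codes[neg[flavor == 0L]] <- "v"
    codes[neg[flavor == 3L]] <- "±"
  }
  codes
}

#' Generate the study-scale synthetic yeast dataset
#'
#' A fixture with the statistical structure the analysis assumes, at the
#' study's own dimensions so every stage can be exercised without external
#' data: a 77-tip Yule tree rescaled to a 150-MYA root; log cell-size evolved
#' under an Ornstein-Uhlenbeck process around an optimum of `log(3.5)` um
#' with stationary SD 0.35 and a pull of `alpha = 0.02 / Myr`
#' (`alpha x tree height = 3`, i.e. moderate signal erosion); fermentation
#' versatility evolved under an equal-rates Mk chain on states 0-6 from a
#' root state of 2 at a rate giving a few dozen expected transitions; a
#' correlated trait pair where the response equals `beta x versatility` plus
#' Brownian error (tip SD 1) with `beta = 0.5`; and a "genetic-distance"
#' version of the tree (branchwise lognormal rate noise, CV ~ 0.3) with
#' three node calibrations (root plus two nested clades at their true ages)
#' for exercising the penalized-likelihood calibration. A regime painting
#' marks a WGD-like clade of roughly a third of the species.
#'
#' Everything is reproducible bit-for-bit from the seed, which the manifest
#' records along with every generating parameter.
#'
#' @param seed integer seed.
#' @param n number of tips (default 77).
#' @param root_age root age in MYA (default 150).
#' @return a `"synthetic_dataset"` list: `tree` (ultrametric, MYA),
#'   `gd_tree` (genetic-distance-like), `table` (CSV-ready trait table),
#'   `log_cell_size`, `versatility`, `corr_trait` (named vectors),
#'   `painting`, `wgd_tips`, `calibrations`, `manifest`.
#' @export
make_paperlike_dataset <- function(seed = 1L, n = 77L, root_age = 150) {
  manifest <- list(
    seed = as.integer(seed), n = as.integer(n), root_age = root_age,
    yule_lambda = 0.024,
    ou = list(alpha = 0.02, theta = log(3.5), stationary_sd = 0.35),
    mk = list(n_states = 7L, pair_rate = 0.002, root_state = 2L),
    corr = list(beta = 0.5, bm_tip_sd = 1),
    gd = list(rate_meanlog = log(0.01), rate_sdlog = 0.3),
    wgd_target_fraction = 1 / 3
  )
  set.seed(seed)
  tree <- simulate_yule_tree(n, manifest$yule_lambda)
  tree <- rescale_tree_height(tree, root_age)

  ou <- manifest$ou
  sigma2 <- 2 * ou$alpha * ou$stationary_sd^2
  log_cell_size <- simulate_trait(tree, "OU",
                                  params = c(alpha = ou$alpha, sigma2 = sigma2,
                                             theta = ou$theta))
  versatility <- simulate_mk_trait(tree, n_states = manifest$mk$n_states,
                                   rate = manifest$mk$pair_rate,
                                   root_state = manifest$mk$root_state)
  C <- phylo_vcv(tree)
  bm_err <- drop(crossprod(chol(C / root_age * manifest$corr$bm_tip_sd^2),
                           rnorm(n)))
  corr_trait <- setNames(manifest$corr$beta * as.numeric(versatility) + bm_err,
                         tree$tip.label)

  # genetic-distance tree: same topology, branch-specific lognormal rates
  gd_tree <- tree
  rates <- exp(rnorm(nrow(tree$edge), manifest$gd$rate_meanlog,
                     manifest$gd$rate_sdlog))
  gd_tree$edge.length <- tree$edge.length * rates

  # WGD-like regime: internal clade closest to the target fraction of tips
  pp <- ape::prop.part(tree)
  sizes <- lengths(pp)
  ok <- sizes < n                               # exclude the root clade
  target <- manifest$wgd_target_fraction * n
  node_idx <- which(ok)[which.min(abs(sizes[ok] - target))]
  clade_tips <- tree$tip.label[pp[[node_idx]]]
  wgd_tips <- clade_tips[c(1L, length(clade_tips))]
  painting <- paint_clade(tree, wgd_tips, label = "WGD", background = "nonWGD")

  # calibrations at the true ages: root, the WGD-like clade, one more node
  ages <- node_ages(tree)
  mrca_wgd <- ape::getMRCA(tree, wgd_tips)
  root_node <- ape::Ntip(tree) + 1L
  root_kids <- tree$edge[tree$edge[, 1L] == root_node, 2L]
  deep <- setdiff(root_kids[root_kids > ape::Ntip(tree)], mrca_wgd)
  cal <- data.frame(
    taxon_a = tree$tip.label[c(1L, which(tree$tip.label == wgd_tips[1L]))],
    taxon_b = tree$tip.label[c(n, which(tree$tip.label == wgd_tips[2L]))],
    age_mya = c(root_age, unname(ages[as.character(mrca_wgd)])),
    stringsAsFactors = FALSE
  )
  if (length(deep)) {
    dn <- deep[1L]
    dt <- tree$tip.label[pp[[dn - ape::Ntip(tree)]]]
    cal <- rbind(cal, data.frame(taxon_a = dt[1L], taxon_b = dt[length(dt)],
                                 age_mya = unname(ages[as.character(dn)])))
  }

  cell_size <- exp(log_cell_size)
  half <- pmin(0.5, 0.4 * cell_size)
  table <- data.frame(species = tree$tip.label,
                      cell_diameter_low_min = cell_size - half,
                      cell_diameter_low_max = cell_size + half,
                      stringsAsFactors = FALSE)
  code_mat <- t(vapply(seq_len(n),
                       function(i) .codes_from_versatility(versatility[i], i),
                       character(length(SUGARS))))
  colnames(code_mat) <- SUGARS
  table <- cbind(table, as.data.frame(code_mat, stringsAsFactors = FALSE))
  table$corr_trait <- as.numeric(corr_trait)

  structure(list(tree = tree, gd_tree = gd_tree, table = table,
                 log_cell_size = log_cell_size,
                 versatility = versatility,
                 corr_trait = corr_trait,
                 painting = painting, wgd_tips = wgd_tips,
                 calibrations = cal, manifest = manifest),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact formats the pipeline reads: `tree.nwk` and `gd_tree.nwk`
#' (Newick), `traits.csv` (trait-table schema), `calibrations.yaml` and
#' `manifest.yaml`.
#'
#' @param ds a `"synthetic_dataset"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(ds$tree), file.path(dir, "tree.nwk"))
  writeLines(write_newick(ds$gd_tree), file.path(dir, "gd_tree.nwk"))
  write.csv(ds$table, file.path(dir, "traits.csv"), row.names = FALSE)
  yaml::write_yaml(lapply(seq_len(nrow(ds$calibrations)), function(i) {
    as.list(ds$calibrations[i, ])
  }), file.path(dir, "calibrations.yaml"))
  yaml::write_yaml(ds$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic yeast-style comparative dataset\n")
  cat("  tips:", ape::Ntip(x$tree), " root age:", signif(tree_height(x$tree), 6),
      "MYA  seed:", x$manifest$seed, "\n")
  cat("  versatility range:", paste(range(x$versatility), collapse = "-"),
      " WGD-like clade:", sum(x$painting$regimes == "WGD"), "branches\n")
  invisible(x)
}
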