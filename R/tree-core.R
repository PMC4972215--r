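#' @importFrom stats median optimize nlminb runif rnorm rexp quantile var setNames
#'   pt coef lm complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

#' Parse a Newick string into a rooted tree
#'
#' Thin, validating front end over [ape::read.tree()]. Unlike plain
#' `read.tree()`, malformed bracketing is reported with the character offset of
#' the first unbalanced parenthesis, and missing branch lengths are an explicit
#' error rather than a silent `NULL` `edge.length`: every comparative method in
#' this package consumes branch lengths, so a tree without them is unusable.
#'
#' @param text a single Newick string (one tree, trailing semicolon).
#' @return an object of class `"phylo"`.
#' @seealso [write_newick()], [read_newick_file()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: no tree found in input", call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  n_edge <- nrow(phy$edge)
  if (n_edge > 0L) {
    if (is.null(phy$edge.length)) {
      stop("Newick tree has no branch lengths; they are required (no silent default)",
           call. = FALSE)
    }
    if (anyNA(phy$edge.length)) {
      stop("Newick tree has ", sum(is.na(phy$edge.length)),
           " edge(s) with missing branch length", call. = FALSE)
    }
    if (any(phy$edge.length < 0)) {
      stop("Newick tree has negative branch lengths", call. = FALSE)
    }
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  phy
}

# Bracket/quote scan with character offsets; ape's own errors do not report
# positions. Quoted labels ('...') may contain parentheses.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at character offset ", i, call. = FALSE)
      }
    }
  }
  if (in_quote) stop("Newick parse error: unterminated quoted label", call. = FALSE)
  if (depth > 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: missing terminating ';' at character offset ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with 10 significant digits so that
#' `parse_newick(write_newick(phy))` round-trips topology, labels and lengths.
#'
#' @param phy a `"phylo"` tree.
#' @return a Newick string.
#' @export
write_newick <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ape::write.tree(phy, digits = 10)
}

#' Read a Newick tree from a file
#' @param path path to a text file holding one Newick tree.
#' @return a `"phylo"` tree.
#' @export
read_newick_file <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Tree height (maximum root-to-tip distance)
#' @param phy a `"phylo"` tree with branch lengths.
#' @return numeric scalar.
#' @export
tree_height <- function(phy) {
  max(ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))])
}

#' Is the tree ultrametric (time-calibrated)?
#'
#' All root-to-tip path lengths equal within a relative tolerance.
#'
#' @param phy a `"phylo"` tree.
#' @param tol relative tolerance on root-to-tip path spread.
#' @return logical.
#' @export
is_ultrametric <- function(phy, tol = 1e-6) {
  d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  h <- max(d)
  if (h <= 0) return(FALSE)
  (max(d) - min(d)) / h < tol
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are expanded into zero-length bifurcations in a fixed
#' order (ape's sequential resolution, not the randomized one), so results are
#' reproducible and the phylogenetic VCV is unchanged. Contrasts-based
#' operations require a fully bifurcating tree; VCV-based ones do not.
#'
#' @param phy a `"phylo"` tree.
#' @return a binary `"phylo"` tree.
#' @export
resolve_polytomies <- function(phy) {
  if (ape::is.binary(phy)) return(phy)
  ape::multi2di(phy, random = FALSE)
}

#' Prune a tree to a set of taxa
#'
#' Keeps the induced subtree: degree-2 internal nodes are suppressed with
#' their branch lengths summed, so root-to-tip path lengths of kept tips are
#' preserved and the VCV of the pruned tree equals the corresponding submatrix
#' of the full VCV.
#'
#' @param phy a `"phylo"` tree.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `"phylo"` tree.
#' @export
prune_to_taxa <- function(phy, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown)) {
    stop("unknown species in 'keep': ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep", call. = FALSE)
  if (length(keep) == ape::Ntip(phy)) return(phy)
  ape::keep.tip(phy, keep)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. This matrix is the computational core
#' of Blomberg's K, the trait-model likelihoods and PGLS.
#'
#' Zero-length terminal branches would make the matrix singular for GLS, so
#' they can be perturbed by `1e-8 * tree height` (below any reporting
#' precision) when `regularize = TRUE`.
#'
#' @param phy a `"phylo"` tree with branch lengths.
#' @param regularize perturb zero-length terminal branches for invertibility.
#' @return a symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(phy, regularize = FALSE) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::Ntip(phy) < 2L) stop("need >= 2 tips for a VCV", call. = FALSE)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (regularize) {
    tip_edge <- phy$edge[, 2L] <= ape::Ntip(phy)
    zero_tip <- tip_edge & phy$edge.length <= 0
    if (any(zero_tip)) {
      phy$edge.length[zero_tip] <- 1e-8 * tree_height(phy)
    }
  }
  ape::vcv(phy)
}

#' Standardized phylogenetically independent contrasts
#'
#' Felsenstein's contrasts, each divided by its expected standard deviation
#' under Brownian motion. Polytomies are resolved first (deterministically,
#' with zero-length edges) unless `resolve = FALSE`, in which case a polytomy
#' is an error.
#'
#' @param phy a `"phylo"` tree.
#' @param trait named numeric vector (names = tip labels) or numeric vector in
#'   tip order.
#' @param resolve resolve polytomies automatically.
#' @return numeric vector of `Ntip - 1` standardized contrasts.
#' @export
independent_contrasts <- function(phy, trait, resolve = TRUE) {
  if (!ape::is.binary(phy)) {
    if (!resolve) {
      stop("tree contains polytomies; resolve them first (see resolve_polytomies())",
           call. = FALSE)
    }
    phy <- resolve_polytomies(phy)
  }
  x <- .match_trait(phy, trait)
  unname(ape::pic(x, phy))
}

# Linear map from tip values to standardized contrasts, as a (n-1) x n matrix.
# Contrasts are linear in the trait, so permutation nulls reduce to one
# matrix product. Rows follow ape::pic()'s ordering.
contrast_matrix <- function(phy) {
  phy <- resolve_polytomies(phy)
  n <- ape::Ntip(phy)
  M <- vapply(seq_len(n), function(i) {
    e <- numeric(n)
    e[i] <- 1
    names(e) <- phy$tip.label
    as.numeric(ape::pic(e, phy))
  }, numeric(n - 1L))
  colnames(M) <- phy$tip.label
  M
}

# Align a trait vector with the tree's tip order; names win over position.
.match_trait <- function(phy, trait) {
  n <- ape::Ntip(phy)
  if (!is.null(names(trait))) {
    miss <- setdiff(phy$tip.label, names(trait))
    if (length(miss)) {
      stop("trait missing for tips: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    trait <- trait[phy$tip.label]
  } else if (length(trait) != n) {
    stop("unnamed trait vector must have one value per tip", call. = FALSE)
  }
  if (anyNA(trait)) stop("trait contains NA", call. = FALSE)
  as.numeric(trait)
}

#' Ages of internal nodes (time before present)
#' @param phy an ultrametric `"phylo"` tree.
#' @return named numeric vector (names = internal node numbers).
#' @export
node_ages <- function(phy) {
  if (!is_ultrametric(phy, tol = 1e-4)) {
    stop("node ages require an ultrametric tree", call. = FALSE)
  }
  ape::branching.times(phy)
}

#' Read a node-calibration configuration
#'
#' A YAML (or JSON) list of `{taxon_a, taxon_b, age_mya}` entries; each entry
#' fixes the age of the MRCA of the two named tips.
#'
#' @param path path to the YAML/JSON file.
#' @return a data.frame with columns `taxon_a`, `taxon_b`, `age_mya`.
#' @export
read_calibrations <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_calibrations(cfg)
}

#' Coerce a list of calibration points to the canonical data.frame
#' @param x a list of lists with fields `taxon_a`, `taxon_b`, `age_mya`.
#' @return a data.frame with one row per calibration.
#' @export
as_calibrations <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("taxon_a", "taxon_b", "age_mya") %in% names(x)))
    df <- x[c("taxon_a", "taxon_b", "age_mya")]
  } else {
    df <- do.call(rbind, lapply(x, function(ci) {
      stopifnot(all(c("taxon_a", "taxon_b", "age_mya") %in% names(ci)))
      data.frame(taxon_a = as.character(ci$taxon_a),
                 taxon_b = as.character(ci$taxon_b),
                 age_mya = as.numeric(ci$age_mya),
                 stringsAsFactors = FALSE)
    }))
  }
  if (any(df$age_mya <= 0)) stop("calibration ages must be > 0", call. = FALSE)
  df
}

#' Penalized-likelihood time calibration
#'
#' Makes the tree ultrametric with node ages in MYA by maximizing a
#' Poisson-type rate log-likelihood (substitutions = rate x duration per
#' branch) minus `smoothing` times a roughness penalty on rate changes between
#' adjacent branches, with the stated node ages held fixed. This is the
#' rate-smoothing method of Sanderson (2002) as implemented in
#' [ape::chronopl()], which the package wraps; calibrated nodes are located as
#' MRCAs of tip pairs.
#'
#' @param phy a `"phylo"` tree with branch lengths (genetic distances).
#' @param calibrations a data.frame from [as_calibrations()] /
#'   [read_calibrations()].
#' @param smoothing non-negative smoothing parameter (default 1).
#' @param tol convergence tolerance passed to the optimizer.
#' @return an ultrametric `"phylo"` tree with branch lengths in MYA.
#' @export
calibrate_tree <- function(phy, calibrations, smoothing = 1, tol = 1e-8) {
  stopifnot(inherits(phy, "phylo"), smoothing >= 0)
  cal <- as_calibrations(calibrations)
  if (nrow(cal) < 1L) stop("need at least one calibration point", call. = FALSE)
  for (nm in c("taxon_a", "taxon_b")) {
    bad <- setdiff(cal[[nm]], phy$tip.label)
    if (length(bad)) stop("calibration taxa not in tree: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  node <- mapply(function(a, b) ape::getMRCA(phy, c(a, b)), cal$taxon_a, cal$taxon_b)
  if (anyDuplicated(node)) stop("calibrated nodes are not distinct", call. = FALSE)
  .check_calibration_order(phy, node, cal$age_mya)
  out <- ape::chronopl(phy, lambda = smoothing, age.min = cal$age_mya,
                       age.max = cal$age_mya, node = node,
                       tol = tol, eval.max = 1e4, iter.max = 5e3)
  attr(out, "ploglik") <- NULL
  attr(out, "rates") <- NULL
  attr(out, "message") <- NULL
  out
}

# A calibrated node must not be constrained older than a calibrated ancestor.
.check_calibration_order <- function(phy, node, age) {
  if (length(node) < 2L) return(invisible(TRUE))
  for (i in seq_along(node)) {
    for (j in seq_along(node)) {
      if (i == j) next
      # is node[i] an ancestor of node[j]?
      anc <- node[j]
      repeat {
        parent <- phy$edge[phy$edge[, 2L] == anc, 1L]
        if (length(parent) == 0L) break
        if (parent == node[i]) {
          if (age[i] < age[j]) {
            stop("infeasible calibration: ancestor node fixed at ", age[i],
                 " MYA is younger than descendant fixed at ", age[j], " MYA",
                 call. = FALSE)
          }
          break
        }
        anc <- parent
      }
    }
  }
  invisible(TRUE)
}
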