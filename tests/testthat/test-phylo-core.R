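test_that("Newick parsing handles minimal and degenerate trees", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(ape::Ntip(tr), 3L)
  root_children <- tr$edge[tr$edge[, 1] == 4L, 2]
  expect_length(root_children, 2L)

  # single-tip tree parses but is unusable for comparative analysis
  tr1 <- parse_newick("(A:1);")
  expect_equal(ape::Ntip(tr1), 1L)
  expect_error(phylo_vcv(tr1), ">= 2 tips")
})

test_that("malformed Newick is rejected with a character offset", {
  expect_error(parse_newick("((A:1,B:1):1,C:2;"), "unclosed '\\('")
  expect_error(parse_newick("(A:1,B:1)):1;"), "offset 10")
  expect_error(parse_newick("(A:1,B:1)"), "missing terminating ';'")
})

test_that("missing branch lengths are an explicit error", {
  expect_error(parse_newick("((A,B),C);"), "branch length")
  expect_error(parse_newick("((A:1,B):1,C:2);"), "branch length")
})

test_that("write/parse round-trips topology, labels and lengths", {
  for (seed in 1:5) {
    tr <- random_yule(12, seed)
    back <- parse_newick(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-9))
  }
})

test_that("VCV matches hand values and the path-intersection oracle", {
  V <- phylo_vcv(tree3())
  expect_equal(diag(V), c(A = 2, B = 2, C = 2))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)

  st <- star_tree(4, len = 3)
  expect_equal(unname(phylo_vcv(st)), 3 * diag(4))

  for (seed in c(11, 12)) {
    tr <- random_yule(10, seed)
    expect_equal(phylo_vcv(tr), brute_force_vcv(tr), tolerance = 1e-10)
  }
})

test_that("VCV is positive semi-definite on random trees", {
  for (seed in 1:5) {
    tr <- random_yule(15, seed)
    V <- phylo_vcv(tr)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * sum(diag(V)))
  }
})

test_that("independent contrasts: closed forms and GLS rate identity", {
  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(abs(independent_contrasts(tr2, c(A = 0, B = 2))), 2 / sqrt(2))

  tr <- random_yule(8, 3)
  const <- setNames(rep(1.7, 8), tr$tip.label)
  expect_equal(independent_contrasts(tr, const), rep(0, 7))

  # sum of squared standardized contrasts == (x - a)' C^-1 (x - a), exactly
  for (seed in 4:6) {
    tr <- random_yule(12, seed)
    x <- setNames(rnorm(12), tr$tip.label)
    u <- independent_contrasts(tr, x)
    C <- phylo_vcv(tr)
    Ci <- solve(C)
    a <- sum(Ci %*% x) / sum(Ci)
    q <- drop(t(x - a) %*% Ci %*% (x - a))
    expect_equal(sum(u^2) / (length(x) - 1), q / (length(x) - 1),
                 tolerance = 1e-8)
  }
})

test_that("contrasts require bifurcation unless resolution is allowed", {
  st <- star_tree(4)
  x <- setNames(rnorm(4), st$tip.label)
  expect_error(independent_contrasts(st, x, resolve = FALSE), "polytom")
  expect_length(independent_contrasts(st, x), 3L)
})

test_that("pruning preserves paths and commutes with the VCV", {
  tr <- tree3()
  pruned <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pruned$tip.label), c("A", "C"))
  expect_equal(unname(diag(phylo_vcv(pruned))), c(2, 2))

  expect_identical(prune_to_taxa(tr, c("A", "B", "C")), tr)
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  full <- random_yule(20, 9)
  keep <- sort(sample(full$tip.label, 8))
  sub <- prune_to_taxa(full, keep)
  expect_equal(phylo_vcv(sub)[keep, keep], phylo_vcv(full)[keep, keep],
               tolerance = 1e-12)
})

test_that("calibration fixes node ages and returns an ultrametric tree", {
  # clock-like tree, one root calibration: ages scale proportionally
  tr <- random_yule(10, 21)
  tr_gd <- tr
  tr_gd$edge.length <- tr$edge.length * 0.2   # uniform substitution rate
  # use two tips spanning the root so the MRCA calibration hits the root
  root <- ape::Ntip(tr) + 1L
  pp <- ape::prop.part(tr)
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  left_tips <- if (kids[1] <= ape::Ntip(tr)) tr$tip.label[kids[1]] else
    tr$tip.label[pp[[kids[1] - ape::Ntip(tr)]]][1]
  right_tips <- if (kids[2] <= ape::Ntip(tr)) tr$tip.label[kids[2]] else
    tr$tip.label[pp[[kids[2] - ape::Ntip(tr)]]][1]
  cal <- data.frame(taxon_a = left_tips, taxon_b = right_tips, age_mya = 10)
  out <- calibrate_tree(tr_gd, cal)
  expect_true(is_ultrametric(out, tol = 1e-6))
  expect_equal(tree_height(out), 10, tolerance = 1e-6)
  # clock input: calibrated ages proportional to original depths
  expect_equal(node_ages(out), node_ages(tr) * 10 / tree_height(tr),
               tolerance = 1e-3)

  # 3-tip toy: all root-to-tip paths equal the fixed root age
  toy <- parse_newick("((A:1,B:2):1,C:4);")
  out3 <- calibrate_tree(toy, data.frame(taxon_a = "A", taxon_b = "C",
                                         age_mya = 10))
  d <- ape::node.depth.edgelength(out3)[1:3]
  expect_equal(unname(d), rep(10, 3), tolerance = 1e-6)
})

test_that("infeasible calibration orderings are rejected before optimization", {
  tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  cal <- data.frame(taxon_a = c("A", "A"), taxon_b = c("D", "B"),
                    age_mya = c(50, 80))   # child clade older than root
  expect_error(calibrate_tree(tr, cal), "infeasible")
})

test_that("calibration config round-trips through YAML", {
  cal <- data.frame(taxon_a = c("A", "B"), taxon_b = c("C", "D"),
                    age_mya = c(150, 100), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(nrow(cal)), function(i) as.list(cal[i, ])), path)
  expect_equal(read_calibrations(path), cal)
})
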