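test_that("RF distance counts symmetric split differences", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,c:1,(d:1,e:1):1);")
  expect_identical(rf_distance(t1, t1), 0L)
  # one NNI away: swap b and c across the ab-edge; the de split survives
  t2 <- ape::read.tree(text = "((a:1,c:1):1,b:1,(d:1,e:1):1);")
  expect_identical(rf_distance(t1, t2), 2L)
  expect_identical(rf_distance(t2, t1), rf_distance(t1, t2))
  # re-rooting never changes the bipartition set
  expect_identical(rf_distance(t1, ape::root(t1, "e", resolve.root = TRUE)), 0L)

  t3 <- ape::read.tree(text = "((a:1,b:1):1,c:1,(x:1,e:1):1);")
  expect_error(rf_distance(t1, t3), "symmetric difference.*d, x")
})

test_that("branch score reflects length differences on shared topology", {
  t1 <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.4,d:0.5):0.2);")
  t2 <- ape::read.tree(text = "((a:0.2,b:0.3):0.3,(c:0.4,d:0.5):0.2);")
  expect_identical(branch_score(t1, t1), 0)
  # only one internal branch differs, 0.1 vs 0.3; after unrooting the two
  # root-adjacent branches merge into one internal branch of 0.3 vs 0.5
  expect_equal(branch_score(t1, t2), 0.2, tolerance = 1e-12)

  nolen <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(branch_score(t1, nolen), "branch lengths")
})

test_that("standardized branch score removes uniform rate scaling", {
  t1 <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.4,d:0.5):0.2);")
  t3 <- t1; t3$edge.length <- t3$edge.length * 3
  expect_equal(standardized_branch_score(t1, t3), 0, tolerance = 1e-12)
  expect_identical(standardized_branch_score(t1, t1), 0)
  # two-step oracle: equals plain branch score of the unit-length rescalings
  t2 <- ape::read.tree(text = "((a:0.9,c:0.1):0.4,(b:0.2,d:0.8):0.3);")
  u <- function(tr) { tr$edge.length <- tr$edge.length / sum(tr$edge.length); tr }
  expect_equal(standardized_branch_score(t1, t2), branch_score(u(t1), u(t2)),
               tolerance = 1e-12)
  zero <- t1; zero$edge.length[] <- 0
  expect_error(standardized_branch_score(t1, zero), "positive total length")
})

test_that("all three metrics agree with the brute-force split enumerator", {
  set.seed(101)
  n_pairs <- 220
  for (i in seq_len(n_pairs)) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n, tip.label = sprintf("t%d", 1:n))
    t2 <- if (i %% 4 == 0) t1 else ape::rtree(n, tip.label = sprintf("t%d", 1:n))
    expect_identical(rf_distance(t1, t2), oracle_rf(t1, t2))
    expect_equal(branch_score(t1, t2), oracle_branch_score(t1, t2),
                 tolerance = 1e-9)
    expect_equal(standardized_branch_score(t1, t2),
                 oracle_standardized_bs(t1, t2), tolerance = 1e-9)
  }
})

test_that("metrics agree with phangorn as an independent implementation", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n, tip.label = sprintf("t%d", 1:n))
    t2 <- ape::rtree(n, tip.label = sprintf("t%d", 1:n))
    expect_identical(rf_distance(t1, t2),
                     as.integer(phangorn::RF.dist(t1, t2)))
    expect_equal(branch_score(t1, t2), as.numeric(phangorn::KF.dist(t1, t2)),
                 tolerance = 1e-9)
  }
})

test_that("metric axioms and the RF ceiling hold", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n); t2 <- ape::rtree(n); t3 <- ape::rtree(n)
    t2$tip.label <- t1$tip.label; t3$tip.label <- t1$tip.label
    expect_gte(rf_distance(t1, t2), 0L)
    expect_lte(rf_distance(t1, t2), 2L * (n - 3L))
    expect_identical(rf_distance(t1, t2), rf_distance(t2, t1))
    expect_identical(rf_distance(t1, t1), 0L)
    bs <- function(a, b) branch_score(a, b)
    expect_lte(bs(t1, t3), bs(t1, t2) + bs(t2, t3) + 1e-9)  # triangle
  }
  # two 8-taxon trees with disjoint internal structure attain 2(n-3) = 10
  cat1 <- ape::read.tree(
    text = "(((((((t1,t2),t3),t4),t5),t6),t7),t8);")
  cat2 <- ape::read.tree(
    text = "(((((((t1,t8),t6),t2),t7),t3),t5),t4);")
  expect_identical(rf_distance(cat1, cat2), 10L)
})

test_that("pairwise matrices are symmetric, zero-diagonal, and complete", {
  ts <- synth_trees(6, 3, divergence = 0, seed = 1)
  m0 <- pairwise_matrix(ts, "rf")
  expect_true(all(m0 == 0))

  ts <- synth_trees(7, 6, divergence = 0.8, seed = 2)
  m <- pairwise_matrix(ts, "branch_score")
  expect_identical(dim(m), c(6L, 6L))
  expect_identical(unname(diag(m)), rep(0, 6))
  expect_equal(unclass(m), t(unclass(m)))
  expect_identical(sum(upper.tri(m)), 15L)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(m[i, j], branch_score(ts[[i]], ts[[j]]), tolerance = 1e-12)

  f <- tempfile(fileext = ".tsv")
  write_distance_matrix(m, f)
  back <- as.matrix(utils::read.delim(f, row.names = 1, check.names = FALSE))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rooting on a metadata outgroup preserves splits and annotates", {
  p <- toy_aligned_project(list(
    g = c(out = "GGGGGGGG", a = "ACGTACGT", b = "ACGTACGA", c = "ACCTACGA")))
  p <- edit_metadata(p, "clade",
                     function(rec) if (rec$otu == "out") "outgroup" else "ingroup")
  p <- nj_tree(p, names(p$alignments)[1])
  tid <- names(p$trees)[1]
  p2 <- root_and_annotate(p, tid, where = list(clade = "outgroup"),
                          fields = c("organism", "clade"))
  rooted <- op_result(p2)
  expect_true(ape::is.rooted(rooted$phylo))
  # single-leaf outgroup sits as sister to everything else
  out_label <- names(which(vapply(rooted$phylo$tip.label, function(l)
    p$records[[l]]$otu == "out", logical(1))))
  root_children <- rooted$phylo$edge[
    rooted$phylo$edge[, 1] == length(rooted$phylo$tip.label) + 1L, 2]
  expect_true(match(out_label, rooted$phylo$tip.label) %in% root_children)
  # rooting does not change the bipartition set
  expect_identical(rf_distance(rooted, p$trees[[tid]]), 0L)
  # annotations carry the requested fields
  expect_identical(rooted$annotations[[out_label]]$clade, "outgroup")
  expect_true(all(vapply(rooted$annotations, function(a)
    a$clade %in% c("ingroup", "outgroup"), logical(1))))

  expect_error(root_and_annotate(p, tid, where = list(clade = "nope")),
               "matches no leaf")
  # a non-monophyletic selection errors with the leaves named
  p3 <- edit_metadata(p, "side",
                      function(rec) if (rec$otu %in% c("out", "b")) "mix" else "rest")
  tr <- p3$trees[[tid]]$phylo
  labs <- tr$tip.label[vapply(tr$tip.label, function(l)
    p3$records[[l]]$otu %in% c("out", "b"), logical(1))]
  if (!ape::is.monophyletic(tr, labs))
    expect_error(root_and_annotate(p3, tid, where = list(side = "mix")),
                 "not monophyletic")
})
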