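ragged_project <- function(n_loci = 3) {
  loci <- lapply(sprintf("g%d", seq_len(n_loci)), locus)
  p <- create_project(loci)
  for (i in seq_len(n_loci))
    for (otu in c("x", "y", "z"))
      p <- phylocrate:::new_record(p, sprintf("g%d", i),
                                   strrep("ACGT", 3 + (otu == "x")),
                                   otu = otu, source = "s")
  p
}

test_that("align is a batch over unaligned selected loci only", {
  p <- toy_aligned_project(list(done = c(x = "ACGT", y = "ACGA")))
  p$loci <- c(p$loci, stats::setNames(list(locus("g1"), locus("g2")),
                                      c("g1", "g2")))
  p$selection <- names(p$loci)
  for (ln in c("g1", "g2"))
    for (otu in c("x", "y"))
      p <- phylocrate:::new_record(p, ln, "AACCGGTT", otu = otu, source = "s")
  p <- align_loci(p)
  expect_length(op_result(p), 2L)  # 'done' was already aligned
  # batch closure: nothing unaligned remains
  expect_warning(p2 <- align_loci(p), "nothing to do")
  expect_length(op_result(p2), 0L)

  # scope limited to one locus
  q <- create_project(list(locus("a"), locus("b")))
  for (ln in c("a", "b"))
    q <- phylocrate:::new_record(q, ln, "ACGT", otu = "x", source = "s")
  q <- align_loci(q, stage_conf("align", "asis", scope = "a"))
  expect_length(op_result(q), 1L)
  expect_identical(q$alignments[[1]]$locus_name, "a")
})

test_that("asis refuses ragged input; pad equalizes it", {
  p <- ragged_project(1)
  expect_error(align_loci(p), "unequal")
  p <- align_loci(p, stage_conf("align", "pad"))
  aln <- p$alignments[[1]]
  expect_identical(length(unique(nchar(aln$rows))), 1L)
  # de-gapping still reproduces every record
  for (rid in names(aln$rows))
    expect_identical(gsub("-", "", aln$rows[[rid]]), p$records[[rid]]$sequence)
})

test_that("gap-threshold trimming keeps columns by non-gap fraction", {
  # 4 rows; column gap counts 0,1,2,3 -> non-gap fractions 1, .75, .5, .25
  rows <- c(a = "AAAA", b = "AAA-", c = "AA--", d = "A---")
  aln <- phylocrate:::new_alignment("t@1", "t", rows)
  t0 <- phylocrate:::trim_alignment(aln, 0)
  expect_identical(t0$rows, aln$rows)                     # identity
  t1 <- phylocrate:::trim_alignment(aln, 1)
  expect_identical(t1$length, 1L)                         # gap-free only
  t5 <- phylocrate:::trim_alignment(aln, 0.5)
  expect_identical(t5$length, 3L)                         # <=2 gaps kept
  expect_identical(t5$kept_columns, 1:3)                  # order preserved
  expect_error(phylocrate:::trim_alignment(aln, 0.5)$rows, NA)
  # zero columns left -> actionable error
  allgap <- phylocrate:::new_alignment("u@1", "u", c(a = "A---", b = "-A--",
                                                     c = "--A-", d = "---A"))
  expect_error(phylocrate:::trim_alignment(allgap, 0.9), "lower the threshold")
})

test_that("kept-column sets are monotone in the threshold (fuzzed)", {
  set.seed(11)
  for (i in 1:30) {
    nr <- sample(3:8, 1); nc <- sample(5:30, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-"), nr * nc, replace = TRUE,
                       prob = c(.2, .2, .2, .2, .2)), nr, nc)
    rows <- stats::setNames(apply(m, 1, paste, collapse = ""),
                            sprintf("r%d", 1:nr))
    aln <- phylocrate:::new_alignment("f@1", "f", rows)
    gts <- sort(stats::runif(3))
    kept <- lapply(gts, function(gt)
      tryCatch(phylocrate:::trim_alignment(aln, gt)$kept_columns,
               error = function(e) integer()))
    expect_true(all(kept[[3]] %in% kept[[2]]))
    expect_true(all(kept[[2]] %in% kept[[1]]))
  }
})

test_that("trim batch registers per-locus trimmed alignments with provenance", {
  p <- toy_aligned_project(list(
    a = c(x = "AC-T", y = "ACGT", z = "AC-T"),
    b = c(x = "GG-G", y = "GGGG", z = "G--G")))
  p <- trim_loci(p, gt = 0.9)
  expect_length(p$trimmed, 2L)
  expect_length(op_result(p), 2L)
  entry <- p$ledger[[length(p$ledger)]]
  expect_identical(entry$operation, "trim")
  expect_setequal(entry$output_ids, names(p$trimmed))
  expect_project_closed(p)
})

test_that("neighbor joining recovers additive quartets and handles edge cases", {
  # quartet: A,B differ at 2 sites; C,D differ at 2; across-pairs differ a lot
  base <- strrep("ACGT", 25)
  flip <- function(s, at, to) { substr(s, at, at) <- to; s }
  A <- base
  B <- flip(flip(base, 1, "T"), 5, "T")
  C <- flip(flip(flip(base, 10, "C"), 20, "C"),
            30, "C")
  C <- flip(flip(flip(C, 40, "C"), 50, "C"), 60, "C")
  D <- flip(C, 2, "G"); C <- flip(C, 3, "T")
  p <- toy_aligned_project(list(q = c(A = A, B = B, C = C, D = D)))
  p <- nj_tree(p, names(p$alignments)[1], model = "p")
  tr <- op_result(p)$phylo
  tr$tip.label <- vapply(tr$tip.label, function(l)
    p$records[[l]]$otu, character(1))
  expected <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(rf_distance(tr, expected), 0L)

  # 3 taxa: the unique unrooted topology
  p3 <- toy_aligned_project(list(t = c(a = "ACGTACGT", b = "ACGTACGA",
                                       c = "ACCTACGA")))
  p3 <- nj_tree(p3, names(p3$alignments)[1])
  expect_identical(length(op_result(p3)$phylo$tip.label), 3L)

  # identical sequences: zero distances, deterministic resolution
  pi1 <- toy_aligned_project(list(t = c(a = "ACGT", b = "ACGT", c = "ACGT",
                                        d = "ACGT")))
  pi1 <- nj_tree(pi1, names(pi1$alignments)[1])
  expect_identical(tree_length(op_result(pi1)), 0)
  expect_true(all(op_result(pi1)$phylo$edge.length >= 0))

  # JC69 divergence ceiling names the offending pair
  pj <- toy_aligned_project(list(t = c(a = "AAAAAAAA", b = "CCCCCCCC",
                                       c = "AAAACCCC")))
  expect_error(nj_tree(pj, names(pj$alignments)[1], model = "JC69"),
               "JC69.*undefined")
})

test_that("JC69 transforms p-distance as -3/4 log(1 - 4p/3)", {
  rows <- c(a = strrep("A", 100), b = paste0(strrep("A", 90), strrep("C", 10)))
  d <- phylocrate:::seq_distance_matrix(rows, "JC69")
  expect_equal(d["a", "b"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  dp <- phylocrate:::seq_distance_matrix(rows, "p")
  expect_identical(dp["a", "b"], 0.1)
})

test_that("a mock external adapter runs, parses back, and records versions", {
  p <- create_project(list(locus("g1"), locus("g2")))
  for (ln in c("g1", "g2"))
    for (otu in c("x", "y"))
      p <- phylocrate:::new_record(p, ln, "ACGTACGT", otu = otu, source = "s")
  p <- register_adapter(p, "mockalign", "align",
                        command = "cp {in} {out}",
                        version_probe = "echo mock-aligner 9.9")
  p <- run_external(p, stage_conf("align", "mockalign"))
  expect_length(op_result(p), 2L)
  entry <- p$ledger[[length(p$ledger)]]
  expect_match(entry$tool, "mock-aligner 9.9")
  expect_project_closed(p)

  # a failing probe errors before any mutation
  q <- create_project(list(locus("g")))
  q <- phylocrate:::new_record(q, "g", "ACGT", otu = "x", source = "s")
  q <- register_adapter(q, "ghost", "align",
                        command = "ghost_tool {in} {out}",
                        version_probe = "ghost_tool --version 2>/dev/null")
  n_aln <- length(q$alignments)
  expect_error(run_external(q, stage_conf("align", "ghost")), "probe")
  expect_length(q$alignments, n_aln)

  # nonzero exit carries captured stderr
  r <- create_project(list(locus("g")))
  r <- phylocrate:::new_record(r, "g", "ACGT", otu = "x", source = "s")
  r <- phylocrate:::new_record(r, "g", "ACGA", otu = "y", source = "s")
  r <- register_adapter(r, "dying", "align",
                        command = "sh -c 'echo boom >&2; exit 3'",
                        version_probe = "echo dying 0.1")
  expect_error(run_external(r, stage_conf("align", "dying")), "boom|status 3")

  expect_error(run_external(p, stage_conf("tree", "unregistered")),
               "no adapter")
})

test_that("a tree adapter's Newick output is parsed with support values", {
  p <- toy_aligned_project(list(g = c(a = "ACGT", b = "ACGA", c = "ACCA",
                                      d = "GCCA")))
  nwk <- "((a:1,b:1)95:0.5,(c:1,d:1)80:0.5);"
  p <- register_adapter(p, "mocktree", "tree",
                        command = paste0("echo '", nwk, "' > {out}"),
                        version_probe = "echo mocktree 1.0")
  aid <- names(p$alignments)[1]
  # tip labels here are plain otus, not record ids; adapter trees keep them
  p$alignments[[aid]]$rows <- stats::setNames(p$alignments[[aid]]$rows,
                                              c("a", "b", "c", "d"))
  p$records <- stats::setNames(p$records, c("a", "b", "c", "d"))
  for (nm in names(p$records)) p$records[[nm]]$record_id <- nm
  p <- run_external(p, stage_conf("tree", "mocktree", scope = aid))
  tr <- p$trees[[op_result(p)[1]]]
  expect_setequal(tr$phylo$tip.label, c("a", "b", "c", "d"))
  expect_true("95" %in% tr$phylo$node.label)
})

test_that("MAFFT runs through the generic adapter contract", {
  p <- create_project(list(locus("g")))
  seqs <- c(x = "ACGTACGTACGTGGTTACGT", y = "ACGTACGTGGTTACGT",
            z = "ACGTACGTACGTGGTTACGA", w = "ACGTACGCAGGTTACGT")
  for (otu in names(seqs))
    p <- phylocrate:::new_record(p, "g", seqs[[otu]], otu = otu, source = "s")
  p <- register_adapter(p, "mafft", "align",
                        command = "mafft --retree 1 {params} {in} > {out}",
                        version_probe = "mafft --version 2>&1")
  p <- run_external(p, stage_conf("align", "mafft"))
  expect_length(op_result(p), 1L)
  aln <- p$alignments[[op_result(p)[1]]]
  expect_length(unique(nchar(aln$rows)), 1L)
  expect_match(p$ledger[[length(p$ledger)]]$tool, "mafft v")
})
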