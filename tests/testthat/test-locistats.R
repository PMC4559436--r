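# Column builders: an alignment whose every column is the given string.
col_aln <- function(cols, otus = NULL) {
  n <- nchar(cols[1])
  rows <- vapply(seq_len(n), function(i)
    paste(vapply(cols, substr, character(1), i, i), collapse = ""),
    character(1))
  names(rows) <- otus %||% sprintf("sp%02d", seq_len(n))
  phylocrate:::new_alignment("toy@0001_align", "toy", rows)
}

test_that("column entropy matches hand-evaluated values and edge rules", {
  expect_identical(column_entropy("AAAA"), 0)
  expect_identical(column_entropy("ACGT"), 2)
  # p = {A: 3/4, G: 1/4}, gap ignored
  expect_equal(column_entropy("AAAG-"), -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(column_entropy("AAAG-"), 0.811278, tolerance = 1e-6)
  # all-gap and ambiguity-only columns are missing, not zero
  expect_true(is.na(column_entropy("----")))
  expect_true(is.na(column_entropy("NN??")))
  # ambiguity codes are excluded from the frequencies
  expect_identical(column_entropy("AANN"), 0)
})

test_that("entropy is bounded and invariant under row permutation/duplication", {
  set.seed(42)
  for (i in 1:200) {
    col <- paste(sample(c("A", "C", "G", "T", "-", "N"), sample(2:30, 1),
                        replace = TRUE), collapse = "")
    se <- column_entropy(col)
    if (!is.na(se)) {
      expect_gte(se, 0)
      expect_lte(se, 2)
    }
    chars <- strsplit(col, "")[[1]]
    expect_identical(column_entropy(paste(sample(chars), collapse = "")), se)
    expect_identical(column_entropy(strrep(col, 2)), se)
  }
})

test_that("compute_locus_stats fills all five families with correct shapes", {
  # 4 identical rows: zero entropy, full conservation, gap-free
  aln <- phylocrate:::new_alignment("a@1", "a",
    c(w = "ACGTACGT", x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT"))
  st <- compute_locus_stats(aln)
  expect_identical(st$column_entropy, rep(0, 8))
  expect_identical(st$column_conservation, rep(1, 8))
  expect_identical(st$column_gap_score, rep(1, 8))
  expect_identical(st$record_lengths, rep(8L, 4))

  # an all-gap column is missing in entropy and has gap score 0
  aln2 <- phylocrate:::new_alignment("b@1", "b",
    c(x = "A-GT", y = "A-GA", z = "A-GT"))
  st2 <- compute_locus_stats(aln2)
  expect_true(is.na(st2$column_entropy[2]))
  expect_identical(st2$column_gap_score[2], 0)
  expect_identical(st2$n_columns, 4L)
  expect_length(st2$column_entropy, 4L)
  expect_length(st2$record_gc, 3L)
})

test_that("summaries match an independent percentile computation", {
  set.seed(7)
  aln <- col_aln(replicate(10, paste(sample(c("A", "C", "G", "T"), 5,
                                            replace = TRUE), collapse = "")))
  st <- compute_locus_stats(aln)
  # brute-force linear-interpolation percentile: h = (n-1)q + 1
  brute_q <- function(x, q) {
    x <- sort(x[!is.na(x)])
    h <- (length(x) - 1) * q + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  ent <- st$column_entropy
  expect_equal(st$summaries$entropy$p25, brute_q(ent, 0.25), tolerance = 1e-12)
  expect_equal(st$summaries$entropy$median, brute_q(ent, 0.5), tolerance = 1e-12)
  expect_equal(st$summaries$entropy$p75, brute_q(ent, 0.75), tolerance = 1e-12)
  expect_lte(st$summaries$entropy$p25, st$summaries$entropy$median)
  expect_lte(st$summaries$entropy$median, st$summaries$entropy$p75)

  # the documented interpolation oracle
  expect_equal(unlist(phylocrate:::five_number(1:100)[c("p25", "median", "p75")]),
               c(p25 = 25.75, median = 50.5, p75 = 75.25))
  # null box -> null whiskers
  fn <- phylocrate:::five_number(rep(3.3, 9))
  expect_identical(fn$whisker_low, 3.3)
  expect_identical(fn$whisker_high, 3.3)
})

test_that("boxplot data is permutation-invariant over columns", {
  cols <- c("AAAA", "ACGT", "AACC", "AAAG", "CCGG")
  a <- col_aln(cols)
  b <- col_aln(rev(cols))
  sa <- compute_locus_stats(a)$summaries$entropy
  sb <- compute_locus_stats(b)$summaries$entropy
  expect_equal(sa, sb)
})

# three hand-shaped loci with known median entropies 0 / 1 / 2 bits
shaped_project <- function() {
  mk <- function(col) vapply(1:4, function(i)
    strrep(substr(col, i, i), 6), character(1))
  toy_aligned_project(list(
    lo  = stats::setNames(mk("AAAA"), sprintf("sp%d", 1:4)),   # entropy 0
    mid = stats::setNames(mk("AACC"), sprintf("sp%d", 1:4)),   # entropy 1
    hi  = stats::setNames(mk("ACGT"), sprintf("sp%d", 1:4))))  # entropy 2
}

test_that("sort_loci orders by summary with lexicographic tie-break", {
  p <- compute_stats(shaped_project())
  expect_identical(sort_loci(p), c("hi", "mid", "lo"))
  expect_identical(sort_loci(p, order = "asc"), rev(sort_loci(p)))
  # ties (gap_score all 1) fall back to locus name
  expect_identical(sort_loci(p, "gap_score"), c("hi", "lo", "mid"))

  p_missing <- shaped_project()
  expect_error(sort_loci(p_missing), "compute_stats")
})

test_that("slice selects by closed interval and rejects empty ranges", {
  p <- compute_stats(shaped_project())
  p1 <- slice_loci(p, min = 0.4, max = 1.9)
  expect_identical(op_result(p1)$locus_names, "mid")
  p2 <- slice_loci(p, min = -Inf, max = Inf)
  expect_length(op_result(p2)$locus_names, 3L)
  expect_error(slice_loci(p, min = 2.5, max = 3), "no locus")
  # slice and its complement partition the loci disjointly
  cut <- 0.5
  lo <- op_result(slice_loci(p, min = -Inf, max = cut))$locus_names
  hi <- op_result(slice_loci(p, min = cut + 1e-9, max = Inf))$locus_names
  expect_length(intersect(lo, hi), 0L)
  expect_setequal(c(lo, hi), p$selection)
})

test_that("slide window offsets and counts follow floor((n-w)/s)+1", {
  p <- synth_dataset(n_loci = 10, n_taxa = 4, locus_length = 60,
                     diversity = seq(0.9, 0.1, length.out = 10), seed = 5)
  p <- compute_stats(p)
  p1 <- slide_loci(p, width = 4, step = 3)
  wins <- op_result(p1)
  expect_length(wins, 3L)
  expect_identical(names(wins), c("win_0", "win_1", "win_2"))
  sorted <- sort_loci(p)
  for (k in 0:2)
    expect_identical(wins[[k + 1]]$locus_names, sorted[(k * 3 + 1):(k * 3 + 4)])

  expect_length(op_result(slide_loci(p, width = 10, step = 3)), 1L)
  expect_error(slide_loci(p, width = 11, step = 3), "width")

  # formula vs explicit enumeration across random configurations
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:60, 1); w <- sample(1:n, 1); s <- sample(1:10, 1)
    offsets <- seq(0, n - w, by = s)
    expect_identical(length(offsets), (n - w) %/% s + 1L)
  }
})

test_that("a prescribed diversity gradient is recovered in sorted order", {
  p <- synth_dataset(n_loci = 10, n_taxa = 8, locus_length = 500,
                     diversity = seq(0.05, 0.95, length.out = 10), seed = 31)
  p <- compute_stats(p)
  # increasing diversity -> ascending entropy sort equals generation order
  expect_identical(sort_loci(p, order = "asc"), sprintf("L%03d", 1:10))
})

test_that("bias diagnostic reports rank correlation or undefined", {
  p <- compute_stats(shaped_project())
  # entropy and conservation are strictly monotone opposites here
  d <- bias_diagnostic(p, "entropy", "conservation")
  expect_identical(d$rho, -1)
  expect_identical(d$n, 3L)
  # constant side (gap score all 1) -> undefined, not zero
  d2 <- bias_diagnostic(p, "entropy", "gap_score")
  expect_true(is.na(d2$rho))

  # 10-locus table vs independent rank computation
  p10 <- synth_dataset(n_loci = 10, n_taxa = 6, locus_length = 80, seed = 13)
  p10 <- compute_stats(p10)
  a <- vapply(p10$stats, function(s) s$summaries$entropy$median, numeric(1))
  b <- vapply(p10$stats, function(s) s$summaries$gc$median, numeric(1))
  d3 <- bias_diagnostic(p10, "entropy", "gc")
  expect_equal(d3$rho, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
})
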