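# Independent oracles. The split enumerator below shares no code with the
# package: it walks the edge matrix with an explicit stack per edge and
# canonicalizes splits as the sorted pair of comma-joined sides.

oracle_splits <- function(tr) {
  tr <- ape::unroot(tr)
  nt <- length(tr$tip.label)
  keys <- character(0); trivial <- logical(0); lens <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    stack <- tr$edge[e, 2]
    tips <- integer(0)
    while (length(stack)) {
      nd <- stack[1]; stack <- stack[-1]
      if (nd <= nt) tips <- c(tips, nd)
      else stack <- c(stack, tr$edge[tr$edge[, 1] == nd, 2])
    }
    a <- paste(sort(tr$tip.label[tips]), collapse = ",")
    b <- paste(sort(setdiff(tr$tip.label, tr$tip.label[tips])), collapse = ",")
    key <- paste(sort(c(a, b)), collapse = " || ")
    i <- match(key, keys)
    len <- if (is.null(tr$edge.length)) NA_real_ else tr$edge.length[e]
    if (is.na(i)) {
      keys <- c(keys, key)
      trivial <- c(trivial, min(length(tips), nt - length(tips)) <= 1L)
      lens <- c(lens, len)
    } else lens[i] <- lens[i] + len
  }
  data.frame(key = keys, trivial = trivial, length = lens,
             stringsAsFactors = FALSE)
}

oracle_rf <- function(t1, t2) {
  k1 <- with(oracle_splits(t1), key[!trivial])
  k2 <- with(oracle_splits(t2), key[!trivial])
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

oracle_branch_score <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  keys <- union(s1$key, s2$key)
  b1 <- s1$length[match(keys, s1$key)]; b1[is.na(b1)] <- 0
  b2 <- s2$length[match(keys, s2$key)]; b2[is.na(b2)] <- 0
  sqrt(sum((b1 - b2)^2))
}

oracle_standardized_bs <- function(t1, t2) {
  u <- function(tr) { tr$edge.length <- tr$edge.length / sum(tr$edge.length); tr }
  oracle_branch_score(u(t1), u(t2))
}

# ---- toy project builders ---------------------------------------------------

# a project with hand-written pre-aligned sequences per locus:
# rows = list(locus_name = c(otu = "gapped sequence", ...))
toy_aligned_project <- function(rows, title = "toy") {
  loci <- lapply(names(rows), function(nm) locus(nm, feature_type = "CDS"))
  p <- create_project(loci, title = title)
  for (ln in names(rows)) {
    for (otu in names(rows[[ln]])) {
      seq <- rows[[ln]][[otu]]
      p <- phylocrate:::new_record(p, ln, gsub("[-?.]", "", seq), otu = otu,
                                   metadata = list(organism = otu),
                                   source = "toy")
    }
  }
  # register the gapped rows as alignments directly
  for (ln in names(rows)) {
    pid <- phylocrate:::next_process_id(p, "align")
    recs <- phylocrate:::records_of_locus(p, ln)
    gapped <- vapply(names(recs), function(rid)
      unname(rows[[ln]][[recs[[rid]]$otu]]), character(1))
    aln <- phylocrate:::new_alignment(paste0(ln, "@", pid), ln, gapped,
                                      produced_by = pid)
    p <- phylocrate:::register_alignment(p, aln)
    p <- phylocrate:::pc_log(p, "align", parameters = list(locus = ln),
                             outputs = aln$object_id)
  }
  p
}

# structural integrity scan: no dangling references anywhere
expect_project_closed <- function(p) {
  for (aln in c(p$alignments, p$trimmed))
    for (rid in names(aln$rows))
      expect_false(is.null(p$records[[rid]] %||% p$excluded[[rid]]),
                   label = paste("alignment row", rid, "resolves"))
  for (cc in p$concatenations)
    expect_true(all(cc$locus_names %in% names(p$loci)))
  for (sm in p$supermatrices)
    expect_true(all(sm$partitions$locus %in% names(p$loci)))
  pids <- vapply(p$ledger, `[[`, character(1), "process_id")
  expect_false(anyDuplicated(pids) > 0)
  expect_true(all(diff(as.integer(sub("_.*", "", pids))) > 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
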