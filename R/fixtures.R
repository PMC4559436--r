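# Synthetic data generators. Every pipeline stage is testable offline:
# multilocus DNA datasets with a controllable per-locus diversity gradient
# and occupancy pattern, random tree sets with a divergence knob, and small
# GenBank flat files to exercise the harvester.
#
# Sequence model: per column a dominant residue is drawn uniformly from
# ACGT; each row then carries the dominant residue with probability
# 1 - 3d/4 and each alternative with probability d/4, where d is the
# locus's diversity level. d = 0 gives invariant columns (entropy 0);
# d = 1 gives uniform columns (entropy 2 bits); expected column entropy is
# strictly increasing in d, which is what the gradient machinery needs.
# No tree-based substitution model is involved: the fixtures exercise the
# statistics and bookkeeping paths, not phylogenetic realism.

#' Generate a synthetic aligned multilocus project
#'
#' Defaults emulate a phylogenomic reanalysis-scale dataset: 465 loci by
#' 26 taxa at full occupancy, with a strictly decreasing per-locus
#' diversity gradient so locus 1 has the highest and the last locus the
#' lowest expected entropy. Sequences are generated aligned (no gaps), so
#' the batch aligner registers them as-is.
#'
#' @param n_loci,n_taxa,locus_length Dataset dimensions.
#' @param diversity Per-locus diversity levels in \[0, 1\] (see the model
#'   note above); a single number is recycled; the default is a strictly
#'   decreasing gradient from 0.95 to 0.05. Values above 1 would demand
#'   column entropy above the 2-bit DNA limit and are an error.
#' @param occupancy Fraction in (0, 1\] of taxon-locus cells carrying data,
#'   or a logical `n_taxa x n_loci` mask. 1 gives a complete matrix.
#' @param seed Integer seed; identical seeds give identical projects.
#' @param title Project title.
#' @return A `pc_project` with records and registered alignments.
#' @export
synth_dataset <- function(n_loci = 465, n_taxa = 26, locus_length = 300,
                          diversity = NULL, occupancy = 1.0, seed = 1,
                          title = "synthetic multilocus dataset") {
  stopifnot(n_loci >= 1, n_taxa >= 2, locus_length >= 1)
  if (is.null(diversity)) diversity <- seq(0.95, 0.05, length.out = n_loci)
  if (length(diversity) == 1L) diversity <- rep(diversity, n_loci)
  stopifnot(length(diversity) == n_loci)
  if (any(diversity < 0 | diversity > 1))
    stop("diversity levels must lie in [0, 1]: the DNA column entropy ",
         "ceiling is 2 bits (uniform residues)", call. = FALSE)
  if (is.matrix(occupancy)) {
    stopifnot(dim(occupancy) == c(n_taxa, n_loci))
    mask <- occupancy
  } else {
    stopifnot(occupancy > 0, occupancy <= 1)
    mask <- NULL   # drawn below, under the seed
  }
  set.seed(seed)
  otus <- sprintf("Taxon_%02d", seq_len(n_taxa))
  locus_names <- sprintf("L%03d", seq_len(n_loci))
  loci <- lapply(locus_names, function(nm) locus(nm, feature_type = "CDS"))
  if (is.null(mask)) {
    mask <- matrix(stats::runif(n_taxa * n_loci) <= occupancy, n_taxa, n_loci)
    for (j in seq_len(n_loci))   # keep every locus analysable
      if (sum(mask[, j]) < 2L) mask[sample(n_taxa, 2L), j] <- TRUE
  }
  alphabet <- c("A", "C", "G", "T")
  project <- create_project(loci, title = title)
  for (j in seq_len(n_loci)) {
    d <- diversity[j]
    dominant <- sample(alphabet, locus_length, replace = TRUE)
    taxa_in <- which(mask[, j])
    p_dom <- 1 - 0.75 * d
    for (i in taxa_in) {
      keep <- stats::runif(locus_length) <= p_dom
      alt <- sample(alphabet, locus_length, replace = TRUE)
      seqchars <- ifelse(keep, dominant, alt)
      project <- new_record(project, locus_names[j],
                            paste(seqchars, collapse = ""),
                            otu = otus[i],
                            metadata = list(organism = otus[i],
                                            diversity = d),
                            source = "synth")
    }
  }
  project <- pc_log(project, "synth_dataset",
    parameters = list(n_loci = n_loci, n_taxa = n_taxa,
                      locus_length = locus_length, occupancy_mean = mean(mask),
                      seed = seed))
  suppressWarnings(align_loci(project, stage_conf("align", "asis")))
}

#' Generate random trees with a shared leaf set
#'
#' A base random binary tree plus `n_trees - 1` derived trees. The
#' divergence knob in \[0, 1\] sets how many leaves are detached and
#' re-attached at random positions in each derived tree: 0 yields identical
#' copies, 1 relocates every leaf (effectively independent topologies).
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param n_trees Number of trees.
#' @param divergence Knob in \[0, 1\].
#' @param seed Integer seed.
#' @return List of ape `phylo` trees named `synth_tree_<i>`, tips
#'   `t01, t02, ...`.
#' @export
synth_trees <- function(n_taxa, n_trees, divergence = 0.5, seed = 1) {
  stopifnot(n_taxa >= 4, n_trees >= 1, divergence >= 0, divergence <= 1)
  set.seed(seed)
  base <- ape::rtree(n_taxa, tip.label = sprintf("t%02d", seq_len(n_taxa)))
  n_moves <- round(divergence * n_taxa)
  trees <- vector("list", n_trees)
  trees[[1]] <- base
  for (k in seq_len(n_trees - 1L)) {
    tr <- base
    if (n_moves > 0) for (m in seq_len(n_moves)) tr <- relocate_leaf(tr)
    trees[[k + 1L]] <- tr
  }
  stats::setNames(trees, sprintf("synth_tree_%d", seq_len(n_trees)))
}

# detach one random leaf and re-attach it halfway along a random edge
relocate_leaf <- function(tr) {
  leaf <- sample(tr$tip.label, 1L)
  rest <- ape::drop.tip(tr, leaf)
  e <- sample(nrow(rest$edge), 1L)
  donor <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "..tmp..",
                          edge.length = stats::runif(1, 0.05, 1), Nnode = 1L),
                     class = "phylo")
  out <- ape::bind.tree(rest, donor, where = rest$edge[e, 2],
                        position = rest$edge.length[e] / 2)
  out$tip.label[out$tip.label == "..tmp.."] <- leaf
  out
}

#' Write a small synthetic GenBank flat file
#'
#' Each entry carries one `cox1` CDS and one `18S ribosomal RNA` rRNA
#' feature with random sequence, organism metadata and accessions
#' `SYN00001, ...` — enough structure to exercise [read_genbank()] and
#' [list_loci()] end to end without any downloaded data. The file is
#' synthetic and says so in its DEFINITION lines.
#'
#' @param path Output file.
#' @param organisms Character vector; one entry is written per organism.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
synth_genbank <- function(path, organisms, seed = 1) {
  set.seed(seed)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(organisms)) {
    org <- organisms[i]
    acc <- sprintf("SYN%05d", i)
    seqlen <- 360L
    s <- paste(sample(c("a", "c", "g", "t"), seqlen, replace = TRUE),
               collapse = "")
    writeLines(c(
      sprintf("LOCUS       %s             %d bp    DNA     linear   SYN", acc, seqlen),
      sprintf("DEFINITION  synthetic record for %s.", org),
      sprintf("ACCESSION   %s", acc),
      "SOURCE      synthetic construct",
      sprintf("  ORGANISM  %s", org),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", seqlen),
      sprintf("                     /organism=\"%s\"", org),
      "     CDS             1..180",
      "                     /gene=\"cox1\"",
      "                     /product=\"cytochrome c oxidase subunit I\"",
      "     rRNA            complement(181..360)",
      "                     /product=\"18S ribosomal RNA\"",
      "ORIGIN"), con)
    for (off in seq(1L, seqlen, by = 60L)) {
      chunk <- substr(s, off, min(off + 59L, seqlen))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
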