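# Supermatrix recipes (Concatenation) and their realization: a concatenated,
# partitioned alignment over OTUs with an occupancy table.

#' Declare a supermatrix recipe
#'
#' A concatenation is declarative: it names the loci to concatenate, the
#' metadata field whose values become the supermatrix rows (OTUs), and the
#' occupancy rules an OTU must satisfy to be included. Building the actual
#' matrix is [build_supermatrix()].
#'
#' @param name Recipe name.
#' @param locus_names Ordered locus names, no duplicates.
#' @param otu_field Metadata field defining OTUs (default `"organism"`).
#' @param rules `list(otus_must_have = <locus names>, min_loci_per_otu = <int>)`;
#'   `NULL` means no constraint. The preset `rules = "complete"` requires
#'   every OTU to have every locus (a zero-missing-data supermatrix).
#' @return A `pc_concatenation`.
#' @export
concatenation <- function(name, locus_names, otu_field = "organism",
                          rules = NULL) {
  locus_names <- as.character(locus_names)
  if (length(locus_names) == 0L)
    stop("a concatenation needs at least one locus", call. = FALSE)
  if (anyDuplicated(locus_names))
    stop("duplicate locus in concatenation: ",
         locus_names[duplicated(locus_names)][1], call. = FALSE)
  if (identical(rules, "complete"))
    rules <- list(otus_must_have = locus_names, min_loci_per_otu = 0L)
  if (is.null(rules)) rules <- list(otus_must_have = NULL, min_loci_per_otu = 0L)
  if (!is.null(rules$otus_must_have) &&
      !all(rules$otus_must_have %in% locus_names))
    stop("rules$otus_must_have lists loci outside the concatenation",
         call. = FALSE)
  structure(
    list(name = name, locus_names = locus_names, otu_field = otu_field,
         rules = rules, produced_by = NA_character_),
    class = "pc_concatenation")
}

#' @export
print.pc_concatenation <- function(x, ...) {
  cat(sprintf("<concatenation %s> %d loci, otu_field=%s\n",
              x$name, length(x$locus_names), x$otu_field))
  invisible(x)
}

# One representative aligned sequence per OTU from a locus alignment:
# the longest ungapped sequence, ties broken by lexicographic record_id.
otu_representatives <- function(project, aln) {
  otus <- vapply(names(aln$rows), function(rid)
    (project$records[[rid]] %||% project$excluded[[rid]])$otu, character(1))
  reps <- list()
  for (otu in unique(otus)) {
    rids <- names(aln$rows)[otus == otu]
    lens <- nchar(degap(aln$rows[rids]))
    best <- rids[order(-lens, rids)][1]
    reps[[otu]] <- best
  }
  reps
}

#' Realize a supermatrix from a recipe
#'
#' Concatenates, in recipe order, one aligned sequence per OTU per locus
#' (the longest ungapped sequence when an OTU has several records for a
#' locus; ties broken by record id). OTUs failing the recipe rules are
#' dropped; an OTU lacking a locus it is allowed to lack is filled with
#' `"?"` across that partition, distinguishing absent loci from alignment
#' gaps `"-"`. Partitions are 1-based inclusive and tile the matrix exactly.
#'
#' @param project A `pc_project` whose recipe loci all have alignments.
#' @param conc A `pc_concatenation` or the name of a registered recipe.
#' @param use_trimmed Prefer trimmed alignments when present.
#' @return Updated project; [op_result()] is the `pc_supermatrix`, with
#'   fields `rows` (otu -> sequence), `partitions` (data frame
#'   locus/start/end), `occupancy` (logical otu x locus matrix) and
#'   `missing_cells`.
#' @export
build_supermatrix <- function(project, conc, use_trimmed = TRUE) {
  if (is.character(conc)) {
    conc <- project$concatenations[[conc]] %||%
      stop("no concatenation named '", conc, "'", call. = FALSE)
  }
  alns <- list()
  for (ln in conc$locus_names) {
    aln <- locus_alignment(project, ln, prefer_trimmed = use_trimmed)
    if (is.null(aln))
      stop("locus '", ln, "' has no alignment; align (or register) it first",
           call. = FALSE)
    alns[[ln]] <- aln
  }
  reps <- lapply(alns, otu_representatives, project = project)
  all_otus <- sort(unique(unlist(lapply(reps, names))))
  occupancy <- vapply(conc$locus_names,
                      function(ln) all_otus %in% names(reps[[ln]]),
                      logical(length(all_otus)))
  if (length(all_otus) == 1L)
    occupancy <- matrix(occupancy, nrow = 1L,
                        dimnames = list(all_otus, conc$locus_names))
  else dimnames(occupancy) <- list(all_otus, conc$locus_names)

  keep <- rep(TRUE, length(all_otus))
  if (!is.null(conc$rules$otus_must_have))
    keep <- keep & apply(occupancy[, conc$rules$otus_must_have, drop = FALSE],
                         1L, all)
  min_loci <- conc$rules$min_loci_per_otu %||% 0L
  keep <- keep & rowSums(occupancy) >= min_loci
  if (!any(keep))
    stop("no OTU satisfies the occupancy rules of '", conc$name, "'",
         call. = FALSE)
  otus <- all_otus[keep]
  occupancy <- occupancy[otus, , drop = FALSE]

  lens <- vapply(alns, `[[`, numeric(1), "length")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  partitions <- data.frame(locus = conc$locus_names,
                           start = as.integer(starts), end = as.integer(ends),
                           stringsAsFactors = FALSE)
  rows <- vapply(otus, function(otu) {
    paste(vapply(conc$locus_names, function(ln) {
      rid <- reps[[ln]][[otu]]
      if (is.null(rid)) strrep("?", lens[[ln]]) else unname(alns[[ln]]$rows[[rid]])
    }, character(1)), collapse = "")
  }, character(1))

  sm <- structure(
    list(name = conc$name, rows = rows, partitions = partitions,
         occupancy = occupancy,
         missing_cells = sum(!occupancy),
         total_length = as.integer(ends[length(ends)]),
         produced_by = next_process_id(project, "build_supermatrix")),
    class = "pc_supermatrix")
  project$supermatrices[[conc$name]] <- sm
  project <- pc_log(project, "build_supermatrix",
    parameters = list(name = conc$name, loci = conc$locus_names,
                      use_trimmed = use_trimmed,
                      n_otus = length(otus),
                      missing_cells = sm$missing_cells),
    inputs = vapply(alns, `[[`, character(1), "object_id"),
    outputs = conc$name)
  with_result(project, sm)
}

#' @export
print.pc_supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix %s> %d OTUs x %d columns, %d loci, %d missing cells\n",
              x$name, length(x$rows), x$total_length, nrow(x$partitions),
              x$missing_cells))
  invisible(x)
}

#' Occupancy table of a supermatrix
#'
#' @param sm A `pc_supermatrix`.
#' @return `list(table, per_otu, per_locus, overall)`: the logical otu x
#'   locus table and coverage fractions by OTU, by locus, and overall.
#' @export
occupancy_table <- function(sm) {
  stopifnot(inherits(sm, "pc_supermatrix"))
  list(table = sm$occupancy,
       per_otu = rowMeans(sm$occupancy),
       per_locus = colMeans(sm$occupancy),
       overall = mean(sm$occupancy))
}

#' Write a supermatrix with its partition and occupancy files
#'
#' @param sm A `pc_supermatrix`.
#' @param path Output directory.
#' @param format `"phylip"` (relaxed) or `"fasta"`.
#' @param char_type Partition-file data type tag.
#' @return Character vector: matrix file, partition file, occupancy TSV.
#' @export
write_supermatrix <- function(sm, path, format = c("phylip", "fasta"),
                              char_type = "DNA") {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(path, gsub("[^A-Za-z0-9_.-]", "_", sm$name))
  mat <- if (format == "phylip") write_phylip_relaxed(sm$rows, paste0(base, ".phy"))
         else write_fasta_named(sm$rows, paste0(base, ".fasta"))
  part <- write_partition_file(sm$partitions, paste0(base, ".partitions"),
                               char_type)
  occ <- paste0(base, ".occupancy.tsv")
  utils::write.table(sm$occupancy * 1L, occ, sep = "\t", quote = FALSE,
                     col.names = NA)
  c(mat, part, occ)
}
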