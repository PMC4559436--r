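# Readers and writers for the standard interchange formats the workflow
# touches: FASTA (Biostrings), Newick (ape), relaxed PHYLIP, PhyloXML (xml2),
# CSV metadata tables and RAxML-style partition files.

degap <- function(x) gsub("[-?.]", "", x)

# ---- alignment / tree containers -------------------------------------------

# rows: named character vector, record_id -> gapped sequence
new_alignment <- function(object_id, locus_name, rows, produced_by = NA_character_) {
  lens <- nchar(rows)
  if (length(unique(lens)) > 1L)
    stop("alignment rows differ in length (", paste(unique(lens), collapse = ", "),
         ")", call. = FALSE)
  structure(
    list(object_id = object_id, locus_name = locus_name,
         rows = rows, length = unname(lens[1] %||% 0L),
         produced_by = produced_by),
    class = "pc_alignment")
}

#' @export
print.pc_alignment <- function(x, ...) {
  cat(sprintf("<alignment %s> locus=%s %d rows x %d columns (by %s)\n",
              x$object_id, x$locus_name, length(x$rows), x$length,
              x$produced_by))
  invisible(x)
}

# character matrix view, rows = records, cols = alignment columns
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- names(aln$rows)
  m
}

# register an alignment into the project, checking referential integrity
register_alignment <- function(project, aln, bin = "alignments") {
  for (rid in names(aln$rows)) {
    rec <- project$records[[rid]] %||% project$excluded[[rid]]
    if (is.null(rec))
      stop("alignment row '", rid, "' refers to no known record", call. = FALSE)
    if (!identical(degap(aln$rows[[rid]]), rec$sequence))
      stop("de-gapped alignment row '", rid,
           "' does not reproduce the record sequence", call. = FALSE)
  }
  project[[bin]][[aln$object_id]] <- aln
  project
}

# phylo: an ape "phylo"; leaf_map: tip label -> record_id or otu
new_tree <- function(object_id, phylo, leaf_map, produced_by = NA_character_,
                     annotations = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  structure(
    list(object_id = object_id, phylo = phylo, leaf_map = leaf_map,
         produced_by = produced_by, annotations = annotations),
    class = "pc_tree")
}

#' Total tree length (sum of branch lengths)
#' @param tree A `pc_tree` or ape `phylo`.
#' @return Numeric sum of all branch lengths.
#' @export
tree_length <- function(tree) {
  ph <- as_phylo(tree)
  if (is.null(ph$edge.length)) return(0)
  sum(ph$edge.length)
}

as_phylo <- function(tree) {
  if (inherits(tree, "pc_tree")) tree$phylo
  else if (inherits(tree, "phylo")) tree
  else stop("not a tree object", call. = FALSE)
}

#' @export
print.pc_tree <- function(x, ...) {
  cat(sprintf("<tree %s> %d tips, length %.4f (by %s)\n",
              x$object_id, length(x$phylo$tip.label), tree_length(x),
              x$produced_by))
  invisible(x)
}

# ---- FASTA ------------------------------------------------------------------

read_fasta_named <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

write_fasta_named <- function(x, path) {
  set <- Biostrings::BStringSet(unname(x))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path)
  path
}

#' Add records from a FASTA file
#'
#' One record per FASTA entry, assigned to `locus_name`. An optional CSV
#' metadata table keyed by FASTA header (first column, or a column named
#' `id`) is merged into each record's metadata; a row keyed to no header
#' raises a warning. Without a table (or without an OTU column) the OTU
#' defaults to the FASTA header itself.
#'
#' @param project A `pc_project`.
#' @param path FASTA file.
#' @param locus_name Project locus (alias-folded) the sequences belong to.
#' @param metadata_table Optional CSV path.
#' @return Updated project; [op_result()] is the number of records added.
#' @export
read_fasta <- function(project, path, locus_name, metadata_table = NULL) {
  locus_resolved <- resolve_locus(project, locus_name)
  if (is.na(locus_resolved))
    stop("unknown locus '", locus_name, "'", call. = FALSE)
  seqs <- read_fasta_named(path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA header: ", names(seqs)[duplicated(names(seqs))][1],
         call. = FALSE)
  meta <- NULL
  if (!is.null(metadata_table)) {
    meta <- utils::read.csv(metadata_table, stringsAsFactors = FALSE,
                            check.names = FALSE)
    keycol <- if ("id" %in% names(meta)) "id" else names(meta)[1]
    orphans <- setdiff(meta[[keycol]], names(seqs))
    if (length(orphans))
      warning("metadata rows with no matching FASTA header: ",
              paste(orphans, collapse = ", "))
    rownames(meta) <- meta[[keycol]]
  }
  src <- tools::file_path_sans_ext(basename(path))
  otu_field <- project$otu_field
  for (hdr in names(seqs)) {
    md <- list(source_file = basename(path), header = hdr)
    otu <- hdr
    if (!is.null(meta) && hdr %in% rownames(meta)) {
      row <- as.list(meta[hdr, , drop = FALSE])
      md <- c(md, row)
      if (!is.null(row[[otu_field]])) otu <- as.character(row[[otu_field]])
    }
    project <- new_record(project, locus_resolved, seqs[[hdr]],
                          otu = otu, metadata = md, source = src)
  }
  project <- pc_log(project, "read_fasta",
    parameters = list(path = path, locus = locus_resolved,
                      metadata_table = metadata_table, added = length(seqs)))
  with_result(project, length(seqs))
}

# ---- relaxed PHYLIP / partition files ---------------------------------------

write_phylip_relaxed <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(x), nchar(x[[1]])), con)
  writeLines(sprintf("%s  %s", names(x), unname(x)), con)
  path
}

# 1-based inclusive intervals, RAxML-style
write_partition_file <- function(partitions, path, char_type = "DNA") {
  writeLines(sprintf("%s, %s = %d-%d", toupper(char_type),
                     partitions$locus, partitions$start, partitions$end),
             path)
  path
}

# ---- PhyloXML ---------------------------------------------------------------

phyloxml_clade <- function(parent, phylo, node, edge_len, annotations, leaf_map) {
  clade <- xml2::xml_add_child(parent, "clade")
  if (!is.na(edge_len))
    xml2::xml_add_child(clade, "branch_length", format(edge_len, digits = 10))
  ntip <- length(phylo$tip.label)
  if (node <= ntip) {
    lab <- phylo$tip.label[node]
    xml2::xml_add_child(clade, "name", lab)
    ann <- annotations[[lab]]
    if (!is.null(ann))
      for (k in names(ann)) {
        prop <- xml2::xml_add_child(clade, "property", as.character(ann[[k]]))
        xml2::xml_set_attrs(prop, c(ref = paste0("phylocrate:", k),
                                    applies_to = "clade",
                                    datatype = "xsd:string"))
      }
  } else {
    if (!is.null(phylo$node.label)) {
      lab <- phylo$node.label[node - ntip]
      if (!is.na(lab) && nzchar(lab))
        xml2::xml_add_child(clade, "confidence", lab, type = "unknown")
    }
    kids <- phylo$edge[phylo$edge[, 1] == node, 2]
    lens <- phylo$edge.length[phylo$edge[, 1] == node]
    if (is.null(phylo$edge.length)) lens <- rep(NA_real_, length(kids))
    for (i in seq_along(kids))
      phyloxml_clade(clade, phylo, kids[i], lens[i], annotations, leaf_map)
  }
  invisible(clade)
}

write_phyloxml <- function(tree, path, rooted = FALSE) {
  ph <- as_phylo(tree)
  doc <- xml2::xml_new_root("phyloxml",
    xmlns = "http://www.phyloxml.org",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance")
  phy <- xml2::xml_add_child(doc, "phylogeny", rooted = tolower(as.character(rooted)))
  if (inherits(tree, "pc_tree"))
    xml2::xml_add_child(phy, "name", tree$object_id)
  root <- length(ph$tip.label) + 1L
  phyloxml_clade(phy, ph, root, NA_real_,
                 if (inherits(tree, "pc_tree")) tree$annotations else NULL,
                 if (inherits(tree, "pc_tree")) tree$leaf_map else NULL)
  xml2::write_xml(doc, path)
  path
}

# ---- project-level write ----------------------------------------------------

#' Write project objects to standard formats
#'
#' @param project A `pc_project`.
#' @param what One of `"records"`, `"alignments"`, `"trees"`,
#'   `"supermatrix"`, `"metadata"`.
#' @param format Output format: FASTA for sequence data (`"fasta"`),
#'   `"phylip"` for alignments/supermatrices, `"newick"` or `"phyloxml"` for
#'   trees, `"csv"` for metadata.
#' @param path Output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_project_files <- function(project, what, format, path) {
  supported <- list(records = "fasta",
                    alignments = c("fasta", "phylip"),
                    trees = c("newick", "phyloxml"),
                    supermatrix = c("fasta", "phylip"),
                    metadata = "csv")
  what <- match.arg(what, names(supported))
  if (!(format %in% supported[[what]]))
    stop("unsupported format '", format, "' for ", what,
         "; supported: ", paste(supported[[what]], collapse = ", "),
         call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (what == "records") {
    for (ln in names(project$loci)) {
      recs <- records_of_locus(project, ln)
      if (length(recs) == 0L) next
      x <- stats::setNames(vapply(recs, `[[`, character(1), "sequence"),
                           vapply(recs, `[[`, character(1), "record_id"))
      files <- c(files, write_fasta_named(x, file.path(path, paste0(ln, ".fasta"))))
    }
  } else if (what == "alignments") {
    for (aln in c(project$alignments, project$trimmed)) {
      f <- file.path(path, paste0(gsub("[^A-Za-z0-9_.-]", "_", aln$object_id),
                                  if (format == "fasta") ".fasta" else ".phy"))
      files <- c(files, if (format == "fasta") write_fasta_named(aln$rows, f)
                        else write_phylip_relaxed(aln$rows, f))
    }
  } else if (what == "trees") {
    for (tr in project$trees) {
      base <- gsub("[^A-Za-z0-9_.-]", "_", tr$object_id)
      if (format == "newick") {
        f <- file.path(path, paste0(base, ".nwk"))
        ape::write.tree(tr$phylo, f)
      } else {
        f <- file.path(path, paste0(base, ".xml"))
        write_phyloxml(tr, f)
      }
      files <- c(files, f)
    }
  } else if (what == "supermatrix") {
    for (sm in project$supermatrices)
      files <- c(files, write_supermatrix(sm, path, format))
  } else if (what == "metadata") {
    f <- file.path(path, "metadata.csv")
    utils::write.csv(metadata_table(project), f, row.names = FALSE)
    files <- f
  }
  files
}

#' Tabulate all record metadata
#'
#' One row per record (kept and excluded), one column per metadata key in
#' the union across records, plus `record_id`, `locus_name` and `otu`.
#'
#' @param project A `pc_project`.
#' @return A data frame; values are strings, missing keys are `NA`.
#' @export
metadata_table <- function(project) {
  recs <- c(project$records, project$excluded)
  keys <- unique(unlist(lapply(recs, function(r) names(r$metadata))))
  rows <- lapply(recs, function(r) {
    vals <- lapply(keys, function(k) {
      v <- r$metadata[[k]]
      if (is.null(v)) NA_character_ else as.character(v)
    })
    names(vals) <- keys
    c(list(record_id = r$record_id, locus_name = r$locus_name, otu = r$otu),
      vals)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(df) <- NULL
  df
}
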