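# The reproducibility layer: whole-project single-file serialization with an
# embedded integrity checksum, a content-addressed checkpoint store with
# linear history and restore, a human-readable report assembled from the
# provenance ledger, and a publishable self-contained archive.
#
# The on-disk format is deliberately open: one header line
#   phylocrate-project v1 md5:<checksum-of-body>
# followed by a JSON body holding all metadata, sequence rows, Newick
# strings and the full ledger, readable without this package.

SERIAL_HEADER <- "phylocrate-project v1"

md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(x, f, eos = NULL)
  unname(tools::md5sum(f))
}

num_or_na <- function(x) {
  vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
}

chr_or_na <- function(x) {
  vapply(x, function(v) if (is.null(v)) NA_character_ else as.character(v),
         character(1))
}

# ---- encode -----------------------------------------------------------------

encode_project <- function(project) {
  enc_aln <- function(a) list(
    object_id = a$object_id, locus_name = a$locus_name,
    rows = as.list(a$rows), produced_by = a$produced_by,
    kept_columns = a$kept_columns)
  enc_tree <- function(t) list(
    object_id = t$object_id,
    newick = ape::write.tree(t$phylo, digits = 12),
    leaf_map = as.list(t$leaf_map), produced_by = t$produced_by,
    annotations = t$annotations)
  enc_sm <- function(s) list(
    name = s$name, rows = as.list(s$rows),
    partitions = list(locus = s$partitions$locus,
                      start = s$partitions$start, end = s$partitions$end),
    occupancy = list(otus = rownames(s$occupancy),
                     loci = colnames(s$occupancy),
                     cells = as.integer(s$occupancy)),
    missing_cells = s$missing_cells, total_length = s$total_length,
    produced_by = s$produced_by)
  enc_stats <- function(st) unclass(st)
  list(title = project$title,
       otu_field = project$otu_field,
       loci = lapply(unname(project$loci), unclass),
       selection = as.list(project$selection),
       records = lapply(unname(project$records), unclass),
       excluded = lapply(unname(project$excluded), unclass),
       alignments = lapply(unname(project$alignments), enc_aln),
       trimmed = lapply(unname(project$trimmed), enc_aln),
       trees = lapply(unname(project$trees), enc_tree),
       concatenations = lapply(unname(project$concatenations), unclass),
       supermatrices = lapply(unname(project$supermatrices), enc_sm),
       stats = lapply(unname(project$stats), enc_stats),
       ledger = project$ledger,
       counters = project$counters,
       adapters = project$adapters,
       auto_checkpoint = project$auto_checkpoint)
}

serialize_body <- function(project) {
  as.character(jsonlite::toJSON(encode_project(project), auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null"))
}

#' Serialize a project to a single self-describing file
#'
#' The file is one header line (format tag + md5 checksum of the body)
#' followed by a JSON body containing every field of the project — loci,
#' records with metadata, alignment rows, Newick tree strings, supermatrix
#' rows and partitions, statistics and the full provenance ledger — so the
#' experiment stays accessible with any JSON parser, without this package.
#'
#' @param project A `pc_project`.
#' @param path Output file (conventionally `.phyloproj.json`).
#' @return `path`, invisibly.
#' @export
serialize_project <- function(project, path) {
  body <- serialize_body(project)
  writeLines(c(paste(SERIAL_HEADER, paste0("md5:", md5_string(body))), body),
             path)
  invisible(path)
}

# ---- decode -----------------------------------------------------------------

decode_project <- function(content) {
  named_by <- function(xs, field) stats::setNames(xs, vapply(xs, `[[`,
                                                  character(1), field))
  dec_locus <- function(l) structure(
    list(name = l$name, aliases = as.character(unlist(l$aliases)),
         feature_type = l$feature_type, char_type = l$char_type),
    class = "pc_locus")
  dec_record <- function(r) structure(
    list(record_id = r$record_id, locus_name = r$locus_name, otu = r$otu,
         sequence = r$sequence, metadata = r$metadata),
    class = "pc_record")
  dec_aln <- function(a) structure(
    list(object_id = a$object_id, locus_name = a$locus_name,
         rows = vapply(a$rows, as.character, character(1)),
         length = if (length(a$rows)) nchar(a$rows[[1]]) else 0L,
         produced_by = a$produced_by,
         kept_columns = if (is.null(a$kept_columns)) NULL
                        else as.integer(unlist(a$kept_columns))),
    class = "pc_alignment")
  dec_tree <- function(t) structure(
    list(object_id = t$object_id,
         phylo = ape::read.tree(text = t$newick),
         leaf_map = vapply(t$leaf_map, as.character, character(1)),
         produced_by = t$produced_by, annotations = t$annotations),
    class = "pc_tree")
  dec_conc <- function(cc) structure(
    list(name = cc$name, locus_names = as.character(unlist(cc$locus_names)),
         otu_field = cc$otu_field,
         rules = list(
           otus_must_have = if (is.null(cc$rules$otus_must_have)) NULL
                            else as.character(unlist(cc$rules$otus_must_have)),
           min_loci_per_otu = cc$rules$min_loci_per_otu %||% 0L),
         produced_by = cc$produced_by),
    class = "pc_concatenation")
  dec_sm <- function(s) {
    otus <- as.character(unlist(s$occupancy$otus))
    loci <- as.character(unlist(s$occupancy$loci))
    occ <- matrix(as.integer(unlist(s$occupancy$cells)) == 1L,
                  nrow = length(otus), ncol = length(loci),
                  dimnames = list(otus, loci))
    structure(
      list(name = s$name, rows = vapply(s$rows, as.character, character(1)),
           partitions = data.frame(
             locus = as.character(unlist(s$partitions$locus)),
             start = as.integer(unlist(s$partitions$start)),
             end = as.integer(unlist(s$partitions$end)),
             stringsAsFactors = FALSE),
           occupancy = occ, missing_cells = as.integer(s$missing_cells),
           total_length = as.integer(s$total_length),
           produced_by = s$produced_by),
      class = "pc_supermatrix")
  }
  dec_stats <- function(st) structure(
    list(locus_name = st$locus_name, source_alignment = st$source_alignment,
         n_rows = as.integer(st$n_rows), n_columns = as.integer(st$n_columns),
         column_entropy = num_or_na(st$column_entropy),
         column_gap_score = num_or_na(st$column_gap_score),
         column_conservation = num_or_na(st$column_conservation),
         record_lengths = as.integer(unlist(st$record_lengths)),
         record_gc = num_or_na(st$record_gc),
         summaries = lapply(st$summaries, function(s)
           lapply(s, function(v) if (is.null(v)) NA_real_ else as.numeric(v)))),
    class = "pc_locus_stats")
  dec_ledger <- function(e) list(
    process_id = e$process_id, operation = e$operation,
    parameters = e$parameters, tool = e$tool, timestamp = e$timestamp,
    input_ids = as.character(unlist(e$input_ids)),
    output_ids = as.character(unlist(e$output_ids)))

  structure(
    list(title = content$title,
         otu_field = content$otu_field,
         loci = named_by(lapply(content$loci, dec_locus), "name"),
         selection = as.character(unlist(content$selection)),
         records = named_by(lapply(content$records, dec_record), "record_id"),
         excluded = named_by(lapply(content$excluded, dec_record), "record_id"),
         alignments = named_by(lapply(content$alignments, dec_aln), "object_id"),
         trimmed = named_by(lapply(content$trimmed, dec_aln), "object_id"),
         trees = named_by(lapply(content$trees, dec_tree), "object_id"),
         concatenations = named_by(lapply(content$concatenations, dec_conc),
                                   "name"),
         supermatrices = named_by(lapply(content$supermatrices, dec_sm), "name"),
         stats = named_by(lapply(content$stats, dec_stats), "locus_name"),
         ledger = lapply(content$ledger, dec_ledger),
         counters = list(process = as.integer(content$counters$process),
                         record = as.integer(content$counters$record)),
         adapters = content$adapters,
         store = NULL,
         auto_checkpoint = isTRUE(content$auto_checkpoint)),
    class = "pc_project")
}

#' Load a serialized project
#'
#' Verifies the embedded checksum before rebuilding anything; a corrupt or
#' truncated file fails with an integrity error and yields no partial
#' object.
#'
#' @param path File written by [serialize_project()].
#' @return A `pc_project` (with no checkpoint store attached).
#' @export
deserialize_project <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1], SERIAL_HEADER))
    stop("not a serialized project file: ", path, call. = FALSE)
  want <- sub(".*md5:", "", lines[1])
  body <- paste(lines[-1], collapse = "\n")
  if (!identical(md5_string(body), want))
    stop("integrity error: checksum mismatch in ", path,
         " (file corrupt or truncated)", call. = FALSE)
  decode_project(jsonlite::fromJSON(body, simplifyVector = FALSE))
}

#' Compare two projects for equality
#'
#' Field-by-field equality through the canonical serialization (the
#' attached checkpoint store, an environment detail, is not part of it).
#'
#' @param a,b `pc_project` objects.
#' @param ignore_timestamps Drop ledger timestamps before comparing, for
#'   comparing independent replays of the same operations.
#' @return `TRUE` or `FALSE`.
#' @export
project_equal <- function(a, b, ignore_timestamps = FALSE) {
  body_a <- serialize_body(a)
  body_b <- serialize_body(b)
  if (ignore_timestamps) {
    strip <- function(x) gsub('"timestamp":"[^"]*"', '"timestamp":""', x)
    body_a <- strip(body_a)
    body_b <- strip(body_b)
  }
  identical(body_a, body_b)
}

# ---- checkpoint store -------------------------------------------------------

#' Initialize a checkpoint store
#'
#' A content-addressed directory store: `objects/<md5>.json` holds each
#' distinct project state; `chain.jsonl` is the append-only linear history.
#'
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly.
#' @export
init_store <- function(dir) {
  dir.create(file.path(dir, "objects"), showWarnings = FALSE, recursive = TRUE)
  chain <- file.path(dir, "chain.jsonl")
  if (!file.exists(chain)) file.create(chain)
  invisible(dir)
}

#' Attach a checkpoint store to a project
#'
#' After attaching, every mutating operation automatically checkpoints the
#' project (switch off with `auto = FALSE` and call [checkpoint()]
#' yourself). Attaching writes the first checkpoint.
#'
#' @param project A `pc_project`.
#' @param dir Store directory ([init_store()] is called on it).
#' @param auto Auto-checkpoint on every mutation.
#' @return Updated project.
#' @export
attach_store <- function(project, dir, auto = TRUE) {
  init_store(dir)
  project$auto_checkpoint <- auto
  project$store <- dir
  # the pc_log call below auto-checkpoints this attach when auto = TRUE
  project <- pc_log(project, "attach_store",
                    parameters = list(dir = dir, auto = auto))
  if (!auto) checkpoint(dir, project, message = "attach_store")
  project
}

read_chain <- function(store) {
  chain <- file.path(store, "chain.jsonl")
  lines <- if (file.exists(chain)) readLines(chain, warn = FALSE) else character()
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON)
}

#' Checkpoint a project into a store
#'
#' The checkpoint id is the md5 of the serialized content, so identical
#' states share one id: checkpointing twice with no intervening change is a
#' no-op returning the same id. History is a single chain; forks live
#' inside the project as alternative objects.
#'
#' @param store Store directory.
#' @param project A `pc_project`.
#' @param message Short description recorded in the chain.
#' @return `list(checkpoint_id, parent_id, message, timestamp)`, invisibly.
#' @export
checkpoint <- function(store, project, message = "") {
  init_store(store)
  body <- serialize_body(project)
  id <- md5_string(body)
  chain <- read_chain(store)
  parent <- if (length(chain)) chain[[length(chain)]]$checkpoint_id else NA
  if (identical(parent, id))
    return(invisible(chain[[length(chain)]]))
  obj <- file.path(store, "objects", paste0(id, ".json"))
  if (!file.exists(obj))
    writeLines(c(paste(SERIAL_HEADER, paste0("md5:", id)), body), obj)
  entry <- list(checkpoint_id = id,
                parent_id = if (is.na(parent)) NULL else parent,
                message = message,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  entry <- entry[!vapply(entry, is.null, logical(1))]
  cat(as.character(jsonlite::toJSON(entry, auto_unbox = TRUE)), "\n",
      sep = "", file = file.path(store, "chain.jsonl"), append = TRUE)
  invisible(list(checkpoint_id = id, parent_id = parent, message = message,
                 timestamp = entry$timestamp))
}

#' List the checkpoint chain
#'
#' @param store Store directory.
#' @return Data frame: `checkpoint_id`, `parent_id`, `message`, `timestamp`.
#' @export
list_checkpoints <- function(store) {
  chain <- read_chain(store)
  if (length(chain) == 0L)
    return(data.frame(checkpoint_id = character(), parent_id = character(),
                      message = character(), timestamp = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(chain, function(e)
    data.frame(checkpoint_id = e$checkpoint_id,
               parent_id = e$parent_id %||% NA_character_,
               message = e$message %||% "",
               timestamp = e$timestamp %||% "", stringsAsFactors = FALSE)))
}

#' Restore a checkpointed project state
#'
#' Returns the project exactly as of the checkpoint — every intermediate
#' object and the ledger prefix included. The store is append-only, so
#' toggling between any checkpoints, in any order, is always possible.
#' Restoring does not itself create a checkpoint; the store stays attached,
#' so the next mutation extends the chain from the restored state.
#'
#' @param store Store directory.
#' @param checkpoint_id Id from [list_checkpoints()] (unique prefix allowed).
#' @return A `pc_project`.
#' @export
restore <- function(store, checkpoint_id) {
  chain <- list_checkpoints(store)
  hit <- chain$checkpoint_id[startsWith(chain$checkpoint_id, checkpoint_id)]
  hit <- unique(hit)
  if (length(hit) != 1L)
    stop("unknown or ambiguous checkpoint '", checkpoint_id,
         "'; available:\n  ",
         paste(sprintf("%s  %s", chain$checkpoint_id, chain$message),
               collapse = "\n  "), call. = FALSE)
  p <- deserialize_project(file.path(store, "objects", paste0(hit, ".json")))
  p$store <- store
  p
}

# ---- report -----------------------------------------------------------------

fmt_params <- function(params) {
  params <- params[!vapply(params, is.null, logical(1))]
  if (length(params) == 0L) return("(none)")
  paste(vapply(names(params), function(k) {
    v <- params[[k]]
    v <- if (length(v) > 6L) paste0(paste(utils::head(v, 6L), collapse = ","),
                                    ",... [", length(v), "]")
         else paste(unlist(v), collapse = ",")
    paste0(k, "=", v)
  }, character(1)), collapse = "; ")
}

#' Assemble the human-readable project report
#'
#' A methods-and-results document built from the provenance ledger:
#' environment (platform and library versions), a methods section listing
#' every operation with its tool, version and parameters, a data section
#' (loci, record counts, accessions), and a results section (per-locus
#' statistic summaries, supermatrix dimensions and occupancy, trees).
#' Only the `Generated:` header line varies between runs on an unchanged
#' project.
#'
#' @param project A `pc_project`.
#' @return Character vector of Markdown lines.
#' @export
project_report <- function(project) {
  md <- c(paste("#", project$title),
          "",
          paste("Generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
          "",
          "## Environment", "",
          paste("-", R.version.string),
          paste("- Platform:", R.version$platform))
  for (pkg in c("phylocrate", "ape", "Biostrings", "jsonlite", "xml2"))
    md <- c(md, sprintf("- %s %s", pkg,
                        as.character(utils::packageVersion(pkg))))
  md <- c(md, "", "## Methods", "")
  for (e in project$ledger)
    md <- c(md, sprintf("- `%s`: %s using %s; parameters: %s",
                        e$process_id, e$operation, e$tool,
                        fmt_params(e$parameters)))
  md <- c(md, "", "## Data", "")
  for (loc in project$loci) {
    recs <- records_of_locus(project, loc$name)
    md <- c(md, sprintf("- locus **%s** (%s, %s): %d records, %d OTUs",
                        loc$name, loc$feature_type, loc$char_type,
                        length(recs), length(otus_of_locus(project, loc$name))))
  }
  accs <- sort(unique(unlist(lapply(c(project$records, project$excluded),
                                    function(r) r$metadata$accession))))
  if (length(accs))
    md <- c(md, "", paste("Accessions:", paste(accs, collapse = ", ")))
  md <- c(md, "", "## Results", "")
  if (length(project$stats)) {
    md <- c(md, "| locus | median entropy (bits) | median gap score | median GC |",
            "|---|---|---|---|")
    for (st in project$stats)
      md <- c(md, sprintf("| %s | %.4f | %.4f | %.4f |", st$locus_name,
                          st$summaries$entropy$median,
                          st$summaries$gap_score$median,
                          st$summaries$gc$median))
  }
  for (sm in project$supermatrices)
    md <- c(md, sprintf("- supermatrix **%s**: %d OTUs x %d columns, %d loci, %d missing cells",
                        sm$name, length(sm$rows), sm$total_length,
                        nrow(sm$partitions), sm$missing_cells))
  for (tr in project$trees)
    md <- c(md, sprintf("- tree **%s**: %d tips, total length %.4f",
                        tr$object_id, length(tr$phylo$tip.label),
                        tree_length(tr)))
  md
}

md_to_html <- function(md) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- vapply(md, function(ln) {
    if (grepl("^### ", ln)) paste0("<h3>", esc(sub("^### ", "", ln)), "</h3>")
    else if (grepl("^## ", ln)) paste0("<h2>", esc(sub("^## ", "", ln)), "</h2>")
    else if (grepl("^# ", ln)) paste0("<h1>", esc(sub("^# ", "", ln)), "</h1>")
    else if (grepl("^- ", ln)) paste0("<li>", esc(sub("^- ", "", ln)), "</li>")
    else if (grepl("^\\|", ln)) paste0("<code>", esc(ln), "</code><br/>")
    else if (!nzchar(ln)) "<p></p>"
    else paste0("<p>", esc(ln), "</p>")
  }, character(1))
  c("<!DOCTYPE html><html><head><meta charset='utf-8'/></head><body>",
    unname(body), "</body></html>")
}

#' Write the report as Markdown and HTML
#'
#' @param project A `pc_project`.
#' @param dir Output directory.
#' @return Paths of `report.md` and `report.html`.
#' @export
write_report <- function(project, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- project_report(project)
  md_path <- file.path(dir, "report.md")
  html_path <- file.path(dir, "report.html")
  writeLines(md, md_path)
  writeLines(md_to_html(md), html_path)
  c(md_path, html_path)
}

# ---- archive ----------------------------------------------------------------

#' Build a publishable experiment archive
#'
#' Produces a zip containing the serialized project, every alignment
#' (FASTA), every tree (Newick and PhyloXML), each supermatrix with its
#' partition and occupancy files, the Markdown/HTML report, the checkpoint
#' chain listing when a store is attached, and a manifest of md5 checksums
#' for every member. Extracting the archive and loading `project.json`
#' recovers the project exactly — the archive is self-contained.
#'
#' @param project A `pc_project`.
#' @param path Output `.zip` path.
#' @return `path`, invisibly.
#' @export
archive_project <- function(project, path) {
  stage <- tempfile("phylocrate_archive_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  serialize_project(project, file.path(stage, "project.json"))
  if (length(project$alignments) || length(project$trimmed))
    write_project_files(project, "alignments", "fasta",
                        file.path(stage, "alignments"))
  if (length(project$trees)) {
    write_project_files(project, "trees", "newick", file.path(stage, "trees"))
    write_project_files(project, "trees", "phyloxml", file.path(stage, "trees"))
  }
  if (length(project$supermatrices))
    write_project_files(project, "supermatrix", "phylip",
                        file.path(stage, "supermatrices"))
  if (length(c(project$records, project$excluded)))
    write_project_files(project, "metadata", "csv", stage)
  write_report(project, stage)
  if (!is.null(project$store)) {
    ck <- list_checkpoints(project$store)
    utils::write.table(ck, file.path(stage, "checkpoints.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  members <- list.files(stage, recursive = TRUE)
  sums <- tools::md5sum(file.path(stage, members))
  writeLines(sprintf("%s\t%s", unname(sums), members),
             file.path(stage, "MANIFEST.tsv"))
  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  status <- system2("python", c("-m", "zipfile", "-c", shQuote(path),
                                list.files(stage)))
  if (status != 0L) stop("failed to create zip archive at ", path, call. = FALSE)
  invisible(path)
}
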