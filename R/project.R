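#' Create a phylogenomics project
#'
#' The project is the single container for an entire multilocus experiment:
#' loci, sequence records, alignments (raw and trimmed), trees, supermatrix
#' recipes and realizations, per-locus statistics, and an append-only
#' provenance ledger. Every mutating operation appends exactly one ledger
#' entry recording the operation, its parameters, tool and version, and the
#' ids of its inputs and outputs, so any object in the container can be traced
#' back to the steps that produced it.
#'
#' @param loci List of [locus()] objects; may be empty (loci can be added
#'   later, e.g. after [list_loci()] inspection).
#' @param title Project title, used in reports.
#' @param otu_field Metadata field whose value defines the operational
#'   taxonomic unit (tree tip) of each record; defaults to `"organism"`.
#' @return An object of class `pc_project`.
#' @examples
#' p <- create_project(list(locus("coi", aliases = "cox1"), locus("18s")),
#'                     title = "demo")
#' length(p$ledger)  # 1: the creation entry
#' @export
create_project <- function(loci = list(), title = "untitled project",
                           otu_field = "organism") {
  if (inherits(loci, "pc_locus")) loci <- list(loci)
  loci <- check_locus_set(loci)
  p <- structure(
    list(title = title,
         otu_field = otu_field,
         loci = loci,
         selection = names(loci),       # loci currently in batch scope
         records = list(),
         excluded = list(),             # records parked by filters
         alignments = list(),
         trimmed = list(),
         trees = list(),
         concatenations = list(),
         supermatrices = list(),
         stats = list(),
         ledger = list(),
         counters = list(process = 0L, record = 0L),
         adapters = list(),
         store = NULL,
         auto_checkpoint = TRUE),
    class = "pc_project")
  pc_log(p, "create_project",
         parameters = list(title = title, n_loci = length(loci)),
         outputs = names(loci))
}

pc_version <- function() {
  as.character(utils::packageVersion("phylocrate"))
}

# Append one provenance ledger entry (the only way the ledger grows) and,
# when a store is attached with auto-checkpointing on, snapshot the project.
pc_log <- function(project, operation, parameters = list(),
                   inputs = character(), outputs = character(),
                   tool = paste0("phylocrate ", pc_version())) {
  serial <- project$counters$process + 1L
  project$counters$process <- serial
  entry <- list(
    process_id = sprintf("%04d_%s", serial, operation),
    operation  = operation,
    parameters = parameters,
    tool       = tool,
    timestamp  = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    input_ids  = as.character(inputs),
    output_ids = as.character(outputs))
  project$ledger[[length(project$ledger) + 1L]] <- entry
  if (!is.null(project$store) && isTRUE(project$auto_checkpoint) &&
      operation != "create_project")
    checkpoint(project$store, project, message = entry$process_id)
  project
}

last_process_id <- function(project) {
  project$ledger[[length(project$ledger)]]$process_id
}

# The id pc_log() will assign to the next entry for `operation`; used so a
# new object can carry produced_by before its creating entry is written.
next_process_id <- function(project, operation) {
  sprintf("%04d_%s", project$counters$process + 1L, operation)
}

#' @export
print.pc_project <- function(x, ...) {
  cat(sprintf("<phylocrate project> %s\n", x$title))
  cat(sprintf("  loci: %d (%d selected) | records: %d (+%d excluded)\n",
              length(x$loci), length(x$selection),
              length(x$records), length(x$excluded)))
  cat(sprintf("  alignments: %d | trimmed: %d | trees: %d | supermatrices: %d\n",
              length(x$alignments), length(x$trimmed), length(x$trees),
              length(x$supermatrices)))
  cat(sprintf("  ledger: %d entries (head %s)\n", length(x$ledger),
              last_process_id(x)))
  invisible(x)
}

#' Result attached to a returned project
#'
#' Mutating verbs return the updated project; side results (counts, filter
#' reports, newly created objects) ride along as the `"result"` attribute.
#'
#' @param project A `pc_project` returned by a mutating verb.
#' @return The operation's side result, or `NULL`.
#' @export
op_result <- function(project) attr(project, "result", exact = TRUE)

with_result <- function(project, value) {
  attr(project, "result") <- value
  project
}

# ---- records ----------------------------------------------------------------

GAP_CHARS <- c("-", "?", ".")

# Create a SequenceRecord and bin it under its locus. `source` is the
# accession or file stem the record came from; the id is
# <locus>_<source>_f<serial>, human-readable yet collision-free.
new_record <- function(project, locus_name, sequence, otu,
                       metadata = list(), source = "local") {
  stopifnot(locus_name %in% names(project$loci))
  sequence <- toupper(gsub(" ", "", sequence))
  if (grepl("[-?.]", sequence))
    stop("record sequences are ungapped; got gap characters in a sequence for locus ",
         locus_name, call. = FALSE)
  serial <- project$counters$record + 1L
  project$counters$record <- serial
  rid <- sprintf("%s_%s_f%d", locus_name, source, serial)
  rec <- structure(
    list(record_id = rid, locus_name = locus_name, otu = otu,
         sequence = sequence, metadata = metadata),
    class = "pc_record")
  project$records[[rid]] <- rec
  project
}

records_of_locus <- function(project, locus_name) {
  Filter(function(r) r$locus_name == locus_name, project$records)
}

otus_of_locus <- function(project, locus_name) {
  unique(vapply(records_of_locus(project, locus_name), `[[`, character(1), "otu"))
}

# ---- fetch ------------------------------------------------------------------

all_object_ids <- function(project) {
  c(names(project$records), names(project$excluded),
    names(project$alignments), names(project$trimmed), names(project$trees),
    names(project$concatenations), names(project$supermatrices),
    names(project$loci))
}

#' Fetch a copy of a project object
#'
#' Looks up a record, alignment, trimmed alignment, tree, concatenation,
#' supermatrix or locus by its id and returns an independent copy; mutating
#' the returned value never changes the project.
#'
#' @param project A `pc_project`.
#' @param object_id Id (or locus name) to fetch.
#' @return The stored object.
#' @export
fetch <- function(project, object_id) {
  for (bin in c("records", "excluded", "alignments", "trimmed", "trees",
                "concatenations", "supermatrices", "loci")) {
    obj <- project[[bin]][[object_id]]
    if (!is.null(obj)) return(obj)
  }
  pool <- all_object_ids(project)
  near <- utils::head(agrep(object_id, pool, max.distance = 0.3, value = TRUE), 5L)
  stop("no object with id '", object_id, "'",
       if (length(near)) paste0("; near matches: ", paste(near, collapse = ", ")),
       call. = FALSE)
}

# ---- metadata editing -------------------------------------------------------

#' Edit record metadata in bulk
#'
#' Selects records by id, locus and/or metadata equality, then sets `field`
#' either to a constant or to the value returned by a function of the record.
#' A selector matching nothing is not an error: 0 is returned with a warning.
#'
#' @param project A `pc_project`.
#' @param field Metadata field to set (the OTU field may be edited too).
#' @param value A single value, or a `function(record)` returning the new value.
#' @param ids,locus,where Selector: explicit record ids, a locus name
#'   (alias-folded), and/or a named list of metadata values that must match
#'   exactly. All given parts must hold (conjunction); all absent selects all.
#' @return The updated project; [op_result()] gives the number of records
#'   changed.
#' @export
edit_metadata <- function(project, field, value,
                          ids = NULL, locus = NULL, where = NULL) {
  stopifnot(is.character(field), length(field) == 1L)
  if (!is.null(locus)) {
    resolved <- resolve_locus(project, locus)
    if (is.na(resolved))
      stop("unknown locus '", locus, "' in selector", call. = FALSE)
    locus <- resolved
  }
  matches <- function(rec) {
    if (!is.null(ids) && !(rec$record_id %in% ids)) return(FALSE)
    if (!is.null(locus) && rec$locus_name != locus) return(FALSE)
    if (!is.null(where))
      for (k in names(where)) {
        have <- if (k == "otu") rec$otu else rec$metadata[[k]]
        if (is.null(have) || !identical(as.character(have), as.character(where[[k]])))
          return(FALSE)
      }
    TRUE
  }
  n <- 0L
  for (rid in names(project$records)) {
    rec <- project$records[[rid]]
    if (!matches(rec)) next
    newval <- if (is.function(value)) value(rec) else value
    if (field == "otu") rec$otu <- as.character(newval)
    else rec$metadata[[field]] <- newval
    project$records[[rid]] <- rec
    n <- n + 1L
  }
  if (n == 0L) warning("edit_metadata: selector matched no records")
  project <- pc_log(project, "edit_metadata",
    parameters = list(field = field,
                      value = if (is.function(value)) "<function>" else value,
                      ids = ids, locus = locus, where = where, updated = n))
  with_result(project, n)
}
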