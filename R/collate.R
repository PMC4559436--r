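# Data selection and filtering between harvest and analysis.

#' GC content of an ungapped sequence
#'
#' (G+C)/(A+C+G+T); ambiguity codes are excluded from both numerator and
#' denominator. This single definition is shared by the filters and by the
#' per-locus statistics, so filtering and reporting can never disagree.
#'
#' @param x Character vector of sequences (gaps tolerated, ignored).
#' @return Numeric vector in \[0, 1\]; `NaN` when no unambiguous base exists.
#' @examples
#' gc_content("ATGC")   # 0.5
#' @export
gc_content <- function(x) {
  x <- toupper(x)
  gc <- nchar(gsub("[^GC]", "", x))
  at <- nchar(gsub("[^AT]", "", x))
  gc / (gc + at)
}

#' Restrict the batch scope to chosen loci
#'
#' Downstream batch operations (stats, align, supermatrix recipes) act only
#' on the selected loci. Selecting all loci is the identity; names are
#' resolved through alias folding.
#'
#' @param project A `pc_project`.
#' @param names Locus names or aliases to select.
#' @return Updated project.
#' @export
select_loci <- function(project, names) {
  resolved <- vapply(names, function(nm) {
    r <- resolve_locus(project, nm)
    if (is.na(r))
      stop("unknown locus '", nm, "'; project loci: ",
           paste(base::names(project$loci), collapse = ", "), call. = FALSE)
    r
  }, character(1))
  project$selection <- unique(unname(resolved))
  project <- pc_log(project, "select_loci",
                    parameters = list(names = unname(resolved)))
  with_result(project, project$selection)
}

validate_range <- function(lo, hi, what) {
  if (!is.null(lo) && !is.null(hi) && lo > hi)
    stop("invalid ", what, " range: min ", lo, " > max ", hi, call. = FALSE)
}

#' Filter records by length, GC content or id
#'
#' Records failing any criterion are moved to the project's excluded bin —
#' recoverable, never deleted; `kept + excluded` always equals the original
#' record set. A record failing several criteria is attributed to the first
#' failing one in the fixed order length, GC, id, so reports are
#' deterministic. Length is the ungapped residue count (ambiguity codes
#' count); GC is [gc_content()].
#'
#' @param project A `pc_project`.
#' @param min_len,max_len Length bounds (inclusive).
#' @param min_gc,max_gc GC bounds in \[0, 1\] (inclusive).
#' @param include_ids If given, only these record ids are kept.
#' @param exclude_ids These record ids are excluded regardless.
#' @return Updated project; [op_result()] is a data frame
#'   (`record_id`, `locus_name`, `criterion`) of removed records, with
#'   attributes `kept` and `removed` (counts).
#' @export
filter_records <- function(project, min_len = NULL, max_len = NULL,
                           min_gc = NULL, max_gc = NULL,
                           include_ids = NULL, exclude_ids = NULL) {
  validate_range(min_len, max_len, "length")
  validate_range(min_gc, max_gc, "GC")
  for (b in c(min_gc, max_gc))
    if (!is.null(b) && (b < 0 || b > 1))
      stop("GC bounds must lie in [0, 1]", call. = FALSE)

  failing_criterion <- function(rec) {
    len <- nchar(rec$sequence)
    if (!is.null(min_len) && len < min_len) return("length")
    if (!is.null(max_len) && len > max_len) return("length")
    if (!is.null(min_gc) || !is.null(max_gc)) {
      gc <- gc_content(rec$sequence)
      if (!is.null(min_gc) && (is.nan(gc) || gc < min_gc)) return("gc")
      if (!is.null(max_gc) && (is.nan(gc) || gc > max_gc)) return("gc")
    }
    if (!is.null(include_ids) && !(rec$record_id %in% include_ids)) return("id")
    if (!is.null(exclude_ids) && rec$record_id %in% exclude_ids) return("id")
    NA_character_
  }

  removed <- list()
  for (rid in names(project$records)) {
    crit <- failing_criterion(project$records[[rid]])
    if (is.na(crit)) next
    removed[[length(removed) + 1L]] <-
      data.frame(record_id = rid,
                 locus_name = project$records[[rid]]$locus_name,
                 criterion = crit, stringsAsFactors = FALSE)
    project$excluded[[rid]] <- project$records[[rid]]
    project$records[[rid]] <- NULL
  }
  report <- if (length(removed)) do.call(rbind, removed) else
    data.frame(record_id = character(), locus_name = character(),
               criterion = character(), stringsAsFactors = FALSE)
  attr(report, "kept") <- length(project$records)
  attr(report, "removed") <- nrow(report)
  project <- pc_log(project, "filter_records",
    parameters = list(min_len = min_len, max_len = max_len,
                      min_gc = min_gc, max_gc = max_gc,
                      include_ids = include_ids, exclude_ids = exclude_ids,
                      kept = length(project$records), removed = nrow(report)))
  with_result(project, report)
}

#' Restore previously excluded records
#'
#' Moves records back from the excluded bin into the active set.
#'
#' @param project A `pc_project`.
#' @param ids Record ids to restore; default all excluded.
#' @return Updated project; [op_result()] is the number restored.
#' @export
unfilter_records <- function(project, ids = names(project$excluded)) {
  n <- 0L
  for (rid in ids) {
    if (is.null(project$excluded[[rid]])) next
    project$records[[rid]] <- project$excluded[[rid]]
    project$excluded[[rid]] <- NULL
    n <- n + 1L
  }
  project <- pc_log(project, "unfilter_records",
                    parameters = list(ids = ids, restored = n))
  with_result(project, n)
}

#' Filter loci by record count or taxonomic coverage
#'
#' Loci with fewer records, or fewer distinct OTUs, than the thresholds are
#' deselected (taxonomic coverage is interpreted as the number of distinct
#' OTUs with data for the locus). Deselection only narrows the batch scope;
#' no data is deleted.
#'
#' @param project A `pc_project`.
#' @param min_records Minimum number of records per locus.
#' @param min_otus Minimum number of distinct OTUs per locus.
#' @return Updated project; [op_result()] is a data frame per selected locus
#'   (`locus`, `n_records`, `n_otus`, `retained`).
#' @export
filter_loci <- function(project, min_records = 0L, min_otus = 0L) {
  stopifnot(min_records >= 0L, min_otus >= 0L)
  rows <- lapply(project$selection, function(ln) {
    nrec <- length(records_of_locus(project, ln))
    notu <- length(otus_of_locus(project, ln))
    data.frame(locus = ln, n_records = nrec, n_otus = notu,
               retained = nrec >= min_records && notu >= min_otus,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  project$selection <- report$locus[report$retained]
  if (length(project$selection) == 0L)
    warning("filter_loci: no locus passes the thresholds")
  project <- pc_log(project, "filter_loci",
    parameters = list(min_records = min_records, min_otus = min_otus,
                      retained = length(project$selection)))
  with_result(project, report)
}
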