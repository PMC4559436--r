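# GenBank flat-file harvesting.
#
# A deliberately small parser for the subset of the flat-file grammar the
# harvest needs: LOCUS / ACCESSION / DEFINITION, the SOURCE organism, the
# FEATURES table (keys, locations with join/complement, qualifiers incl.
# multi-line quoted values) and the ORIGIN sequence.

# ---- low-level parsing ------------------------------------------------------

parse_genbank_entries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  term <- grep("^//", lines)
  starts <- c(1L, utils::head(term, -1L) + 1L)
  if (length(term) == 0L) { starts <- 1L; term <- length(lines) }
  out <- list()
  for (i in seq_along(term)) {
    chunk <- lines[starts[i]:term[i]]
    if (any(grepl("^LOCUS", chunk)))
      out[[length(out) + 1L]] <- parse_genbank_entry(chunk)
  }
  out
}

parse_genbank_entry <- function(lines) {
  kw <- function(key) {
    i <- grep(paste0("^", key, "\\s"), lines)[1]
    if (is.na(i)) return(NA_character_)
    trimws(sub(paste0("^", key, "\\s+"), "", lines[i]))
  }
  locus_line <- kw("LOCUS")
  name <- if (is.na(locus_line)) NA_character_ else strsplit(locus_line, "\\s+")[[1]][1]
  accession <- kw("ACCESSION")
  if (!is.na(accession)) accession <- strsplit(accession, "\\s+")[[1]][1]
  if (is.na(accession) || !nzchar(accession)) accession <- name
  definition <- kw("DEFINITION")
  org_i <- grep("^\\s+ORGANISM\\s", lines)[1]
  organism <- if (is.na(org_i)) NA_character_ else
    trimws(sub("^\\s+ORGANISM\\s+", "", lines[org_i]))

  feat_i <- grep("^FEATURES", lines)[1]
  orig_i <- grep("^(ORIGIN|BASE COUNT)", lines)[1]
  features <- list()
  if (!is.na(feat_i)) {
    end <- if (is.na(orig_i)) length(lines) else orig_i - 1L
    if (end > feat_i)
      features <- parse_feature_table(lines[(feat_i + 1L):end])
  }

  sequence <- ""
  orig_i <- grep("^ORIGIN", lines)[1]
  if (!is.na(orig_i) && orig_i < length(lines)) {
    seq_lines <- lines[(orig_i + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  list(name = name, accession = accession, definition = definition,
       organism = organism, features = features, sequence = sequence)
}

# Feature lines have the key at column 6 and qualifiers indented with "/".
parse_feature_table <- function(lines) {
  feats <- list()
  cur <- NULL
  cur_qual <- NULL
  flush_feat <- function() if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  for (ln in lines) {
    if (grepl("^ {5}\\S", ln)) {                       # new feature
      flush_feat()
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = parts[1],
                  location = paste(parts[-1], collapse = ""),
                  qualifiers = list())
      cur_qual <- NULL
    } else if (!is.null(cur)) {
      body <- trimws(ln)
      if (startsWith(body, "/")) {                     # new qualifier
        m <- regmatches(body, regexec('^/([^=]+)(=(.*))?$', body))[[1]]
        qname <- m[2]
        qval <- if (length(m) >= 4 && nzchar(m[3])) m[4] else "TRUE"
        cur$qualifiers[[qname]] <- qval
        cur_qual <- qname
      } else if (!is.null(cur_qual)) {                 # continuation
        sep <- if (cur_qual %in% c("translation")) "" else " "
        cur$qualifiers[[cur_qual]] <-
          paste0(cur$qualifiers[[cur_qual]], sep, body)
      } else {                                         # location continuation
        cur$location <- paste0(cur$location, body)
      }
    }
  }
  flush_feat()
  for (i in seq_along(feats))
    feats[[i]]$qualifiers <- lapply(feats[[i]]$qualifiers, strip_quotes)
  feats
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

# Location grammar subset: 10..20, <10..>20, complement(...), join(a..b,c..d).
# Returns list(ranges = matrix(start, end), complement = logical).
parse_location <- function(loc) {
  comp <- grepl("complement", loc)
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",")[[1]]
  ranges <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2)))
  list(ranges = ranges, complement = comp)
}

extract_feature_seq <- function(entry_seq, location) {
  loc <- parse_location(location)
  pieces <- apply(loc$ranges, 1L, function(r) substr(entry_seq, r[1], r[2]))
  s <- paste(pieces, collapse = "")
  if (loc$complement)
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

feature_name <- function(feat) {
  feat$qualifiers$gene %||% feat$qualifiers$product %||% NA_character_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- harvesting -------------------------------------------------------------

#' Harvest records from GenBank flat files
#'
#' Scans every entry in the given files; each feature of a harvestable type
#' whose `gene` or `product` qualifier alias-folds to a project locus yields
#' one [SequenceRecord][create_project], carrying the feature sub-sequence
#' (reverse-complemented when on the minus strand), the source organism as
#' its OTU, the accession, and all feature qualifiers as metadata. Features
#' that match no locus are never silently dropped: they are returned in the
#' unassigned table of the result.
#'
#' @param project A `pc_project` with loci defined.
#' @param paths GenBank flat-file paths.
#' @param feature_types Feature keys considered harvestable.
#' @return Updated project; [op_result()] holds
#'   `list(added, unassigned)` where `unassigned` is a data frame of
#'   (accession, feature_type, name) for unmatched features.
#' @export
read_genbank <- function(project, paths,
                         feature_types = c("CDS", "rRNA", "gene", "tRNA")) {
  added <- 0L
  unassigned <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("cannot read GenBank file: ", path, call. = FALSE)
    entries <- parse_genbank_entries(path)
    if (length(entries) == 0L)
      warning("no GenBank entries found in ", path)
    for (entry in entries) {
      for (feat in entry$features) {
        if (!(feat$key %in% feature_types)) next
        nm <- feature_name(feat)
        if (is.na(nm)) next
        locus_name <- resolve_locus(project, nm)
        if (is.na(locus_name)) {
          unassigned[[length(unassigned) + 1L]] <-
            data.frame(accession = entry$accession, feature_type = feat$key,
                       name = nm, stringsAsFactors = FALSE)
          next
        }
        md <- c(list(accession = entry$accession,
                     definition = entry$definition,
                     organism = entry$organism,
                     feature_type = feat$key,
                     location = feat$location),
                feat$qualifiers)
        project <- new_record(project, locus_name,
                              extract_feature_seq(entry$sequence, feat$location),
                              otu = entry$organism, metadata = md,
                              source = entry$accession)
        added <- added + 1L
      }
    }
  }
  unassigned <- if (length(unassigned)) do.call(rbind, unassigned) else
    data.frame(accession = character(), feature_type = character(),
               name = character(), stringsAsFactors = FALSE)
  if (added == 0L) warning("read_genbank: no records were added")
  project <- pc_log(project, "read_genbank",
    parameters = list(paths = paths, feature_types = feature_types,
                      added = added, unassigned = nrow(unassigned)))
  with_result(project, list(added = added, unassigned = unassigned))
}

#' Inventory the loci present in GenBank files
#'
#' Lists every gene/product name observed on harvestable features, with
#' counts, grouped by alias folding so spelling variants of the same gene
#' land in one suggested group. The inventory is the raw material for
#' choosing which rows to turn into [locus()] definitions.
#'
#' @inheritParams read_genbank
#' @param paths GenBank flat-file paths.
#' @return Data frame with columns `feature_type`, `observed_name`, `count`,
#'   `suggested_group` (the fold key shared by synonymous spellings).
#' @export
list_loci <- function(paths, feature_types = c("CDS", "rRNA", "gene", "tRNA")) {
  rows <- list()
  for (path in paths) {
    for (entry in parse_genbank_entries(path)) {
      for (feat in entry$features) {
        if (!(feat$key %in% feature_types)) next
        nm <- feature_name(feat)
        if (is.na(nm)) next
        rows[[length(rows) + 1L]] <-
          data.frame(feature_type = feat$key, observed_name = nm,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(feature_type = character(), observed_name = character(),
                      count = integer(), suggested_group = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = seq_len(nrow(df))),
                          by = list(feature_type = df$feature_type,
                                    observed_name = df$observed_name),
                          FUN = length)
  agg$suggested_group <- fold_name(agg$observed_name)
  agg <- agg[order(agg$suggested_group, agg$observed_name), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
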