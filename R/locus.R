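#' Define a locus
#'
#' A locus names one gene or genomic region analysed across taxa. Sequences
#' assigned to a locus form one dataset that is aligned and analysed together.
#' Aliases are case-insensitive synonyms (GenBank gene naming is inconsistent:
#' `cox1`, `COX-1` and `COI` should all land in the same bin), folded by
#' lower-casing and stripping underscores, hyphens and spaces.
#'
#' @param name Locus name, non-empty string; unique within a project after
#'   alias folding.
#' @param aliases Character vector of synonyms (may be empty).
#' @param feature_type GenBank feature type the locus is harvested from,
#'   e.g. `"CDS"`, `"rRNA"`, `"gene"`, `"tRNA"`.
#' @param char_type `"dna"` or `"protein"`.
#' @return An object of class `pc_locus`.
#' @examples
#' locus("coi", aliases = c("cox1", "COI"), feature_type = "CDS")
#' @export
locus <- function(name, aliases = character(), feature_type = "gene",
                  char_type = c("dna", "protein")) {
  char_type <- match.arg(char_type)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("locus name must be a non-empty string", call. = FALSE)
  structure(
    list(name = name,
         aliases = unique(as.character(aliases)),
         feature_type = feature_type,
         char_type = char_type),
    class = "pc_locus")
}

#' @export
print.pc_locus <- function(x, ...) {
  cat(sprintf("<locus %s> type=%s chars=%s aliases=[%s]\n",
              x$name, x$feature_type, x$char_type,
              paste(x$aliases, collapse = ", ")))
  invisible(x)
}

#' Fold a locus name or alias to its canonical comparison key
#'
#' Lower-case, with underscores, hyphens, dots and spaces removed.
#'
#' @param x Character vector of names.
#' @return Character vector of folded keys.
#' @export
fold_name <- function(x) {
  gsub("[-_. ]", "", tolower(as.character(x)))
}

# All folded keys (name + aliases) claimed by one locus.
locus_keys <- function(loc) unique(fold_name(c(loc$name, loc$aliases)))

# Validate a list of pc_locus for name/alias collisions; returns the list
# named by locus name or stops with a message naming both offenders.
check_locus_set <- function(loci) {
  if (length(loci) == 0L) return(stats::setNames(list(), character()))
  stopifnot(all(vapply(loci, inherits, logical(1), "pc_locus")))
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(names(loci)))
    stop("duplicate locus name: ", names(loci)[duplicated(names(loci))][1],
         call. = FALSE)
  claimed <- character()   # folded key -> locus name
  owners  <- character()
  for (loc in loci) {
    for (k in locus_keys(loc)) {
      hit <- match(k, claimed)
      if (!is.na(hit) && owners[hit] != loc$name)
        stop(sprintf(
          "locus name/alias collision: '%s' of locus '%s' folds to the same key as locus '%s'",
          k, loc$name, owners[hit]), call. = FALSE)
      claimed <- c(claimed, k)
      owners  <- c(owners, loc$name)
    }
  }
  loci
}

# Resolve a user-supplied name through alias folding to a project locus name,
# or NA if no locus claims it.
resolve_locus <- function(project, name) {
  key <- fold_name(name)
  for (loc in project$loci)
    if (key %in% locus_keys(loc)) return(loc$name)
  NA_character_
}
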