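# Per-locus alignment and sequence statistics, and the parameter-gradient
# machinery built on them: sorting loci by a summary statistic, slicing a
# supermatrix recipe out of a statistic interval, and sliding fixed-width
# windows along the gradient.

PC_STATISTICS <- c("entropy", "gap_score", "conservation", "length", "gc")
PC_SUMMARIES  <- c("median", "p25", "p75")

alphabet_of <- function(char_type) {
  if (char_type == "protein") strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  else c("A", "C", "G", "T")
}

#' Shannon entropy of one alignment column
#'
#' SE = -sum p_i log2(p_i) over the frequencies p_i of the unambiguous,
#' non-gap residues in the column. Gap characters (`-`, `?`, `.`) and
#' ambiguity codes are ignored; a column with no unambiguous residue has no
#' defined entropy and returns `NA` (not 0), so all-gap columns never drag
#' summaries down.
#'
#' @param column Residues of one column, as a single string or a character
#'   vector of single characters.
#' @param char_type `"dna"` (alphabet ACGT, SE <= 2 bits) or `"protein"`
#'   (20 states, SE <= log2 20).
#' @return Entropy in bits, or `NA`.
#' @examples
#' column_entropy("AAAA")   # 0
#' column_entropy("ACGT")   # 2
#' column_entropy("AAAG-")  # 0.8112781
#' @export
column_entropy <- function(column, char_type = "dna") {
  chars <- if (length(column) == 1L) strsplit(column, "")[[1]] else column
  chars <- toupper(chars)
  counts <- table(factor(chars, levels = alphabet_of(char_type)))
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  p <- counts[counts > 0] / n
  -sum(p * log2(p)) + 0   # + 0 normalizes IEEE negative zero
}

# Five-number summary with Tukey 1.5*IQR whiskers. Linear interpolation
# between order statistics (quantile type 7) so summaries are
# bit-reproducible. When the box has null range the whiskers are null too.
five_number <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(list(p25 = NA_real_, median = NA_real_, p75 = NA_real_,
                whisker_low = NA_real_, whisker_high = NA_real_))
  q <- unname(stats::quantile(x, c(.25, .5, .75), type = 7))
  iqr <- q[3] - q[1]
  if (iqr == 0) {
    wl <- wh <- q[2]
  } else {
    wl <- min(x[x >= q[1] - 1.5 * iqr])
    wh <- max(x[x <= q[3] + 1.5 * iqr])
  }
  list(p25 = q[1], median = q[2], p75 = q[3],
       whisker_low = wl, whisker_high = wh)
}

#' Compute the statistics of one alignment
#'
#' Five statistic families: per-column Shannon entropy (bits, gaps and
#' ambiguity codes ignored), per-column gap score (fraction of rows with a
#' non-gap character; 1 = gap-free), per-column conservation (frequency of
#' the modal unambiguous residue among unambiguous residues), per-record
#' ungapped length, and per-record GC content. Each family carries a
#' five-number box/whisker summary (25/50/75 percentiles, 1.5*IQR whiskers).
#'
#' @param aln A `pc_alignment`.
#' @param char_type `"dna"` or `"protein"`.
#' @return A `pc_locus_stats` object.
#' @export
compute_locus_stats <- function(aln, char_type = "dna") {
  stopifnot(inherits(aln, "pc_alignment"), length(aln$rows) > 0L)
  m <- aln_matrix(aln)
  alpha <- alphabet_of(char_type)
  counts <- vapply(alpha, function(a) colSums(m == a),
                   numeric(ncol(m)))                      # ncol x |alpha|
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, alpha))
  tot <- rowSums(counts)
  p <- counts / ifelse(tot == 0, NA_real_, tot)
  plogp <- ifelse(is.na(p) | p == 0, 0, p * log2(p))
  entropy <- ifelse(tot == 0, NA_real_, -rowSums(plogp) + 0)  # +0: no -0
  gap_score <- colMeans(!matrix(m %in% GAP_CHARS, nrow(m), ncol(m)))
  conservation <- ifelse(tot == 0, NA_real_,
                         apply(counts, 1L, max) / ifelse(tot == 0, NA, tot))
  lens <- nchar(degap(unname(aln$rows)))
  gc <- gc_content(unname(aln$rows))
  values <- list(entropy = unname(entropy),
                 gap_score = unname(gap_score),
                 conservation = unname(conservation),
                 length = lens, gc = gc)
  structure(
    list(locus_name = aln$locus_name,
         source_alignment = aln$object_id,
         n_rows = length(aln$rows), n_columns = ncol(m),
         column_entropy = values$entropy,
         column_gap_score = values$gap_score,
         column_conservation = values$conservation,
         record_lengths = lens, record_gc = gc,
         summaries = lapply(values, five_number)),
    class = "pc_locus_stats")
}

#' @export
print.pc_locus_stats <- function(x, ...) {
  cat(sprintf("<locus stats %s> %d rows x %d columns; median entropy %.3f bits\n",
              x$locus_name, x$n_rows, x$n_columns, x$summaries$entropy$median))
  invisible(x)
}

#' Compute statistics for every selected locus
#'
#' @param project A `pc_project` with alignments for the selected loci.
#' @param use_trimmed Use the trimmed alignment when one exists.
#' @return Updated project with `project$stats` filled; [op_result()] lists
#'   the loci processed.
#' @export
compute_stats <- function(project, use_trimmed = FALSE) {
  done <- character()
  for (ln in project$selection) {
    aln <- locus_alignment(project, ln, prefer_trimmed = use_trimmed)
    if (is.null(aln)) next
    project$stats[[ln]] <- compute_locus_stats(aln, project$loci[[ln]]$char_type)
    done <- c(done, ln)
  }
  project <- pc_log(project, "compute_stats",
                    parameters = list(loci = done, use_trimmed = use_trimmed))
  with_result(project, done)
}

# latest alignment (or trimmed alignment) of a locus, by registration order
locus_alignment <- function(project, locus_name, prefer_trimmed = TRUE) {
  pick <- function(bin) {
    hits <- Filter(function(a) a$locus_name == locus_name, bin)
    if (length(hits)) hits[[length(hits)]] else NULL
  }
  if (prefer_trimmed) pick(project$trimmed) %||% pick(project$alignments)
  else pick(project$alignments)
}

locus_summary <- function(project, locus_name, statistic, summary) {
  st <- project$stats[[locus_name]]
  if (is.null(st))
    stop("no statistics computed for locus '", locus_name,
         "'; run compute_stats() first", call. = FALSE)
  st$summaries[[statistic]][[summary]]
}

#' Order the selected loci along a statistic gradient
#'
#' Ties are broken by locus name (lexicographic) so the order is total and
#' deterministic.
#'
#' @param project A `pc_project` with stats computed.
#' @param statistic One of `"entropy"`, `"gap_score"`, `"conservation"`,
#'   `"length"`, `"gc"`.
#' @param summary Which summary to sort on: `"median"`, `"p25"` or `"p75"`.
#' @param order `"desc"` (default: highest first) or `"asc"`.
#' @return Character vector of locus names in sorted order.
#' @export
sort_loci <- function(project, statistic = "entropy", summary = "median",
                      order = c("desc", "asc")) {
  statistic <- match.arg(statistic, PC_STATISTICS)
  summary <- match.arg(summary, PC_SUMMARIES)
  order <- match.arg(order)
  loci <- project$selection
  vals <- vapply(loci, locus_summary, numeric(1),
                 project = project, statistic = statistic, summary = summary)
  o <- base::order(if (order == "desc") -vals else vals, loci)
  loci[o]
}

#' Per-locus box-plot numbers
#'
#' The exact five-number summaries any rendering of the per-locus statistic
#' distributions would draw.
#'
#' @inheritParams sort_loci
#' @return Data frame: `locus`, `p25`, `median`, `p75`, `whisker_low`,
#'   `whisker_high`.
#' @export
boxplot_data <- function(project, statistic = "entropy") {
  statistic <- match.arg(statistic, PC_STATISTICS)
  rows <- lapply(project$selection, function(ln) {
    st <- project$stats[[ln]]
    if (is.null(st))
      stop("no statistics computed for locus '", ln, "'", call. = FALSE)
    s <- st$summaries[[statistic]]
    data.frame(locus = ln, p25 = s$p25, median = s$median, p75 = s$p75,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Slice a supermatrix recipe out of a statistic interval
#'
#' Selects exactly the loci whose summary statistic lies in `[min, max]`
#' and registers them as a named [Concatenation][concatenation] recipe.
#' An empty selection is an error (the bounds are reported), never an empty
#' supermatrix.
#'
#' @inheritParams sort_loci
#' @param min,max Inclusive bounds on the summary statistic.
#' @param name Recipe name; default derived from the bounds.
#' @param rules Occupancy rules passed to [concatenation()].
#' @return Updated project; [op_result()] is the new `pc_concatenation`.
#' @export
slice_loci <- function(project, statistic = "entropy", summary = "median",
                       min = -Inf, max = Inf, name = NULL, rules = NULL) {
  statistic <- match.arg(statistic, PC_STATISTICS)
  summary <- match.arg(summary, PC_SUMMARIES)
  if (min > max) stop("slice bounds: min > max", call. = FALSE)
  vals <- vapply(project$selection, locus_summary, numeric(1),
                 project = project, statistic = statistic, summary = summary)
  inside <- project$selection[!is.na(vals) & vals >= min & vals <= max]
  if (length(inside) == 0L) {
    obs <- if (any(!is.na(vals)))
      sprintf("; observed range is [%g, %g]",
              base::min(vals, na.rm = TRUE), base::max(vals, na.rm = TRUE))
    else ""
    stop(sprintf("no locus has %s %s in [%g, %g]%s",
                 summary, statistic, min, max, obs), call. = FALSE)
  }
  if (is.null(name))
    name <- sprintf("slice_%s_%g_%g", statistic, min, max)
  conc <- concatenation(name, inside, otu_field = project$otu_field,
                        rules = rules)
  project$concatenations[[name]] <- conc
  project <- pc_log(project, "slice",
    parameters = list(statistic = statistic, summary = summary,
                      min = min, max = max, loci = inside),
    outputs = name)
  with_result(project, conc)
}

#' Sliding-window supermatrix recipes along a statistic gradient
#'
#' Sorts the selected loci by the chosen summary statistic and cuts
#' fixed-width windows: window k holds the sorted loci at positions
#' `k*step + 1 ... k*step + width`, for k = 0 ... floor((n-width)/step).
#' Every window has exactly `width` loci; a trailing remainder that cannot
#' fill a window is omitted so all windows are comparable. Each window is
#' registered as a Concatenation named `<prefix>_k`.
#'
#' @inheritParams sort_loci
#' @param width Window width in loci.
#' @param step Window step in loci.
#' @param prefix Name prefix for the window recipes.
#' @param rules Occupancy rules passed to [concatenation()].
#' @return Updated project; [op_result()] is the ordered list of
#'   `pc_concatenation` windows.
#' @export
slide_loci <- function(project, statistic = "entropy", summary = "median",
                       width, step, order = c("desc", "asc"),
                       prefix = "win", rules = NULL) {
  statistic <- match.arg(statistic, PC_STATISTICS)
  summary <- match.arg(summary, PC_SUMMARIES)
  order <- match.arg(order)
  n <- length(project$selection)
  if (width < 1L || width > n)
    stop("window width ", width, " invalid for ", n, " selected loci",
         call. = FALSE)
  if (step < 1L) stop("window step must be >= 1", call. = FALSE)
  sorted <- sort_loci(project, statistic, summary, order)
  ks <- 0:((n - width) %/% step)
  wins <- lapply(ks, function(k) {
    nm <- sprintf("%s_%d", prefix, k)
    concatenation(nm, sorted[(k * step + 1):(k * step + width)],
                  otu_field = project$otu_field, rules = rules)
  })
  names(wins) <- vapply(wins, `[[`, character(1), "name")
  for (w in wins) project$concatenations[[w$name]] <- w
  project <- pc_log(project, "slide",
    parameters = list(statistic = statistic, summary = summary,
                      width = width, step = step, order = order,
                      n_loci = n, n_windows = length(wins)),
    outputs = names(wins))
  with_result(project, wins)
}

#' Rank-correlation diagnostic between two per-locus statistics
#'
#' Spearman rank correlation between the per-locus summaries of two
#' statistics, e.g. entropy vs GC content or entropy vs gap score, used to
#' check that the sorting statistic is not confounded by composition or
#' missing data. Loci with a missing summary on either side are dropped
#' pairwise; a constant side makes the correlation undefined (`NA`), never 0.
#'
#' @param project A `pc_project` with stats computed.
#' @param statistic_a,statistic_b The two statistics to compare.
#' @param summary Summary to use for both sides.
#' @return `list(rho, n)`; `rho` is `NA` when undefined.
#' @export
bias_diagnostic <- function(project, statistic_a, statistic_b,
                            summary = "median") {
  statistic_a <- match.arg(statistic_a, PC_STATISTICS)
  statistic_b <- match.arg(statistic_b, PC_STATISTICS)
  a <- vapply(project$selection, locus_summary, numeric(1),
              project = project, statistic = statistic_a, summary = summary)
  b <- vapply(project$selection, locus_summary, numeric(1),
              project = project, statistic = statistic_b, summary = summary)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    stop("bias_diagnostic needs summaries for at least 3 loci", call. = FALSE)
  rho <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
         else stats::cor(a, b, method = "spearman")
  list(rho = rho, n = length(a))
}

#' Export the per-locus statistics table as TSV
#'
#' @param project A `pc_project` with stats computed.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_stats_table <- function(project, path) {
  rows <- lapply(PC_STATISTICS, function(st) {
    df <- boxplot_data(project, st)
    df$statistic <- st
    df
  })
  df <- do.call(rbind, rows)
  utils::write.table(df[, c("locus", "statistic", "p25", "median", "p75",
                            "whisker_low", "whisker_high")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
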