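# Analysis stages: alignment, trimming and tree reconstruction, with batch
# semantics over the selected loci and pluggable external-tool adapters.
# Native methods (pass-through/pad alignment, gap-threshold trimmer,
# neighbor joining) make the whole pipeline runnable with no external
# binaries; adapters for MAFFT-style tools are configuration, not code.

#' Configure an analysis stage
#'
#' @param stage `"align"`, `"trim"` or `"tree"`.
#' @param method Native method name (`"asis"`, `"pad"`, `"gt"`, `"nj"`) or
#'   the name of a registered adapter.
#' @param params Named list of method parameters.
#' @param scope Optional locus names / object ids the batch is limited to.
#' @return A `pc_conf`.
#' @export
stage_conf <- function(stage = c("align", "trim", "tree"), method,
                       params = list(), scope = NULL) {
  stage <- match.arg(stage)
  structure(list(stage = stage, method = method, params = params,
                 scope = scope),
            class = "pc_conf")
}

# ---- alignment --------------------------------------------------------------

#' Align all unaligned selected loci (batch)
#'
#' One call aligns every in-scope locus that has records but no alignment
#' yet; loci already aligned are left alone, so repeated calls are no-ops.
#' Native methods: `"asis"` registers equal-length sequences as already
#' aligned (the usual case for curated or simulated input); `"pad"`
#' right-pads ragged sequences with gaps to equal length (a placeholder, not
#' a real aligner). Any registered `align`-stage adapter name runs the
#' external tool instead.
#'
#' @param project A `pc_project`.
#' @param conf A [stage_conf()]; default `asis`.
#' @return Updated project; [op_result()] is the vector of new alignment ids.
#' @export
align_loci <- function(project, conf = stage_conf("align", "asis")) {
  stopifnot(conf$stage == "align")
  if (!(conf$method %in% c("asis", "pad")))
    return(run_external(project, conf))
  scope <- conf$scope %||% project$selection
  scope <- vapply(scope, function(nm) resolve_locus(project, nm), character(1))
  aligned_already <- vapply(project$alignments, `[[`, character(1), "locus_name")
  pid <- next_process_id(project, "align")
  new_ids <- character()
  pending <- list()
  for (ln in scope) {
    if (ln %in% aligned_already) next
    recs <- records_of_locus(project, ln)
    if (length(recs) == 0L) next
    seqs <- stats::setNames(vapply(recs, `[[`, character(1), "sequence"),
                            names(recs))
    if (conf$method == "pad") {
      w <- max(nchar(seqs))
      seqs <- paste0(seqs, strrep("-", w - nchar(seqs)))
      names(seqs) <- names(recs)
    } else if (length(unique(nchar(seqs))) > 1L) {
      stop("locus '", ln, "' has unequal sequence lengths; method 'asis' ",
           "needs pre-aligned input (use an aligner adapter or 'pad')",
           call. = FALSE)
    }
    id <- paste0(ln, "@", pid)
    pending[[id]] <- new_alignment(id, ln, seqs, produced_by = pid)
    new_ids <- c(new_ids, id)
  }
  if (length(new_ids) == 0L)
    warning("align: no unaligned locus in scope; nothing to do")
  for (id in names(pending))
    project <- register_alignment(project, pending[[id]])
  project <- pc_log(project, "align",
    parameters = list(method = conf$method, scope = unname(scope)),
    outputs = new_ids,
    tool = paste0("phylocrate:", conf$method, " ", pc_version()))
  with_result(project, new_ids)
}

# ---- trimming ---------------------------------------------------------------

# Pure column filter: keep columns whose non-gap fraction is >= gt.
trim_alignment <- function(aln, gt, object_id = paste0(aln$object_id, "_gt", gt),
                           produced_by = NA_character_) {
  stopifnot(gt >= 0, gt <= 1)
  m <- aln_matrix(aln)
  nongap <- colMeans(!matrix(m %in% GAP_CHARS, nrow(m), ncol(m)))
  keep <- nongap >= gt
  if (!any(keep))
    stop("trimming at gap threshold ", gt, " removes every column of '",
         aln$object_id, "'; lower the threshold", call. = FALSE)
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(
    list(object_id = object_id, locus_name = aln$locus_name,
         rows = stats::setNames(rows, names(aln$rows)),
         length = sum(keep), produced_by = produced_by,
         kept_columns = which(keep)),
    class = "pc_alignment")
}

#' Trim alignments by gap threshold (batch)
#'
#' The native trimmer keeps exactly the columns whose fraction of non-gap
#' characters is at least `gt`, preserving column order. `gt = 0` keeps
#' everything; `gt = 1` keeps only gap-free columns; kept-column sets shrink
#' monotonically as `gt` grows. Trimmed alignments are registered alongside
#' (never replacing) their sources; note the trimmed rows no longer de-gap
#' to the full record sequence, which is why they live in their own bin.
#'
#' @param project A `pc_project`.
#' @param gt Non-gap fraction threshold in \[0, 1\].
#' @param scope Alignment ids or locus names; default all alignments of
#'   selected loci.
#' @return Updated project; [op_result()] is the vector of trimmed ids.
#' @export
trim_loci <- function(project, gt, scope = NULL) {
  stopifnot(is.numeric(gt), gt >= 0, gt <= 1)
  alns <- if (is.null(scope)) {
    Filter(function(a) a$locus_name %in% project$selection, project$alignments)
  } else {
    found <- list()
    for (s in scope) {
      if (!is.null(project$alignments[[s]])) found[[s]] <- project$alignments[[s]]
      else {
        ln <- resolve_locus(project, s)
        if (is.na(ln)) stop("trim scope '", s, "' matches nothing", call. = FALSE)
        a <- locus_alignment(project, ln, prefer_trimmed = FALSE)
        if (!is.null(a)) found[[a$object_id]] <- a
      }
    }
    found
  }
  pid <- next_process_id(project, "trim")
  new_ids <- character()
  for (aln in alns) {
    id <- paste0(aln$locus_name, "@", pid)
    tr <- trim_alignment(aln, gt, object_id = id, produced_by = pid)
    project$trimmed[[id]] <- tr
    new_ids <- c(new_ids, id)
  }
  project <- pc_log(project, "trim",
    parameters = list(gt = gt, scope = scope),
    inputs = vapply(alns, `[[`, character(1), "object_id"),
    outputs = new_ids,
    tool = paste0("phylocrate:gap-threshold ", pc_version()))
  with_result(project, new_ids)
}

# ---- distances + neighbor joining ------------------------------------------

# Pairwise distances between gapped sequences. Sites where either sequence
# has a gap or ambiguity code are skipped pairwise. JC69 is undefined at
# p >= 3/4 (the correction diverges); the offending pair is named.
seq_distance_matrix <- function(rows, model = c("p", "JC69"),
                                char_type = "dna") {
  model <- match.arg(model)
  alpha <- alphabet_of(char_type)
  m <- do.call(rbind, strsplit(unname(toupper(rows)), ""))
  valid <- matrix(m %in% alpha, nrow(m), ncol(m))
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok))
      stop("no comparable sites between '", names(rows)[i], "' and '",
           names(rows)[j], "'", call. = FALSE)
    p <- mean(m[i, ok] != m[j, ok])
    if (model == "JC69") {
      if (p >= 0.75)
        stop("JC69 distance undefined for pair '", names(rows)[i], "' / '",
             names(rows)[j], "' (p = ", signif(p, 3), " >= 3/4)", call. = FALSE)
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

# Clamp negative NJ branch lengths to zero, moving the deficit onto the
# sibling branch so path lengths through the parent are preserved.
clamp_negative_edges <- function(phylo) {
  if (is.null(phylo$edge.length)) return(phylo)
  repeat {
    neg <- which(phylo$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1]
    parent <- phylo$edge[e, 1]
    sibs <- setdiff(which(phylo$edge[, 1] == parent), e)
    deficit <- -phylo$edge.length[e]
    phylo$edge.length[e] <- 0
    if (length(sibs))
      phylo$edge.length[sibs[1]] <- phylo$edge.length[sibs[1]] + deficit
  }
  phylo
}

#' Neighbor-joining tree from an alignment or supermatrix
#'
#' Native tree builder so the full pipeline runs without external programs:
#' pairwise p- or JC69 distances (pairwise deletion of gap/ambiguous sites)
#' followed by neighbor joining (ape). Negative branch lengths are clamped
#' to zero with the deficit transferred to the sibling branch. Tip labels
#' are record ids (alignment input) or OTUs (supermatrix input); `leaf_map`
#' records the mapping.
#'
#' @param project A `pc_project`.
#' @param id Alignment / trimmed-alignment id or supermatrix name.
#' @param model `"p"` or `"JC69"` for DNA; protein data uses `"p"`.
#' @return Updated project; [op_result()] is the new `pc_tree`.
#' @export
nj_tree <- function(project, id, model = c("p", "JC69")) {
  model <- match.arg(model)
  obj <- project$supermatrices[[id]] %||% project$alignments[[id]] %||%
    project$trimmed[[id]]
  if (is.null(obj))
    stop("'", id, "' is not an alignment or supermatrix", call. = FALSE)
  if (inherits(obj, "pc_alignment")) {
    rows <- obj$rows
    char_type <- project$loci[[obj$locus_name]]$char_type
    leaf_map <- stats::setNames(names(rows), names(rows))
  } else if (inherits(obj, "pc_supermatrix")) {
    rows <- obj$rows
    char_type <- "dna"
    leaf_map <- stats::setNames(names(rows), names(rows))
  } else stop("'", id, "' is not an alignment or supermatrix", call. = FALSE)
  if (length(rows) < 3L)
    stop("neighbor joining needs at least 3 sequences", call. = FALSE)
  if (char_type == "protein" && model != "p")
    stop("protein data supports the p distance only", call. = FALSE)
  rows <- rows[order(names(rows))]   # deterministic join order on ties
  d <- seq_distance_matrix(rows, model, char_type)
  phylo <- clamp_negative_edges(ape::nj(stats::as.dist(d)))
  pid <- next_process_id(project, "nj_tree")
  tid <- paste0(id, "@", pid)
  tr <- new_tree(tid, phylo, leaf_map, produced_by = pid)
  project$trees[[tid]] <- tr
  project <- pc_log(project, "nj_tree",
    parameters = list(source = id, model = model),
    inputs = id, outputs = tid,
    tool = paste0("ape::nj ", as.character(utils::packageVersion("ape"))))
  with_result(project, tr)
}

# ---- external-tool adapters -------------------------------------------------

#' Register an external-tool adapter
#'
#' An adapter binds a stage to a shell command template with `{in}`, `{out}`
#' and `{params}` placeholders, plus a version-probe command whose first
#' output line is stored in the ledger whenever the adapter runs. Input is
#' written as FASTA; output is parsed back per stage (`align`/`trim`: FASTA
#' alignment; `tree`: Newick).
#'
#' @param project A `pc_project`.
#' @param name Adapter name (used as `method` in [stage_conf()]).
#' @param stage `"align"`, `"trim"` or `"tree"`.
#' @param command Command template, e.g.
#'   `"mafft --auto {params} {in} > {out}"`.
#' @param version_probe Command printing the tool version, e.g.
#'   `"mafft --version 2>&1"`.
#' @param params Default `{params}` substitution.
#' @return Updated project.
#' @export
register_adapter <- function(project, name, stage, command, version_probe,
                             params = "") {
  project$adapters[[name]] <- list(name = name, stage = stage,
                                   command = command,
                                   version_probe = version_probe,
                                   params = params)
  project <- pc_log(project, "register_adapter",
    parameters = list(name = name, stage = stage, command = command))
  with_result(project, name)
}

probe_adapter <- function(adapter) {
  out <- tryCatch(
    suppressWarnings(system(adapter$version_probe, intern = TRUE)),
    error = function(e) NULL)
  if (is.null(out) || length(out) == 0L)
    stop("adapter '", adapter$name,
         "' failed its version probe; is the tool installed?", call. = FALSE)
  trimws(out[1])
}

run_adapter_once <- function(adapter, in_file, out_file, params, workdir) {
  cmd <- adapter$command
  cmd <- gsub("{in}", shQuote(in_file), cmd, fixed = TRUE)
  cmd <- gsub("{out}", shQuote(out_file), cmd, fixed = TRUE)
  cmd <- gsub("{params}", params, cmd, fixed = TRUE)
  log_file <- file.path(workdir, "stderr.log")
  status <- system(paste0(cmd, " 2> ", shQuote(log_file)))
  if (status != 0L)
    stop("adapter '", adapter$name, "' exited with status ", status, ":\n",
         paste(readLines(log_file, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  if (!file.exists(out_file))
    stop("adapter '", adapter$name, "' produced no output file (kept: ",
         workdir, ")", call. = FALSE)
}

#' Run an external tool over the batch scope
#'
#' Probes the tool version first (configuration errors surface before any
#' mutation), writes inputs, runs the command per in-scope dataset, parses
#' outputs back into the project, and records the tool version in the
#' ledger entry.
#'
#' @param project A `pc_project` with the adapter registered.
#' @param conf A [stage_conf()] whose `method` names the adapter.
#' @return Updated project; [op_result()] is the vector of new object ids.
#' @export
run_external <- function(project, conf) {
  adapter <- project$adapters[[conf$method]]
  if (is.null(adapter))
    stop("no adapter named '", conf$method, "' is registered", call. = FALSE)
  if (adapter$stage != conf$stage)
    stop("adapter '", conf$method, "' is for stage '", adapter$stage, "'",
         call. = FALSE)
  version <- probe_adapter(adapter)
  params <- conf$params$params %||% adapter$params
  workdir <- tempfile(paste0("phylocrate_", adapter$name, "_"))
  dir.create(workdir)
  op <- paste0("external_", conf$stage)
  pid <- next_process_id(project, op)
  new_ids <- character(); in_ids <- character()
  pending <- list()

  if (conf$stage == "align") {
    scope <- conf$scope %||% project$selection
    aligned_already <- vapply(project$alignments, `[[`, character(1), "locus_name")
    for (ln in scope) {
      ln <- resolve_locus(project, ln)
      if (ln %in% aligned_already) next
      recs <- records_of_locus(project, ln)
      if (length(recs) == 0L) next
      in_f <- file.path(workdir, paste0(ln, ".in.fasta"))
      out_f <- file.path(workdir, paste0(ln, ".out.fasta"))
      write_fasta_named(
        stats::setNames(vapply(recs, `[[`, character(1), "sequence"),
                        names(recs)), in_f)
      run_adapter_once(adapter, in_f, out_f, params, workdir)
      rows <- read_fasta_named(out_f)
      missing <- setdiff(names(recs), names(rows))
      if (length(missing))
        stop("adapter output lacks sequences for: ",
             paste(missing, collapse = ", "), " (kept: ", workdir, ")",
             call. = FALSE)
      id <- paste0(ln, "@", pid)
      pending[[id]] <- new_alignment(id, ln, toupper(rows[names(recs)]),
                                     produced_by = pid)
      new_ids <- c(new_ids, id)
    }
    for (id in names(pending)) project <- register_alignment(project, pending[[id]])
  } else if (conf$stage == "tree") {
    scope <- conf$scope %||% names(project$alignments)
    for (aid in scope) {
      aln <- fetch(project, aid)
      in_f <- file.path(workdir, "in.fasta")
      out_f <- file.path(workdir, "out.nwk")
      write_fasta_named(aln$rows, in_f)
      run_adapter_once(adapter, in_f, out_f, params, workdir)
      phylo <- tryCatch(ape::read.tree(out_f), error = function(e) NULL)
      if (is.null(phylo))
        stop("adapter output is not parseable Newick (kept: ", out_f, ")",
             call. = FALSE)
      tid <- paste0(aid, "@", pid)
      project$trees[[tid]] <- new_tree(
        tid, phylo, stats::setNames(phylo$tip.label, phylo$tip.label),
        produced_by = pid)
      new_ids <- c(new_ids, tid)
      in_ids <- c(in_ids, aid)
    }
  } else stop("external trimming adapters are configured like aligners; ",
              "use stage 'align' with a trimmed-FASTA-emitting command",
              call. = FALSE)

  project <- pc_log(project, op,
    parameters = list(adapter = adapter$name, command = adapter$command,
                      params = params, scope = conf$scope),
    inputs = in_ids, outputs = new_ids,
    tool = paste0(adapter$name, " ", version))
  with_result(project, new_ids)
}
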