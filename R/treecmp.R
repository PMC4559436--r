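# Tree comparison over bipartitions, and metadata-driven rooting/annotation.
#
# A bipartition (split) is the 2-set partition of the leaf labels induced by
# removing one branch; it is invariant under re-rooting, so every metric
# here unroots its inputs first. Trivial splits (one leaf | rest) carry no
# topological information and are excluded from RF; their branch lengths
# (pendant branches) still contribute to the branch-score distance, as the
# metric is defined over all branches.

# Splits of a tree: data frame (key, trivial, length). Keys are canonical:
# the sorted labels of the side NOT containing the lexicographically
# smallest leaf, joined with "|".
tree_splits <- function(tree) {
  phylo <- ape::unroot(as_phylo(tree))
  ntip <- length(phylo$tip.label)
  ord <- stats::reorder(phylo, "postorder")
  below <- vector("list", ntip + phylo$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  edges <- ord$edge
  lens <- ord$edge.length %||% rep(NA_real_, nrow(edges))
  for (e in seq_len(nrow(edges)))
    below[[edges[e, 1]]] <- c(below[[edges[e, 1]]], below[[edges[e, 2]]])
  labels <- phylo$tip.label
  ref <- sort(labels)[1]
  rows <- lapply(seq_len(nrow(edges)), function(e) {
    side <- labels[below[[edges[e, 2]]]]
    if (ref %in% side) side <- setdiff(labels, side)
    size <- length(side)
    data.frame(key = paste(sort(side), collapse = "|"),
               trivial = min(size, ntip - size) <= 1L,
               length = lens[e], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # collapse duplicate keys (possible around multifurcations), summing lengths
  if (anyDuplicated(out$key)) {
    agg <- stats::aggregate(length ~ key + trivial, data = out, FUN = sum,
                            na.action = stats::na.pass)
    out <- agg
  }
  out
}

check_same_leaves <- function(t1, t2) {
  l1 <- as_phylo(t1)$tip.label
  l2 <- as_phylo(t2)$tip.label
  d <- c(setdiff(l1, l2), setdiff(l2, l1))
  if (length(d))
    stop("trees have different leaf sets; symmetric difference: ",
         paste(sort(d), collapse = ", "), call. = FALSE)
}

#' Robinson-Foulds symmetric distance
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees. 0 iff the unrooted topologies are identical; at most 2(n-3) for
#' two binary trees on n leaves. Branch lengths and support values are
#' ignored. Multifurcating trees are allowed.
#'
#' @param t1,t2 `pc_tree` or ape `phylo` objects on the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  k1 <- s1$key[!s1$trivial]; k2 <- s2$key[!s2$trivial]
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

split_length_map <- function(splits, include_pendant) {
  s <- if (include_pendant) splits else splits[!splits$trivial, , drop = FALSE]
  stats::setNames(s$length, s$key)
}

#' Branch-score distance
#'
#' The square root of the sum of squared branch-length differences over the
#' union of bipartitions of the two trees, a branch absent from a tree
#' contributing length 0. Pendant branches are included by default (the
#' metric is defined over all branches); set `include_pendant = FALSE` to
#' restrict to internal branches.
#'
#' @inheritParams rf_distance
#' @param include_pendant Include pendant (leaf) branches.
#' @return Non-negative number.
#' @export
branch_score <- function(t1, t2, include_pendant = TRUE) {
  check_same_leaves(t1, t2)
  for (t in list(t1, t2))
    if (is.null(as_phylo(t)$edge.length))
      stop("branch_score needs branch lengths on both trees", call. = FALSE)
  b1 <- split_length_map(tree_splits(t1), include_pendant)
  b2 <- split_length_map(tree_splits(t2), include_pendant)
  keys <- union(names(b1), names(b2))
  v1 <- ifelse(keys %in% names(b1), b1[keys], 0)
  v2 <- ifelse(keys %in% names(b2), b2[keys], 0)
  sqrt(sum((v1 - v2)^2))
}

rescale_to_unit_length <- function(tree) {
  phylo <- as_phylo(tree)
  tl <- sum(phylo$edge.length)
  if (is.null(phylo$edge.length) || tl <= 0)
    stop("standardized branch score needs a tree of positive total length",
         call. = FALSE)
  phylo$edge.length <- phylo$edge.length / tl
  phylo
}

#' Rate-standardized branch-score distance
#'
#' The branch-score distance after dividing every branch length in each
#' tree by that tree's total length, so trees differing only by a uniform
#' rate scaling compare as identical and the metric isolates relative
#' branch-length structure plus topology.
#'
#' @inheritParams branch_score
#' @return Non-negative number; 0 when one tree is a uniform rescaling of
#'   the other.
#' @export
standardized_branch_score <- function(t1, t2, include_pendant = TRUE) {
  branch_score(rescale_to_unit_length(t1), rescale_to_unit_length(t2),
               include_pendant = include_pendant)
}

#' Pairwise tree-distance matrix
#'
#' @param trees List of `pc_tree`/`phylo` objects with a shared leaf set,
#'   or a project (all its trees are used).
#' @param metric `"rf"`, `"branch_score"` or `"standardized_branch_score"`.
#' @param ... Passed to the metric (e.g. `include_pendant`).
#' @return Symmetric numeric matrix with tree ids as dimnames and zero
#'   diagonal, of class `pc_distance_matrix` (attribute `metric`).
#' @export
pairwise_matrix <- function(trees,
                            metric = c("rf", "branch_score",
                                       "standardized_branch_score"), ...) {
  metric <- match.arg(metric)
  if (inherits(trees, "pc_project")) trees <- trees$trees
  if (length(trees) < 2L) stop("need at least two trees", call. = FALSE)
  ids <- names(trees) %||% vapply(seq_along(trees), function(i) {
    if (inherits(trees[[i]], "pc_tree")) trees[[i]]$object_id
    else paste0("tree_", i)
  }, character(1))
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) names(trees) <- ids
  fun <- switch(metric, rf = rf_distance, branch_score = branch_score,
                standardized_branch_score = standardized_branch_score)
  n <- length(trees)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- tryCatch(fun(trees[[i]], trees[[j]], ...), error = function(e)
      stop("pair (", ids[i], ", ", ids[j], "): ", conditionMessage(e),
           call. = FALSE))
    m[i, j] <- m[j, i] <- v
  }
  structure(m, metric = metric, class = c("pc_distance_matrix", "matrix",
                                          "array"))
}

#' Write a distance matrix as TSV
#' @param m A matrix from [pairwise_matrix()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

# leaves of a tree whose mapped record matches a metadata predicate
match_leaves <- function(project, tree, ids = NULL, where = NULL) {
  labs <- as_phylo(tree)$tip.label
  hit <- vapply(labs, function(lab) {
    target <- tree$leaf_map[[lab]] %||% lab
    rec <- project$records[[target]] %||% project$excluded[[target]]
    if (!is.null(ids) && !(target %in% ids) && !(lab %in% ids)) return(FALSE)
    if (!is.null(where)) {
      if (is.null(rec)) {
        # otu-labelled leaf: allow matching on the otu field itself
        recs <- Filter(function(r) r$otu == target, project$records)
        rec <- if (length(recs)) recs[[1]] else NULL
      }
      if (is.null(rec)) return(FALSE)
      for (k in names(where)) {
        have <- if (k == "otu") rec$otu else rec$metadata[[k]]
        if (is.null(have) ||
            !identical(as.character(have), as.character(where[[k]])))
          return(FALSE)
      }
    }
    !is.null(ids) || !is.null(where)
  }, logical(1))
  labs[hit]
}

#' Root a tree on a metadata-defined outgroup and annotate its leaves
#'
#' The outgroup is every leaf whose record matches the selector; it must be
#' at least one leaf, fewer than all, and monophyletic in the unrooted tree.
#' The tree is rooted on the branch subtending the outgroup and each leaf
#' is annotated with the requested metadata fields (carried into PhyloXML
#' output). Rooting never changes the bipartition set.
#'
#' @param project A `pc_project`.
#' @param tree_id Id of a tree in the project.
#' @param ids,where Outgroup selector, as in [edit_metadata()].
#' @param fields Metadata keys to attach to each leaf.
#' @return Updated project; [op_result()] is the new rooted `pc_tree`.
#' @export
root_and_annotate <- function(project, tree_id, ids = NULL, where = NULL,
                              fields = character()) {
  tr <- fetch(project, tree_id)
  if (!inherits(tr, "pc_tree")) stop("'", tree_id, "' is not a tree", call. = FALSE)
  out <- match_leaves(project, tr, ids = ids, where = where)
  ntip <- length(tr$phylo$tip.label)
  if (length(out) == 0L)
    stop("outgroup selector matches no leaf", call. = FALSE)
  if (length(out) >= ntip)
    stop("outgroup selector matches every leaf", call. = FALSE)
  rooted <- tryCatch(
    ape::root(ape::unroot(tr$phylo), outgroup = out, resolve.root = TRUE),
    error = function(e)
      stop("outgroup is not monophyletic in the tree: ",
           paste(out, collapse = ", "), call. = FALSE))
  ann <- NULL
  if (length(fields)) {
    ann <- lapply(stats::setNames(nm = rooted$tip.label), function(lab) {
      target <- tr$leaf_map[[lab]] %||% lab
      rec <- project$records[[target]] %||% project$excluded[[target]]
      if (is.null(rec)) {
        recs <- Filter(function(r) r$otu == target, project$records)
        rec <- if (length(recs)) recs[[1]] else NULL
      }
      vals <- lapply(stats::setNames(nm = fields), function(k) {
        if (is.null(rec)) NA_character_
        else if (k == "otu") rec$otu
        else rec$metadata[[k]] %||% NA_character_
      })
      vals
    })
  }
  pid <- next_process_id(project, "root_and_annotate")
  tid <- paste0(tree_id, "@", pid)
  project$trees[[tid]] <- new_tree(tid, rooted, tr$leaf_map,
                                   produced_by = pid, annotations = ann)
  project <- pc_log(project, "root_and_annotate",
    parameters = list(tree = tree_id, ids = ids, where = where,
                      fields = fields, outgroup = out),
    inputs = tree_id, outputs = tid)
  with_result(project, project$trees[[tid]])
}
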