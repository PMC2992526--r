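#' Read and write Newick trees
#'
#' Thin, validating wrappers around the ape Newick parser/serializer. Trees
#' are `ape::phylo` objects throughout the package; internal-node labels
#' hold bootstrap supports (integers in \[0, 100\]) when present.
#'
#' @param source file path, or literal Newick text when `text = TRUE`.
#' @param text logical.
#' @return `read_newick`: a `phylo`. `write_newick`: the Newick string,
#'   invisibly when written to a path.
#' @export
read_newick <- function(source, text = FALSE) {
  tr <- tryCatch(
    if (text) ape::read.tree(text = source) else ape::read.tree(source),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop2("newick_parse_error", "malformed Newick input")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop2("newick_duplicate_error", "duplicate leaf label '%s'",
          tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    ok <- is.na(sup) | (sup >= 0 & sup <= 100)
    if (!all(ok)) {
      stop2("newick_support_error", "support values must lie in [0, 100]")
    }
  }
  tr
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @param path output path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Internal (non-trivial) bipartitions of an unrooted tree, each encoded as a
# canonical key: the sorted side not containing the reference leaf.
unrooted_splits <- function(tree, ref_labels = sort(tree$tip.label)) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs)
  keys <- character(0L)
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    # canonical side: the one not containing the alphabetically first leaf
    if (ref_labels[1L] %in% side) side <- setdiff(ref_labels, side)
    if (length(side) <= 1L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of internal bipartitions present in exactly one of the two
#' unrooted trees (trivial leaf splits excluded).
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop2("tree_leafset_error", "trees have different leaf sets")
  }
  # multifurcating trees are fine here (symmetric difference of splits);
  # silence phangorn's non-binary caution
  as.integer(suppressWarnings(
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                      check.labels = TRUE)))
}

#' Does a tree contain a clan?
#'
#' A clan is a group of leaves separated from all others by a single edge of
#' the unrooted tree (the unrooted analogue of a monophyletic group).
#'
#' @param tree a `phylo`.
#' @param leaves character vector: a proper, non-empty subset of the leaf
#'   set.
#' @return `TRUE` iff some edge induces exactly `{leaves, complement}`.
#' @export
contains_clan <- function(tree, leaves) {
  labs <- tree$tip.label
  if (length(leaves) == 0L || any(!leaves %in% labs)) {
    stop2("tree_clan_error", "leaves must be a non-empty subset of the leaf set")
  }
  if (length(leaves) >= length(labs)) {
    stop2("tree_clan_error", "leaves must be a proper subset of the leaf set")
  }
  if (length(leaves) == 1L || length(leaves) == length(labs) - 1L) {
    return(TRUE)  # pendant edge always induces a singleton clan
  }
  ref <- sort(labs)
  side <- sort(unique(leaves))
  if (ref[1L] %in% side) side <- setdiff(ref, side)
  key <- paste(sort(side), collapse = "\r")
  key %in% unrooted_splits(tree, ref)
}

#' Majority-rule consensus tree
#'
#' Contains exactly the bipartitions whose frequency among the input trees
#' strictly exceeds `threshold`; internal-node labels carry the support
#' `round(100 * frequency)`. Unresolved parts collapse to polytomies.
#'
#' @param trees a list of `phylo` objects (or `multiPhylo`) on one leaf set.
#' @param threshold fraction in \[0.5, 1); default 0.5 (strict majority).
#' @return a `phylo` with `node.label` supports.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  trees <- unclass(trees)
  if (length(trees) < 1L) stop2("tree_consensus_error", "need >= 1 tree")
  labs <- sort(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, labs)) {
      stop2("tree_leafset_error", "trees have different leaf sets")
    }
  }
  counts <- new.env(parent = emptyenv())
  for (t in trees) {
    for (k in unrooted_splits(t, labs)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / length(trees), numeric(1L))
  keep <- keys[freq > threshold]
  supp <- round(100 * freq[freq > threshold])
  build_tree_from_splits(labs, keep, supp)
}

# Build a phylo from a laminar family of splits. Each split key is the sorted
# side excluding labs[1]; splits from a strict-majority rule nest, so the
# smallest enclosing split is the parent.
build_tree_from_splits <- function(labs, keys, supports = NULL) {
  sides <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  ord <- order(lengths(sides), decreasing = TRUE)
  sides <- sides[ord]
  supports <- if (length(keys)) supports[ord]
  ntip <- length(labs)
  nnode <- length(sides) + 1L              # root (leaf 1 side) + one per split
  # node numbering: tips 1..ntip (alphabetical), internals ntip+1 (root), ...
  parent_of <- integer(ntip + nnode)       # 0 = unset
  root <- ntip + 1L
  # assign each leaf and each split node to the smallest containing split
  split_node <- ntip + 1L + seq_along(sides)
  container <- function(set) {
    # smallest split strictly containing `set`
    best <- root; bsize <- ntip
    for (j in seq_along(sides)) {
      s <- sides[[j]]
      if (length(s) > length(set) && all(set %in% s) && length(s) < bsize) {
        best <- split_node[j]; bsize <- length(s)
      } else if (length(s) == length(set) && !identical(sort(set), sort(s)) &&
                 all(set %in% s)) {
        best <- split_node[j]; bsize <- length(s)
      }
    }
    best
  }
  for (j in seq_along(sides)) parent_of[split_node[j]] <- container(sides[[j]])
  for (i in seq_len(ntip)) {
    if (labs[i] == labs[1L]) { parent_of[i] <- root; next }
    # smallest split containing this single leaf
    best <- root; bsize <- ntip
    for (j in seq_along(sides)) {
      s <- sides[[j]]
      if (labs[i] %in% s && length(s) < bsize) {
        best <- split_node[j]; bsize <- length(s)
      }
    }
    parent_of[i] <- best
  }
  child <- which(parent_of > 0L)
  edge <- cbind(parent_of[child], child)
  tr <- structure(list(edge = edge, tip.label = labs,
                       Nnode = nnode,
                       node.label = c("", as.character(
                         if (length(sides)) supports else character(0L)))),
                  class = "phylo")
  tr <- ape::collapse.singles(tr)
  tr
}
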