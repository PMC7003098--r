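#' Read a Newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Internal node labels
#' after `)` are taxon-level names on species trees and support values on
#' gene trees; both are preserved verbatim in `node.label`. Gene-tree leaves
#' follow the `"Species|gene"` convention (see [split_leaf_labels()]).
#'
#' @param path file path, or a Newick string via `text`.
#' @param text optional literal Newick string.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree found", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  tr
}

#' Write a tree as Newick
#'
#' Round-trip stable with [read_newick()]: topology, labels, and branch
#' lengths survive a write/read cycle (lengths to at least 1e-9).
#'
#' @param tree a `phylo`.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return `path`, or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

# ---- internal tree helpers ------------------------------------------------

n_tips <- function(tree) length(tree$tip.label)

is_rooted_binary <- function(tree) {
  ape::is.rooted(tree) && ape::is.binary(tree)
}

# children of each node, as a list indexed by node id
children_list <- function(tree) {
  n_node <- n_tips(tree) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# postorder of internal node ids (children before parents)
postorder_internal <- function(tree) {
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  unique(eo[, 1])
}

# leaf labels under each node (list indexed by node id)
descendant_tips <- function(tree) {
  nt <- n_tips(tree)
  n_node <- nt + tree$Nnode
  out <- vector("list", n_node)
  for (i in seq_len(nt)) out[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo)))
    out[[eo[i, 1]]] <- c(out[[eo[i, 1]]], out[[eo[i, 2]]])
  out
}

# named node id lookup for a species tree: leaves + internal node labels
species_node_ids <- function(stree) {
  nt <- n_tips(stree)
  ids <- c(seq_len(nt), nt + seq_len(stree$Nnode))
  nm <- c(stree$tip.label,
          if (is.null(stree$node.label)) rep("", stree$Nnode) else stree$node.label)
  stats::setNames(ids, nm)
}
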