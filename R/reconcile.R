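# species-tree index used by the reconciliation routines
stree_index <- function(stree) {
  nt <- n_tips(stree)
  n_node <- nt + stree$Nnode
  parent <- integer(n_node)
  parent[stree$edge[, 2]] <- stree$edge[, 1]
  root <- nt + 1L
  depth <- integer(n_node)
  ord <- ape::reorder.phylo(stree, "cladewise")$edge
  for (i in seq_len(nrow(ord))) depth[ord[i, 2]] <- depth[ord[i, 1]] + 1L
  name <- c(stree$tip.label,
            if (is.null(stree$node.label)) paste0("node", nt + seq_len(stree$Nnode))
            else stree$node.label)
  list(nt = nt, parent = parent, depth = depth, root = root, name = name,
       tip_id = stats::setNames(seq_len(nt), stree$tip.label))
}

slca <- function(idx, a, b) {
  while (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
  while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  while (a != b) { a <- idx$parent[a]; b <- idx$parent[b] }
  a
}

#' LCA reconciliation of a rooted gene tree with a species tree
#'
#' Standard last-common-ancestor mapping: every gene-tree leaf maps to its
#' species; every internal node maps to the species-tree LCA of its
#' children's images. A node is a duplication iff it maps to the same
#' species-tree node as one of its children. Losses are counted per child
#' edge: `edge_distance(M(v), M(c)) - 1` below a speciation and
#' `edge_distance(M(v), M(c))` below a duplication.
#'
#' @param gtree rooted binary gene tree (`phylo`), leaves `"Species|gene"`.
#' @param stree rooted species tree (`phylo`) whose tips cover every species
#'   in `gtree`.
#' @return a `reconciliation`: list with `D`, `L`, `events` (character per
#'   internal node, `"speciation"`/`"duplication"`), `mapping` (species node
#'   id per gene-tree node), `mapping_name`, `losses` (per gene-tree node,
#'   losses charged to its two child edges), plus the input trees.
#' @export
lca_reconcile <- function(gtree, stree) {
  if (!ape::is.rooted(gtree) || !ape::is.binary(gtree))
    stop("gene tree must be rooted and binary", call. = FALSE)
  idx <- stree_index(stree)
  nt <- n_tips(gtree)
  species <- split_leaf_labels(gtree$tip.label)$species
  unknown <- setdiff(species, names(idx$tip_id))
  if (length(unknown))
    stop("species not in species tree: ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  n_node <- nt + gtree$Nnode
  M <- integer(n_node)
  M[seq_len(nt)] <- idx$tip_id[species]
  kids <- children_list(gtree)
  events <- character(gtree$Nnode)
  losses <- numeric(n_node)
  D <- 0L; L <- 0L
  for (v in postorder_internal(gtree)) {
    c1 <- kids[[v]][1]; c2 <- kids[[v]][2]
    M[v] <- slca(idx, M[c1], M[c2])
    dup <- (M[v] == M[c1]) || (M[v] == M[c2])
    events[v - nt] <- if (dup) "duplication" else "speciation"
    if (dup) D <- D + 1L
    for (c in c(c1, c2)) {
      dist <- idx$depth[M[c]] - idx$depth[M[v]]
      l <- if (dup) dist else dist - 1L
      losses[v] <- losses[v] + l
      L <- L + l
    }
  }
  structure(list(D = D, L = as.integer(L), events = events, mapping = M,
                 mapping_name = idx$name[M], losses = losses,
                 gene_tree = gtree, species_tree = stree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("<reconciliation> D =", x$D, " L =", x$L, "\n")
  invisible(x)
}

# adjacency of an unrooted phylo: list of (neighbor, length, edge index)
unrooted_adjacency <- function(tree) {
  n_node <- n_tips(tree) + tree$Nnode
  adj <- vector("list", n_node)
  len <- tree$edge.length %||% rep(1, nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    adj[[u]] <- c(adj[[u]], list(c(v, len[k], k)))
    adj[[v]] <- c(adj[[v]], list(c(u, len[k], k)))
  }
  adj
}

# root an unrooted binary tree on edge `k`, splitting its length in half
root_on_edge <- function(tree, k) {
  adj <- unrooted_adjacency(tree)
  nt <- n_tips(tree)
  build <- function(node, via) {
    nb <- Filter(function(e) e[3] != via, adj[[node]])
    if (node <= nt) return(tree$tip.label[node])
    paste0("(", paste(vapply(nb, function(e)
      paste0(build(e[1], e[3]), ":", format(e[2], digits = 12)), ""),
      collapse = ","), ")")
  }
  u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
  half <- (tree$edge.length[k] %||% 1) / 2
  read_newick(text = paste0("(", build(u, k), ":", format(half, digits = 12),
                            ",", build(v, k), ":", format(half, digits = 12),
                            ");"))
}

#' Enumerate all rootings of an unrooted gene tree
#'
#' Places the root on each of the `2n - 3` edges in turn. Each returned tree
#' unroots back to the input (internal support labels are not carried over).
#'
#' @param tree unrooted binary `phylo` with n >= 3 tips.
#' @return list of rooted `phylo` trees; attribute `"edge_length"` gives the
#'   original length of each split edge.
#' @export
enumerate_rootings <- function(tree) {
  if (ape::is.rooted(tree))
    stop("tree is rooted; unroot it first (ape::unroot)", call. = FALSE)
  if (n_tips(tree) < 3) stop("need n >= 3", call. = FALSE)
  out <- lapply(seq_len(nrow(tree$edge)), function(k) root_on_edge(tree, k))
  attr(out, "edge_length") <- tree$edge.length %||% rep(1, nrow(tree$edge))
  out
}

#' Best rooting of a gene tree under a species hypothesis
#'
#' Reconciles every rooting of the unrooted gene tree against `stree` and
#' returns the one minimizing the duplication/loss cost — lexicographic
#' `(D, L)` by default (losses are never traded against duplications
#' silently), or the weighted sum `weights["dup"] * D + weights["loss"] * L`
#' when `weights` is given. Ties are broken by the longest original root
#' edge, then by canonical leaf-name order of the resulting split; the full
#' tie set is reported.
#'
#' @param tree gene tree (`phylo`), rooted trees are unrooted first.
#' @param stree rooted species hypothesis.
#' @param weights optional named numeric `c(dup=, loss=)`.
#' @return rooted `phylo` with attributes `"D"`, `"L"`, `"edge"` (index of
#'   the chosen edge), `"ties"` (indices of all minimum-cost edges).
#' @export
best_rooting <- function(tree, stree, weights = NULL) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  roots <- enumerate_rootings(tree)
  elen <- attr(roots, "edge_length")
  rec <- lapply(roots, lca_reconcile, stree = stree)
  Ds <- vapply(rec, `[[`, 0L, "D"); Ls <- vapply(rec, `[[`, 0L, "L")
  if (is.null(weights)) {
    key <- Ds * (max(Ls) + 1) + Ls
  } else key <- weights[["dup"]] * Ds + weights[["loss"]] * Ls
  ties <- which(key == min(key))
  if (length(ties) > 1) {
    longest <- ties[elen[ties] == max(elen[ties])]
    if (length(longest) > 1) {
      skey <- vapply(longest, function(k) {
        side <- sort(descendant_tips(tree)[[tree$edge[k, 2]]])
        paste(side, collapse = "\r")
      }, "")
      longest <- longest[order(skey)]
    }
    pick <- longest[1]
  } else pick <- ties
  out <- roots[[pick]]
  attr(out, "D") <- Ds[pick]; attr(out, "L") <- Ls[pick]
  attr(out, "edge") <- pick; attr(out, "ties") <- ties
  out
}

#' Count simple phylum-early root choices on an unrooted gene tree
#'
#' A root edge is a simple X-early choice iff one of its two sides contains
#' only genes from phylum X: rooting there makes phylum X the sister lineage
#' to everything else. Counts are reported per phylum. When species
#' hypotheses are supplied, the duplication/loss cost of every rooting under
#' every hypothesis is tabulated as the cost-based generalization (root
#' choices "in combination with inferred gene losses").
#'
#' @param tree unrooted binary gene tree.
#' @param scheme a [clade_scheme()].
#' @param hypotheses optional named list of rooted species trees.
#' @return a `root_choice_report`: list with `counts` (named integer per
#'   phylum), `per_edge` (data.frame: edge, pure phylum or NA, and D/L
#'   columns per hypothesis), `n_edges`.
#' @export
count_root_choices <- function(tree, scheme, hypotheses = NULL) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  phyla <- leaf_phyla(tree$tip.label, scheme)
  tips <- descendant_tips(tree)
  all_tips <- tree$tip.label
  n_edge <- nrow(tree$edge)
  # an edge is a simple X-early choice if either side holds only phylum X;
  # in a two-phylum tree one edge can be a choice for both phyla at once
  pure <- vector("list", n_edge)
  for (k in seq_len(n_edge)) {
    side <- tips[[tree$edge[k, 2]]]
    p1 <- unique(phyla[match(side, all_tips)])
    p2 <- unique(phyla[match(setdiff(all_tips, side), all_tips)])
    lab <- c(if (length(p1) == 1) p1, if (length(p2) == 1) p2)
    pure[[k]] <- unique(lab)
  }
  counts <- table(factor(unlist(pure), levels = unique(scheme$phylum_of)))
  per_edge <- data.frame(
    edge = seq_len(n_edge),
    pure_phylum = vapply(pure, function(p)
      if (length(p)) paste(p, collapse = ",") else NA_character_, ""),
    stringsAsFactors = FALSE)
  if (!is.null(hypotheses)) {
    roots <- enumerate_rootings(tree)
    for (h in names(hypotheses)) {
      rec <- lapply(roots, lca_reconcile, stree = hypotheses[[h]])
      per_edge[[paste0("D_", h)]] <- vapply(rec, `[[`, 0L, "D")
      per_edge[[paste0("L_", h)]] <- vapply(rec, `[[`, 0L, "L")
    }
  }
  structure(list(counts = c(counts), per_edge = per_edge, n_edges = n_edge),
            class = "root_choice_report")
}

#' @export
print.root_choice_report <- function(x, ...) {
  cat("<root_choice_report>", x$n_edges, "root edges; simple choices:\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}
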