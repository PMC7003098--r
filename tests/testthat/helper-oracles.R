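# Independent oracles used by the property tests. These deliberately avoid
# the package's reconciliation code paths: mappings are found by species-set
# containment scans, rootings are generated through phytools, and homology
# relations by per-pair MRCA lookups through ape.

species_of <- function(labels) sub("\\|.*$", "", labels)

# all descendant tip labels per node, via ape only
ora_tips <- function(tree) {
  nt <- length(tree$tip.label)
  out <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) out[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo)))
    out[[eo[i, 1]]] <- c(out[[eo[i, 1]]], out[[eo[i, 2]]])
  out
}

# edge-count depth of every species-tree node
ora_depth <- function(stree) {
  d <- integer(length(stree$tip.label) + stree$Nnode)
  eo <- ape::reorder.phylo(stree, "cladewise")$edge
  for (i in seq_len(nrow(eo))) d[eo[i, 2]] <- d[eo[i, 1]] + 1L
  d
}

# reconciliation by minimal-containing-clade scan (no LCA walking)
oracle_reconcile <- function(gtree, stree) {
  st <- ora_tips(stree)
  sizes <- lengths(st)
  depth <- ora_depth(stree)
  gt <- ora_tips(gtree)
  nt <- length(gtree$tip.label)
  mapsp <- function(spset) {
    cand <- which(vapply(st, function(x) all(spset %in% x), logical(1)))
    cand[which.min(sizes[cand])]
  }
  M <- vapply(seq_along(gt), function(v)
    mapsp(unique(species_of(gt[[v]]))), 1L)
  D <- 0L; L <- 0L
  for (v in (nt + 1):(nt + gtree$Nnode)) {
    kids <- gtree$edge[gtree$edge[, 1] == v, 2]
    dup <- any(M[kids] == M[v])
    if (dup) D <- D + 1L
    for (c in kids) {
      dist <- depth[M[c]] - depth[M[v]]
      L <- L + if (dup) dist else dist - 1L
    }
  }
  list(D = D, L = L, M = M)
}

# all rootings through phytools::reroot (independent of root_on_edge)
oracle_rootings <- function(utree) {
  if (is.null(utree$edge.length)) utree$edge.length <- rep(1, nrow(utree$edge))
  lapply(seq_len(nrow(utree$edge)), function(k)
    phytools::reroot(utree, utree$edge[k, 2],
                     position = utree$edge.length[k] / 2))
}

# independent recoding of the duplication-timing rules over one rooted tree
oracle_rooted_category <- function(rooted, stree, phymap, eum = c("B", "Cn", "Pl"),
                                   strict = TRUE) {
  rec <- oracle_reconcile(rooted, stree)
  nt <- length(rooted$tip.label)
  gt <- ora_tips(rooted)
  sizes_s <- lengths(ora_tips(stree))
  dups <- c()
  for (v in (nt + 1):(nt + rooted$Nnode)) {
    kids <- rooted$edge[rooted$edge[, 1] == v, 2]
    if (any(rec$M[kids] == rec$M[v])) dups <- c(dups, v)
  }
  if (!length(dups)) return("NO_DUPLICATION")
  ph <- function(node) unique(unname(phymap[species_of(gt[[node]])]))
  verdict <- function(v) {
    kids <- rooted$edge[rooted$edge[, 1] == v, 2]
    S1 <- ph(kids[1]); S2 <- ph(kids[2])
    U <- union(S1, S2); I <- intersect(S1, S2)
    sis <- function(X) {
      p <- rooted$edge[match(v, rooted$edge[, 2]), 1]
      if (is.na(p)) return(FALSE)
      o <- setdiff(rooted$edge[rooted$edge[, 1] == p, 2], v)
      if (length(o) != 1) return(FALSE)
      lv <- gt[[o]]
      if (!all(unname(phymap[species_of(lv)]) == X)) return(FALSE)
      !(strict && anyDuplicated(species_of(lv)) > 0)
    }
    if (any(c("Choanoflagellatea", "Outgroup") %in% I))
      return("PRE_CHOANOZOAN_UNINFORMATIVE")
    if (length(U) == 1) return("PHYLUM_SPECIFIC")
    if ("Po" %in% I && any(eum %in% S1) && any(eum %in% S2) &&
        !("Ct" %in% U) && sis("Ct")) return("BENTHOZOA_SUPPORT")
    if ("Ct" %in% I && any(eum %in% S1) && any(eum %in% S2) &&
        !("Po" %in% U) && sis("Po")) return("NEURALIA_SUPPORT")
    if ("Ct" %in% I) return("CTENOPHORE_SHARED_UNINFORMATIVE")
    if (all(U %in% eum) && sum(S1 %in% eum) >= 2 && sum(S2 %in% eum) >= 2)
      return("EUMETAZOA_DUPLICATION")
    NA_character_
  }
  vs <- vapply(dups, verdict, "")
  pr <- c("BENTHOZOA_SUPPORT", "NEURALIA_SUPPORT", "EUMETAZOA_DUPLICATION",
          "PRE_CHOANOZOAN_UNINFORMATIVE", "CTENOPHORE_SHARED_UNINFORMATIVE",
          "PHYLUM_SPECIFIC")
  hit <- pr[pr %in% vs]
  if (length(hit)) hit[1] else NA_character_
}

# full brute-force family classification over every min-cost rooting
oracle_classify <- function(tree, phymap, hypotheses, strict = TRUE) {
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  outg <- utree$tip.label[unname(phymap[species_of(utree$tip.label)]) %in%
                            c("Choanoflagellatea", "Outgroup")]
  roots <- oracle_rootings(utree)
  tips <- ora_tips(utree)
  fixed <- NULL
  if (length(outg)) {
    for (k in seq_len(nrow(utree$edge))) {
      side <- tips[[utree$edge[k, 2]]]
      if (setequal(side, outg) ||
          setequal(setdiff(utree$tip.label, side), outg)) { fixed <- k; break }
    }
  }
  cats <- c()
  for (h in hypotheses) {
    if (!is.null(fixed)) {
      edges <- fixed
    } else {
      costs <- vapply(roots, function(r) {
        x <- oracle_reconcile(r, h); x$D * 10000 + x$L }, 1)
      edges <- which(costs == min(costs))
    }
    for (k in edges)
      cats <- c(cats, oracle_rooted_category(roots[[k]], h, phymap,
                                             strict = strict))
  }
  pinned <- unique(cats[!is.na(cats)])
  if (length(pinned) == 1) pinned else "AMBIGUOUS_ROOT"
}

# per-pair homology oracle: MRCA lookup per gene pair
oracle_truth_table <- function(history) {
  tr <- history$tree
  labs <- tr$tip.label
  ev <- setNames(history$events$type, history$events$label)
  lv <- setNames(history$events$level, history$events$label)
  nt <- length(labs)
  out <- list()
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    m <- ape::getMRCA(tr, c(labs[i], labs[j]))
    lab <- tr$node.label[m - nt]
    type <- unname(ev[lab])
    sa <- species_of(labs[i]); sb <- species_of(labs[j])
    if (type == "speciation" && sa != sb)
      out[[length(out) + 1]] <- c(labs[i], labs[j], "ortholog")
    if (type == "duplication" && sa == sb)
      out[[length(out) + 1]] <- c(labs[i], labs[j], "paralog", unname(lv[lab]))
  }
  out
}

# small hand-built homology table used by the screen tests
toy_table <- function() {
  rows <- list(
    c("tA", "Tribolium", "tB", "Tribolium", "within_species_paralog", "Metazoa"),
    c("tB", "Tribolium", "tC", "Tribolium", "within_species_paralog", "Cucujiformia"),
    c("tD", "Tribolium", "tE", "Tribolium", "within_species_paralog", "Bilateria"),
    c("tA", "Tribolium", "a1", "Aedes", "ortholog_one2one", ""),
    c("tB", "Tribolium", "a2", "Aedes", "ortholog_one2one", ""),
    c("tD", "Tribolium", "a3", "Aedes", "ortholog_one2one", ""),
    c("tE", "Tribolium", "a4", "Aedes", "ortholog_one2one", ""),
    c("tA", "Tribolium", "c1", "Capitella", "ortholog_one2one", ""),
    c("tB", "Tribolium", "c2", "Capitella", "ortholog_one2one", ""),
    c("tD", "Tribolium", "c3", "Capitella", "ortholog_one2one", ""),
    c("tA", "Tribolium", "p1", "Trichoplax", "ortholog_one2one", ""),
    c("tB", "Tribolium", "p2", "Trichoplax", "ortholog_one2one", ""),
    c("tD", "Tribolium", "p3", "Trichoplax", "ortholog_one2one", ""),
    c("tE", "Tribolium", "p4", "Trichoplax", "ortholog_one2one", ""),
    c("tA", "Tribolium", "s1", "Amphimedon", "ortholog_one2one", ""),
    c("tB", "Tribolium", "m1", "Mnemiopsis", "ortholog_one2one", ""))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("gene_a", "species_a", "gene_b", "species_b", "relation",
                 "duplication_level")
  homology_table(df)
}

default_hypotheses <- function(n_per_phylum = c(B = 1, Cn = 1, Pl = 1,
                                                Ct = 1, Po = 1), ...) {
  h <- default_species_trees(n_per_phylum, ...)
  list(scheme = h$scheme,
       hyps = h[c("sponge_early", "ctenophore_early")])
}
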