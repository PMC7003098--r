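FAMILY_CATEGORIES <- c("NO_DUPLICATION", "PRE_CHOANOZOAN_UNINFORMATIVE",
                       "CTENOPHORE_SHARED_UNINFORMATIVE", "BENTHOZOA_SUPPORT",
                       "NEURALIA_SUPPORT", "EUMETAZOA_DUPLICATION",
                       "PHYLUM_SPECIFIC", "AMBIGUOUS_ROOT")

# precedence when aggregating duplication-node verdicts into one family call:
# positive branching evidence first, then uninformative classes
CATEGORY_PRECEDENCE <- c("BENTHOZOA_SUPPORT", "NEURALIA_SUPPORT",
                         "EUMETAZOA_DUPLICATION",
                         "PRE_CHOANOZOAN_UNINFORMATIVE",
                         "CTENOPHORE_SHARED_UNINFORMATIVE",
                         "PHYLUM_SPECIFIC")

# verdict for one duplication node, from the phylum sets of its two child
# clades, with the sister-lineage ("immediately outside") checks done on the
# rooted gene tree
node_verdict <- function(v, rec, scheme, strict) {
  g <- rec$gene_tree
  nt <- n_tips(g)
  kids <- children_list(g)
  tips <- descendant_tips(g)
  phy <- function(node) unique(leaf_phyla(tips[[node]], scheme))
  S1 <- phy(kids[[v]][1]); S2 <- phy(kids[[v]][2])
  U <- union(S1, S2); I <- intersect(S1, S2)
  eum <- scheme$eumetazoa
  outg <- c("Choanoflagellatea", "Outgroup")

  # sister clade of v holds only phylum X (optionally single-copy/species)?
  sister_is <- function(X) {
    parent <- g$edge[match(v, g$edge[, 2]), 1]
    if (is.na(parent)) return(FALSE)
    o <- setdiff(kids[[parent]], v)
    if (length(o) != 1) return(FALSE)
    lv <- tips[[o]]
    ph <- leaf_phyla(lv, scheme)
    if (!all(ph == X)) return(FALSE)
    if (strict && anyDuplicated(split_leaf_labels(lv)$species)) return(FALSE)
    TRUE
  }

  if (any(outg %in% I)) return("PRE_CHOANOZOAN_UNINFORMATIVE")
  if (length(U) == 1) return("PHYLUM_SPECIFIC")
  if ("Po" %in% I && any(eum %in% S1) && any(eum %in% S2) &&
      !("Ct" %in% U) && sister_is("Ct")) return("BENTHOZOA_SUPPORT")
  if ("Ct" %in% I && any(eum %in% S1) && any(eum %in% S2) &&
      !("Po" %in% U) && sister_is("Po")) return("NEURALIA_SUPPORT")
  if ("Ct" %in% I) return("CTENOPHORE_SHARED_UNINFORMATIVE")
  if (all(U %in% eum) && sum(S1 %in% eum) >= 2 && sum(S2 %in% eum) >= 2)
    return("EUMETAZOA_DUPLICATION")
  NA_character_
}

# apparent losses per paralog clade of a duplication node: metazoan phyla
# spanned by the clade's species-tree image but absent from its leaves
apparent_losses <- function(v, rec, scheme) {
  g <- rec$gene_tree
  kids <- children_list(g)
  gtips <- descendant_tips(g)
  stips <- descendant_tips(rec$species_tree)
  lapply(kids[[v]], function(c) {
    expected <- unique(phylum_of(scheme, stips[[rec$mapping[c]]]))
    observed <- unique(leaf_phyla(gtips[[c]], scheme))
    setdiff(expected, observed)
  })
}

# verdicts of one rooted, reconciled tree: data.frame of duplication nodes
rooted_verdicts <- function(rooted, stree, scheme, strict) {
  rec <- lca_reconcile(rooted, stree)
  nt <- n_tips(rooted)
  dups <- which(rec$events == "duplication") + nt
  if (!length(dups))
    return(list(category = "NO_DUPLICATION", rec = rec,
                nodes = data.frame(node = integer(), verdict = character())))
  verdicts <- vapply(dups, node_verdict, "", rec = rec, scheme = scheme,
                     strict = strict)
  hit <- CATEGORY_PRECEDENCE[CATEGORY_PRECEDENCE %in% verdicts]
  # a rooting whose duplications pin no category asserts nothing (NA)
  category <- if (length(hit)) hit[1] else NA_character_
  list(category = category, rec = rec,
       nodes = data.frame(node = dups, verdict = verdicts,
                          stringsAsFactors = FALSE))
}

#' Classify the duplication timing of a gene family
#'
#' Determines what a family's duplications say about early animal branching.
#' When non-metazoan outgroup genes (choanoflagellates or deeper) are
#' present and separable, the tree is rooted on the edge splitting them off;
#' otherwise every minimum duplication/loss-cost rooting under every
#' supplied hypothesis is evaluated. For each duplication node with child
#' phylum sets S1, S2 (in precedence order): outgroup phyla in both clades
#' mean the duplication predates Choanozoa
#' (`PRE_CHOANOZOAN_UNINFORMATIVE`); a single-phylum duplication is
#' `PHYLUM_SPECIFIC`; sponges plus eumetazoans in both clades, no ctenophore
#' inside, and a ctenophore lineage branching immediately outside is
#' `BENTHOZOA_SUPPORT` (mirrored: `NEURALIA_SUPPORT`); ctenophores in both
#' clades are `CTENOPHORE_SHARED_UNINFORMATIVE`; a duplication wholly inside
#' Eumetazoa spanning >= 2 eumetazoan phyla per clade is
#' `EUMETAZOA_DUPLICATION`. Families whose admissible rootings disagree —
#' or whose duplications pin no category — are `AMBIGUOUS_ROOT`; families
#' with no duplication under any admissible rooting are `NO_DUPLICATION`.
#'
#' @param tree gene tree (`phylo`, rooted or unrooted; rooted input is
#'   re-evaluated from its unrooted topology).
#' @param scheme a [clade_scheme()] covering the gene tree's species.
#' @param hypotheses named list of rooted species trees (the competing
#'   hypotheses), each covering all species in the tree.
#' @param strict_single_copy_sister require the Benthozoa/Neuralia sister
#'   lineage to be single-copy per species (default TRUE).
#' @return a `family_classification`: list with `category`, `per_rooting`
#'   (data.frame: hypothesis, edge, D, L, category), `duplication_nodes`,
#'   `apparent_losses`, `rootings_used`.
#' @export
classify_family <- function(tree, scheme, hypotheses,
                            strict_single_copy_sister = TRUE) {
  stopifnot(inherits(scheme, "clade_scheme"), is.list(hypotheses),
            length(hypotheses) >= 1)
  if (is.null(names(hypotheses)))
    names(hypotheses) <- paste0("hypothesis", seq_along(hypotheses))
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  leaf_phyla(utree$tip.label, scheme)  # validate species coverage
  outg <- utree$tip.label[leaf_phyla(utree$tip.label, scheme) %in%
                            c("Choanoflagellatea", "Outgroup")]

  candidate_edges <- function() {
    tips <- descendant_tips(utree)
    if (length(outg)) {
      for (k in seq_len(nrow(utree$edge))) {
        side <- tips[[utree$edge[k, 2]]]
        if (setequal(side, outg) ||
            setequal(setdiff(utree$tip.label, side), outg))
          return(list(outgroup_rooted = k))
      }
    }
    NULL
  }
  fixed <- candidate_edges()

  evals <- list()
  for (h in names(hypotheses)) {
    stree <- hypotheses[[h]]
    if (!is.null(fixed)) {
      edges <- fixed[[1]]
    } else {
      roots <- enumerate_rootings(utree)
      costs <- lapply(roots, lca_reconcile, stree = stree)
      Ds <- vapply(costs, `[[`, 0L, "D"); Ls <- vapply(costs, `[[`, 0L, "L")
      key <- Ds * (max(Ls) + 1) + Ls
      edges <- which(key == min(key))
    }
    for (k in edges) {
      rooted <- root_on_edge(utree, k)
      rv <- rooted_verdicts(rooted, stree, scheme, strict_single_copy_sister)
      evals[[length(evals) + 1L]] <-
        list(hypothesis = h, edge = k, rv = rv)
    }
  }
  cats <- vapply(evals, function(e) e$rv$category, "")
  per_rooting <- data.frame(
    hypothesis = vapply(evals, `[[`, "", "hypothesis"),
    edge = vapply(evals, `[[`, 0L, "edge"),
    D = vapply(evals, function(e) e$rv$rec$D, 0L),
    L = vapply(evals, function(e) e$rv$rec$L, 0L),
    category = cats, stringsAsFactors = FALSE)
  # rootings that pin no category do not veto those that do; ambiguity means
  # two admissible rootings assert different categories, or none asserts any
  pinned <- unique(cats[!is.na(cats)])
  category <- if (length(pinned) == 1) pinned else "AMBIGUOUS_ROOT"
  # report duplication evidence from the first evaluation matching the call
  m <- match(category, cats)
  pick <- evals[[if (is.na(m)) 1L else m]]
  loss_report <- lapply(seq_len(nrow(pick$rv$nodes)), function(i)
    apparent_losses(pick$rv$nodes$node[i], pick$rv$rec, scheme))
  names(loss_report) <- pick$rv$nodes$node
  structure(list(category = category, per_rooting = per_rooting,
                 duplication_nodes = pick$rv$nodes,
                 apparent_losses = loss_report,
                 rootings_used = unique(per_rooting$edge)),
            class = "family_classification")
}

#' @export
print.family_classification <- function(x, ...) {
  cat("<family_classification>", x$category, "(",
      nrow(x$per_rooting), "rooting evaluations )\n")
  invisible(x)
}

#' Partition alignment columns by resemblance to two clades
#'
#' For each column, the probe consensus residue is compared with the
#' consensus residues (majority, >= 50% of non-gap, non-X residues) of two
#' reference clades: a column is `A-like` when the probe matches clade A's
#' consensus and not clade B's, `B-like` in the mirrored case, and
#' `neither` otherwise.
#'
#' @param aln an [aa_alignment()].
#' @param cladeA_rows,cladeB_rows,probe_rows disjoint row-id vectors.
#' @return list with `assignment` (character per column), `counts`, and the
#'   three consensus vectors.
#' @export
diagnostic_columns <- function(aln, cladeA_rows, cladeB_rows, probe_rows) {
  stopifnot(inherits(aln, "aa_alignment"))
  groups <- list(A = cladeA_rows, B = cladeB_rows, probe = probe_rows)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stop("empty clade: ", g, call. = FALSE)
    if (!all(groups[[g]] %in% rownames(aln)))
      stop("unknown row id(s) in ", g, call. = FALSE)
  }
  if (length(intersect(cladeA_rows, cladeB_rows)) ||
      length(intersect(cladeA_rows, probe_rows)) ||
      length(intersect(cladeB_rows, probe_rows)))
    stop("row sets must be disjoint", call. = FALSE)
  consensus <- function(rows) {
    apply(aln[rows, , drop = FALSE], 2, function(col) {
      col <- col[col %in% AA_ALPHABET]
      if (!length(col)) return(NA_character_)
      tab <- sort(table(col), decreasing = TRUE)
      if (tab[1] / sum(tab) >= 0.5) names(tab)[1] else NA_character_
    })
  }
  cA <- consensus(cladeA_rows); cB <- consensus(cladeB_rows)
  cP <- consensus(probe_rows)
  a_like <- !is.na(cP) & !is.na(cA) & cP == cA & (is.na(cB) | cP != cB)
  b_like <- !is.na(cP) & !is.na(cB) & cP == cB & (is.na(cA) | cP != cA)
  assignment <- ifelse(a_like, "A-like", ifelse(b_like, "B-like", "neither"))
  list(assignment = assignment,
       counts = c(`A-like` = sum(a_like), `B-like` = sum(b_like),
                  neither = sum(!a_like & !b_like)),
       consensus_A = cA, consensus_B = cB, consensus_probe = cP)
}
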