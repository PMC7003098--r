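#' Tree-based ortholog calling from a (possibly mis-rooted) gene tree
#'
#' Labels every internal node speciation/duplication by [lca_reconcile()]
#' against the assumed species hypothesis, then emits a Compara-style
#' homology table: a cross-species pair is an ortholog iff its gene-tree LCA
#' is a speciation node; within-species pairs become paralogs at the level
#' of their LCA duplication's species mapping; subtypes by reciprocal
#' counting. This is how a mis-rooted tree manufactures false-positive gene
#' losses: genes flipped across the root lose all their ortholog calls.
#'
#' @param gtree rooted binary gene tree.
#' @param stree assumed rooted species hypothesis.
#' @return a [homology_table()].
#' @export
call_orthologs <- function(gtree, stree) {
  rec <- lca_reconcile(gtree, stree)
  nt <- n_tips(gtree)
  g <- gtree
  g$node.label <- paste0("r", seq_len(g$Nnode))
  event_of <- stats::setNames(rec$events, g$node.label)
  level_of <- stats::setNames(rec$mapping_name[nt + seq_len(g$Nnode)],
                              g$node.label)
  table_from_labeled_tree(g, event_of, level_of)
}

#' Ortholog coverage of a focal species against a reference
#'
#' Percentage of the focal species' genes that receive at least one ortholog
#' call in the reference species, aggregated over a list of per-family
#' homology tables.
#'
#' @param tables list of [homology_table()]s (one per family).
#' @param focal_species,reference_species species names.
#' @param focal_genes optional explicit focal gene universe (defaults to all
#'   focal genes mentioned in the tables; supply the true gene list when
#'   genes may have lost every record).
#' @return percentage in `[0, 100]`.
#' @export
ortholog_coverage <- function(tables, focal_species, reference_species,
                              focal_genes = NULL) {
  if (inherits(tables, "homology_table")) tables <- list(tables)
  if (is.null(focal_genes))
    focal_genes <- unique(unlist(lapply(tables, genes_of_species,
                                        species = focal_species)))
  if (!length(focal_genes))
    stop("focal species absent: ", focal_species, call. = FALSE)
  hit <- vapply(focal_genes, function(g)
    any(vapply(tables, function(tb)
      length(ortholog_partners(tb, g, reference_species)) > 0, logical(1))),
    logical(1))
  100 * sum(hit) / length(focal_genes)
}

#' Root-to-tip rate heterogeneity between two clades
#'
#' Ratio of the mean root-to-tip path length of clade 1 to that of clade 2
#' (branch-length units); 1.0 for an ultrametric symmetric tree, invariant
#' under uniform scaling of all branch lengths.
#'
#' @param gtree rooted `phylo` with branch lengths.
#' @param clade_partition list of two leaf-label vectors.
#' @return positive ratio.
#' @export
rate_heterogeneity <- function(gtree, clade_partition) {
  stopifnot(is.list(clade_partition), length(clade_partition) == 2)
  depth <- ape::node.depth.edgelength(gtree)
  m <- function(leaves) {
    idx <- match(leaves, gtree$tip.label)
    if (anyNA(idx)) stop("unknown leaf label(s)", call. = FALSE)
    mean(depth[idx])
  }
  den <- m(clade_partition[[2]])
  if (den == 0) stop("zero mean root-to-tip length in clade 2", call. = FALSE)
  m(clade_partition[[1]]) / den
}

#' Amino-acid composition heterogeneity (Pearson chi-square)
#'
#' Pearson chi-square of pooled residue counts, group versus rest, over the
#' residues with nonzero pooled count; degrees of freedom = residues - 1.
#'
#' @param aln an [aa_alignment()].
#' @param group_rows,rest_rows nonempty disjoint row-id vectors.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
composition_heterogeneity <- function(aln, group_rows, rest_rows) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!length(group_rows) || !length(rest_rows))
    stop("both groups must be nonempty", call. = FALSE)
  cg <- aa_counts(aln[group_rows, , drop = FALSE])
  cr <- aa_counts(aln[rest_rows, , drop = FALSE])
  keep <- (cg + cr) > 0
  if (sum(keep) < 2)
    stop("degenerate input: fewer than two residues observed", call. = FALSE)
  obs <- rbind(group = cg[keep], rest = cr[keep])
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  df <- sum(keep) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' The forced-rooting ortholog-miscalling experiment
#'
#' Quantifies what happens when gene families from one world are forced into
#' the other rooting model. For each family: simulate a true history under
#' `cfg` (the TRUE hypothesis), derive the analysis tree (neighbor-joining
#' on Poisson-corrected p-distances of the evolved sequences, or the true
#' tree when `use_nj = FALSE`), force the minimum duplication/loss rooting
#' under the ASSUMED hypothesis, call orthologs from the forced tree, and
#' aggregate: per-species ortholog coverage against the reference species,
#' the ctenophore coverage deficit gap (minimum over other lineages minus
#' the ctenophore value; positive = deficit), per-phylum false-loss rates
#' (fraction of families in which a phylum's gene that truly has orthologs
#' receives none), and — per family with a surviving focal duplication —
#' the clade rate-heterogeneity ratio and composition chi-square. Families
#' whose analysis fails (e.g. saturated distances) are logged and skipped.
#'
#' @param cfg a [sim_config()] describing the TRUE world.
#' @param assumed_hypothesis `"sponge_early"` or `"ctenophore_early"` (or a
#'   rooted species tree).
#' @param n_families families per run.
#' @param seed integer seed (drives all per-family sub-seeds).
#' @param use_nj infer trees by NJ (default) or analyze true trees.
#' @param reference_species coverage references; default the first cnidarian
#'   and first sponge species.
#' @return a `miscall_result`: list with `coverage` (species x reference
#'   matrix, percent), `deficit_gap` (per reference), `ct_is_strict_min`,
#'   `false_loss_rate` (per phylum), `rate_ratio` (mean), `composition_chisq`
#'   (mean), `n_families`, `n_skipped`, `seed`, `per_family`.
#' @export
run_experiment <- function(cfg, assumed_hypothesis, n_families, seed,
                           use_nj = TRUE, reference_species = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_families >= 1)
  hyp <- default_species_trees(cfg$n_per_phylum, cfg$n_choanoflagellate,
                               cfg$n_outgroup)
  scheme <- hyp$scheme
  assumed <- if (inherits(assumed_hypothesis, "phylo")) assumed_hypothesis
  else hyp[[match.arg(assumed_hypothesis,
                      c("sponge_early", "ctenophore_early"))]]
  species <- names(scheme$phylum_of)
  metazoan <- species[scheme$phylum_of %in% c("B", "Cn", "Pl", "Ct", "Po")]
  if (is.null(reference_species))
    reference_species <- c(species[scheme$phylum_of == "Cn"][1],
                           species[scheme$phylum_of == "Po"][1])

  tables <- list(); true_genes <- list(); fam_rows <- list()
  rate_ratios <- c(); chisqs <- c()
  false_loss_hits <- stats::setNames(numeric(5),
                                     c("B", "Cn", "Pl", "Ct", "Po"))
  n_ok <- 0L; n_skipped <- 0L
  for (i in seq_len(n_families)) {
    fam <- tryCatch({
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(seed, i)
      cfg_i$family_id <- paste0("fam", i)
      hist <- simulate_family(cfg_i)
      truth <- homology_table_from_truth(hist)
      aln <- if (use_nj) evolve_sequences(hist, cfg_i) else NULL
      analysis_tree <- if (use_nj)
        neighbor_joining(poisson_correct(p_distance(aln))) else hist$tree
      rooted <- best_rooting(analysis_tree, assumed)
      calls <- call_orthologs(rooted, assumed)
      list(hist = hist, truth = truth, calls = calls, aln = aln)
    }, error = function(e) NULL)
    if (is.null(fam)) { n_skipped <- n_skipped + 1L; next }
    n_ok <- n_ok + 1L
    tables[[n_ok]] <- fam$calls
    lv <- split_leaf_labels(fam$hist$tree$tip.label)
    for (s in unique(lv$species))
      true_genes[[s]] <- c(true_genes[[s]], lv$label[lv$species == s])

    # false loss: a gene with true orthologs that received no call at all
    called_orth <- unique(c(
      fam$calls$gene_a[is_ortholog_relation(fam$calls$relation)],
      fam$calls$gene_b[is_ortholog_relation(fam$calls$relation)]))
    true_orth <- unique(c(
      fam$truth$gene_a[is_ortholog_relation(fam$truth$relation)],
      fam$truth$gene_b[is_ortholog_relation(fam$truth$relation)]))
    miscalled <- setdiff(true_orth, called_orth)
    if (length(miscalled)) {
      ph <- leaf_phyla(miscalled, scheme)
      for (p in unique(ph)) false_loss_hits[p] <- false_loss_hits[p] + 1
    }
    fam_rows[[n_ok]] <- data.frame(
      family = i, n_genes = n_tips(fam$hist$tree),
      n_miscalled = length(miscalled),
      miscalled_phyla = paste(sort(unique(leaf_phyla(miscalled, scheme))),
                              collapse = ","))
    # rate/composition heterogeneity relative to the focal duplication
    if (!is.na(fam$hist$focal_duplication)) {
      tr <- fam$hist$tree
      v <- n_tips(tr) + match(fam$hist$focal_duplication, tr$node.label)
      kd <- children_list(tr)[[v]]
      if (length(kd) == 2) {
        parts <- lapply(kd, function(k) descendant_tips(tr)[[k]])
        rr <- tryCatch(rate_heterogeneity(tr, parts), error = function(e) NA)
        rate_ratios <- c(rate_ratios, rr)
        if (!is.null(fam$aln) && length(parts[[1]]) && length(parts[[2]])) {
          cs <- tryCatch(composition_heterogeneity(fam$aln, parts[[1]],
                                                   parts[[2]])$statistic,
                         error = function(e) NA)
          chisqs <- c(chisqs, cs)
        }
      }
    }
  }
  if (!n_ok) stop("every family failed", call. = FALSE)

  coverage <- matrix(NA_real_, length(species), length(reference_species),
                     dimnames = list(species, reference_species))
  for (s in species) {
    if (is.null(true_genes[[s]])) next
    for (r in reference_species) {
      if (s == r) next
      coverage[s, r] <- ortholog_coverage(tables, s, r,
                                          focal_genes = true_genes[[s]])
    }
  }
  ct_sp <- species[scheme$phylum_of == "Ct"]
  gap <- stats::setNames(numeric(length(reference_species)),
                         reference_species)
  for (r in reference_species) {
    ct_val <- mean(coverage[ct_sp, r], na.rm = TRUE)
    others <- setdiff(metazoan, c(ct_sp, r))
    gap[r] <- min(coverage[others, r], na.rm = TRUE) - ct_val
  }
  structure(list(coverage = coverage, deficit_gap = gap,
                 ct_is_strict_min = all(gap > 0),
                 false_loss_rate = false_loss_hits / n_ok,
                 rate_ratio = if (length(rate_ratios))
                   mean(rate_ratios, na.rm = TRUE) else NA_real_,
                 composition_chisq = if (length(chisqs))
                   mean(chisqs, na.rm = TRUE) else NA_real_,
                 n_families = n_ok, n_skipped = n_skipped, seed = seed,
                 per_family = do.call(rbind, fam_rows)),
            class = "miscall_result")
}

#' @export
print.miscall_result <- function(x, ...) {
  cat("<miscall_result>", x$n_families, "families (", x$n_skipped,
      "skipped ); deficit gap:\n")
  print(round(x$deficit_gap, 2))
  cat("false-loss rate per phylum:\n")
  print(round(x$false_loss_rate, 3))
  invisible(x)
}
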