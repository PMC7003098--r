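#' Configuration of the model-agnostic paralogy screen
#'
#' Encodes one run of the screen cascade over a homology table: pick the
#' paralogy groups of a focal species (excluding duplications at
#' too-recent taxonomic levels), require orthologs in a set of anchor taxa,
#' keep small groups, sample a fraction, and only then annotate presence or
#' absence in the sponge-like and ctenophore-like species. The annotation
#' species are never used as filters — that is the model-agnosticism that
#' protects the screen from orthology calls biased by an assumed root.
#'
#' @param focal_species species whose genes seed the screen.
#' @param required_ortholog_taxa species in which every retained gene must
#'   have >= 1 ortholog called.
#' @param required_paralogy_taxa species in which, additionally, >= 1 of
#'   those ortholog partners must itself be paralogy-grouped.
#' @param excluded_duplication_levels taxonomic levels (species-tree node
#'   names) whose within-species duplications are disregarded.
#' @param keep_size_range inclusive `[min, max]` group size kept
#'   (min >= 2; use `Inf` for no upper bound).
#' @param sample_fraction fraction of kept groups sampled, in (0, 1].
#' @param seed integer seed for the group sampling.
#' @param annotate_species species flagged (not filtered) at the end.
#' @param drop_mode `"sever"` (default; excluded levels only sever paralogy
#'   edges) or `"remove"` (genes with an excluded-level duplication are
#'   dropped outright).
#' @param ortholog_requirement `"per_gene"` (default) or `"per_group"`.
#' @return a `screen_config`.
#' @export
screen_config <- function(focal_species,
                          required_ortholog_taxa = character(),
                          required_paralogy_taxa = character(),
                          excluded_duplication_levels = character(),
                          keep_size_range = c(2, 3),
                          sample_fraction = 1, seed = 1,
                          annotate_species = character(),
                          drop_mode = c("sever", "remove"),
                          ortholog_requirement = c("per_gene", "per_group")) {
  drop_mode <- match.arg(drop_mode)
  ortholog_requirement <- match.arg(ortholog_requirement)
  if (keep_size_range[1] < 2) stop("keep_size_range min must be >= 2",
                                   call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  if (length(intersect(annotate_species,
                       c(focal_species, required_ortholog_taxa))))
    stop("annotate_species must not double as filter species", call. = FALSE)
  structure(list(focal_species = focal_species,
                 required_ortholog_taxa = required_ortholog_taxa,
                 required_paralogy_taxa = required_paralogy_taxa,
                 excluded_duplication_levels = excluded_duplication_levels,
                 keep_size_range = keep_size_range,
                 sample_fraction = sample_fraction, seed = as.integer(seed),
                 annotate_species = annotate_species, drop_mode = drop_mode,
                 ortholog_requirement = ortholog_requirement),
            class = "screen_config")
}

#' The five-criteria placozoan-anchored screen variant
#'
#' Alternate screen configuration anchored on the placozoan *Trichoplax
#' adhaerens*: genes must be paralogy-grouped in Trichoplax, have homologs
#' in the cnidarian *Nematostella vectensis* (which must themselves be
#' paralogy-grouped), in the lophotrochozoan *Lottia gigantea* and the
#' ecdysozoan *Drosophila melanogaster*, and in the demosponge *Amphimedon
#' queenslandica*.
#'
#' @return a [screen_config()].
#' @export
trichoplax_anchor_config <- function() {
  screen_config(
    focal_species = "Trichoplax_adhaerens",
    required_ortholog_taxa = c("Nematostella_vectensis", "Lottia_gigantea",
                               "Drosophila_melanogaster",
                               "Amphimedon_queenslandica"),
    required_paralogy_taxa = "Nematostella_vectensis",
    keep_size_range = c(2, Inf),
    sample_fraction = 1)
}

new_paralogy_groups <- function(edges, focal_species) {
  if (nrow(edges) == 0) {
    groups <- list()
  } else {
    gr <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                        directed = FALSE)
    comp <- igraph::components(gr)
    groups <- split(names(comp$membership), comp$membership)
    groups <- lapply(unname(groups), sort)
    groups <- groups[order(vapply(groups, `[`, "", 1))]
  }
  structure(list(groups = groups, edges = edges,
                 focal_species = focal_species),
            class = "paralogy_groups")
}

#' @export
print.paralogy_groups <- function(x, ...) {
  cat("<paralogy_groups>", length(x$groups), "groups,",
      length(unique(unlist(x$groups))), "genes (focal:", x$focal_species,
      ")\n")
  invisible(x)
}

#' Paralogy groups of a focal species
#'
#' Takes the within-species paralog records of the focal species, drops
#' those whose duplication level is excluded (too recent to bear on early
#' animal branching), and groups the remaining genes as connected components
#' of the surviving paralogy edges (the transitive closure of pairwise
#' paralogy). Genes left without any paralogy edge are discarded as
#' singletons.
#'
#' @param table a [homology_table()].
#' @param focal_species focal species name.
#' @param excluded_levels duplication levels to disregard.
#' @param drop_mode `"sever"` or `"remove"` (see [screen_config()]).
#' @return a `paralogy_groups` object.
#' @export
paralogy_groups <- function(table, focal_species,
                            excluded_levels = character(),
                            drop_mode = c("sever", "remove")) {
  drop_mode <- match.arg(drop_mode)
  stopifnot(inherits(table, "homology_table"))
  par <- table[table$relation == "within_species_paralog" &
                 table$species_a == focal_species, , drop = FALSE]
  if (drop_mode == "remove" && nrow(par)) {
    poisoned <- unique(c(
      par$gene_a[par$duplication_level %in% excluded_levels],
      par$gene_b[par$duplication_level %in% excluded_levels]))
    par <- par[!(par$gene_a %in% poisoned | par$gene_b %in% poisoned), ,
               drop = FALSE]
  }
  par <- par[!(par$duplication_level %in% excluded_levels), , drop = FALSE]
  new_paralogy_groups(par[c("gene_a", "gene_b", "duplication_level")],
                      focal_species)
}

# genes of `species` with >= 1 ortholog record against taxon `taxon`
ortholog_partners <- function(table, gene, taxon) {
  is_orth <- is_ortholog_relation(table$relation)
  c(table$gene_b[is_orth & table$gene_a == gene & table$species_b == taxon],
    table$gene_a[is_orth & table$gene_b == gene & table$species_a == taxon])
}

#' Require orthologs in anchor taxa
#'
#' A gene survives iff it has at least one ortholog record in every required
#' taxon (and, for `required_paralogy_taxa`, at least one such partner that
#' is itself in a within-species paralog relation). Groups are rebuilt as
#' connected components after gene removal. In `"per_group"` mode the
#' requirement is collective: a group survives iff each required taxon is
#' hit by at least one of its genes.
#'
#' @param groups a `paralogy_groups` object.
#' @param table the [homology_table()].
#' @param required_taxa species that must be hit.
#' @param mode `"per_gene"` (default) or `"per_group"`.
#' @param required_paralogy_taxa subset of taxa whose partners must be
#'   paralogy-grouped.
#' @return a filtered `paralogy_groups` object.
#' @export
require_orthologs <- function(groups, table, required_taxa,
                              mode = c("per_gene", "per_group"),
                              required_paralogy_taxa = character()) {
  mode <- match.arg(mode)
  stopifnot(inherits(groups, "paralogy_groups"))
  if (!length(required_taxa) && !length(required_paralogy_taxa))
    return(groups)
  universe <- unique(c(table$species_a, table$species_b))
  missing <- setdiff(c(required_taxa, required_paralogy_taxa), universe)
  if (length(missing))
    stop("required taxa absent from the table's species universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  paralog_genes <- unique(c(
    table$gene_a[table$relation == "within_species_paralog"],
    table$gene_b[table$relation == "within_species_paralog"]))
  gene_ok <- function(g, taxon) {
    p <- ortholog_partners(table, g, taxon)
    if (!length(p)) return(FALSE)
    if (taxon %in% required_paralogy_taxa) any(p %in% paralog_genes) else TRUE
  }
  taxa <- union(required_taxa, required_paralogy_taxa)
  genes <- unique(unlist(groups$groups))
  if (mode == "per_gene") {
    keep <- vapply(genes, function(g)
      all(vapply(taxa, gene_ok, logical(1), g = g)), logical(1))
    kept_genes <- genes[keep]
    edges <- groups$edges[groups$edges$gene_a %in% kept_genes &
                            groups$edges$gene_b %in% kept_genes, ,
                          drop = FALSE]
    new_paralogy_groups(edges, groups$focal_species)
  } else {
    keep_group <- vapply(groups$groups, function(gs)
      all(vapply(taxa, function(t)
        any(vapply(gs, gene_ok, logical(1), taxon = t)), logical(1))),
      logical(1))
    kept_genes <- unlist(groups$groups[keep_group])
    edges <- groups$edges[groups$edges$gene_a %in% kept_genes &
                            groups$edges$gene_b %in% kept_genes, ,
                          drop = FALSE]
    new_paralogy_groups(edges, groups$focal_species)
  }
}

#' Bin paralogy groups by size
#'
#' Splits groups into those within the kept size range (small, tractable
#' families) and the set-aside remainder (large expansions whose root-choice
#' ambiguity grows with size).
#'
#' @param groups a `paralogy_groups` object.
#' @param keep_range inclusive `[min, max]` sizes to keep.
#' @return list with `kept` (a `paralogy_groups`), `set_aside` (list of
#'   groups), `set_aside_sizes`, and `fraction_genes_set_aside`.
#' @export
bin_by_size <- function(groups, keep_range = c(2, 3)) {
  stopifnot(inherits(groups, "paralogy_groups"))
  sizes <- lengths(groups$groups)
  keep <- sizes >= keep_range[1] & sizes <= keep_range[2]
  kept_genes <- unlist(groups$groups[keep])
  edges <- groups$edges[groups$edges$gene_a %in% kept_genes &
                          groups$edges$gene_b %in% kept_genes, , drop = FALSE]
  total <- sum(sizes)
  list(kept = new_paralogy_groups(edges, groups$focal_species),
       set_aside = groups$groups[!keep],
       set_aside_sizes = sizes[!keep],
       fraction_genes_set_aside = if (total) sum(sizes[!keep]) / total else 0)
}

#' Sample paralogy groups without replacement
#'
#' Draws `floor(fraction * n)` groups by a seeded shuffle; deterministic for
#' a given seed, and the identity at `fraction = 1`.
#'
#' @param groups a `paralogy_groups` object.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return a `paralogy_groups` object holding the sample (original order).
#' @export
sample_groups <- function(groups, fraction, seed) {
  stopifnot(inherits(groups, "paralogy_groups"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  n <- length(groups$groups)
  m <- floor(fraction * n)
  idx <- sort(with_seed(seed, sample.int(n))[seq_len(m)])
  kept_genes <- unlist(groups$groups[idx])
  edges <- groups$edges[groups$edges$gene_a %in% kept_genes &
                          groups$edges$gene_b %in% kept_genes, , drop = FALSE]
  out <- new_paralogy_groups(edges, groups$focal_species)
  out$groups <- groups$groups[idx]
  out
}

#' Annotate sampled groups with sponge/ctenophore presence
#'
#' Pure annotation — no filtering: each group is flagged per annotation
#' species with whether any of its genes has an ortholog called there.
#' Groups missing at least one flagged species are labeled apparent-loss
#' candidates (a signature of gene loss, either true or false-positive).
#'
#' @param sample a `paralogy_groups` object (typically the screen sample).
#' @param table the [homology_table()].
#' @param annotate_species species to flag.
#' @return data.frame: one row per group with `group`, `size`, one
#'   `has_<species>` column per annotation species, and
#'   `apparent_loss_candidate`.
#' @export
annotate_presence <- function(sample, table, annotate_species) {
  stopifnot(inherits(sample, "paralogy_groups"))
  out <- data.frame(group = seq_along(sample$groups),
                    size = lengths(sample$groups))
  for (sp in annotate_species) {
    out[[paste0("has_", sp)]] <- vapply(sample$groups, function(gs)
      any(vapply(gs, function(g)
        length(ortholog_partners(table, g, sp)) > 0, logical(1))),
      logical(1))
  }
  flag_cols <- grep("^has_", names(out), value = TRUE)
  out$apparent_loss_candidate <- if (length(flag_cols))
    !apply(out[flag_cols], 1, all) else logical(nrow(out))
  out
}

#' Run the full screen cascade
#'
#' Applies, in order: paralogy grouping with excluded levels, the ortholog
#' requirement, size binning, seeded sampling, and presence annotation.
#' Stage gene counts are monotone non-increasing.
#'
#' @param table a [homology_table()].
#' @param config a [screen_config()].
#' @return a `screen_report`: list with `stage_counts`, `groups`, `kept`,
#'   `set_aside`, `sample`, `annotation`, `config`.
#' @export
run_screen <- function(table, config) {
  stopifnot(inherits(config, "screen_config"))
  focal_genes <- genes_of_species(table, config$focal_species)
  g1 <- paralogy_groups(table, config$focal_species,
                        config$excluded_duplication_levels, config$drop_mode)
  g2 <- require_orthologs(g1, table, config$required_ortholog_taxa,
                          config$ortholog_requirement,
                          config$required_paralogy_taxa)
  b <- bin_by_size(g2, config$keep_size_range)
  s <- sample_groups(b$kept, config$sample_fraction, config$seed)
  ann <- annotate_presence(s, table, config$annotate_species)
  counts <- c(focal = length(focal_genes),
              in_paralogy_groups = length(unique(unlist(g1$groups))),
              with_required_orthologs = length(unique(unlist(g2$groups))),
              in_kept_size_range = length(unique(unlist(b$kept$groups))),
              sampled = length(unique(unlist(s$groups))))
  structure(list(stage_counts = counts, groups = g1, filtered = g2,
                 kept = b$kept, set_aside = b$set_aside,
                 set_aside_sizes = b$set_aside_sizes, sample = s,
                 annotation = ann, config = config),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> cascade gene counts:\n")
  print(x$stage_counts)
  cat(length(x$sample$groups), "groups sampled (",
      sum(x$annotation$apparent_loss_candidate),
      "apparent-loss candidates )\n")
  invisible(x)
}

#' Write a screen report to disk
#'
#' Emits `report.json` (stage counts, config, annotation) and
#' `groups.tsv` (group membership) under `dir`.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stage_counts = as.list(report$stage_counts),
         n_groups_sampled = length(report$sample$groups),
         set_aside_sizes = report$set_aside_sizes,
         annotation = report$annotation,
         config = unclass(report$config)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  mem <- data.frame(
    group = rep(seq_along(report$sample$groups),
                lengths(report$sample$groups)),
    gene = unlist(report$sample$groups))
  utils::write.table(mem, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
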