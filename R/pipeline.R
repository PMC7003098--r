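#' Pipeline configuration
#'
#' One global seed drives deterministic per-stage sub-seeds (stage-index
#' hashing), so a full run is reproducible from a single knob.
#'
#' @param stages subset of `c("simulate", "screen", "infer", "classify",
#'   "miscall")`, executed in this canonical order.
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param n_families number of synthetic families.
#' @param sim named list of [sim_config()] overrides (e.g. `lambda`, `r1`).
#' @param screen named list of [screen_config()] overrides.
#' @param infer list: `bootstrap` (replicates, 0 = none), `correction`.
#' @param miscall list: `assumed` hypothesis, `use_nj`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "screen", "infer",
                                       "classify", "miscall"),
                            seed, out_dir, n_families = 20,
                            sim = list(), screen = list(),
                            infer = list(bootstrap = 0,
                                         correction = "poisson"),
                            miscall = list(assumed = "sponge_early",
                                           use_nj = TRUE)) {
  order_ <- c("simulate", "screen", "infer", "classify", "miscall")
  stages <- order_[order_ %in% match.arg(stages, order_, several.ok = TRUE)]
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(stages = stages, seed = as.integer(seed), out_dir = out_dir,
                 n_families = n_families, sim = sim, screen = screen,
                 infer = infer, miscall = miscall),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order — simulate gene families, screen
#' the pooled truth-derived homology table, infer NJ trees, classify each
#' family's duplication timing against both rooting hypotheses, and run the
#' forced-rooting miscall experiment — writing every artifact plus a
#' manifest (inputs, seeds, package version) under `out_dir`. Reruns with
#' an identical configuration produce byte-identical manifests.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_bundle`: list of stage results and artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = cfg, artifacts = character())
  manifest <- list(seed = cfg$seed, stages = list(),
                   version = as.character(utils::packageVersion("dupliphy")))
  base_sim <- function(i, stage_seed) {
    args <- cfg$sim
    args$seed <- derive_seed(stage_seed, i)
    args$family_id <- sprintf("fam%03d", i)
    do.call(sim_config, args)
  }
  need_upstream <- function(field, stage) {
    if (is.null(bundle[[field]]))
      stop("stage '", stage, "' needs upstream artifact '", field,
           "' — run the simulate stage first", call. = FALSE)
  }

  for (stage in cfg$stages) {
    sseed <- derive_seed(cfg$seed, match(stage, c("simulate", "screen",
                                                  "infer", "classify",
                                                  "miscall")))
    if (stage == "simulate") {
      dir.create(file.path(cfg$out_dir, "simulate"), showWarnings = FALSE)
      fams <- lapply(seq_len(cfg$n_families), function(i) {
        sc <- base_sim(i, sseed)
        hist <- simulate_family(sc)
        aln <- evolve_sequences(hist, sc)
        list(config = sc, history = hist, alignment = aln,
             truth = homology_table_from_truth(hist))
      })
      for (f in fams) {
        stem <- file.path(cfg$out_dir, "simulate", f$config$family_id)
        write_newick(f$history$tree, paste0(stem, ".nwk"))
        write_alignment(f$alignment, paste0(stem, ".fas"))
      }
      pooled <- homology_table(do.call(rbind, lapply(fams, function(f)
        as.data.frame(f$truth))))
      write_homology_table(pooled, file.path(cfg$out_dir, "simulate",
                                             "homology.tsv"))
      jsonlite::write_json(
        lapply(fams, function(f) list(
          family = f$config$family_id,
          n_genes = n_tips(f$history$tree),
          events = f$history$events)),
        file.path(cfg$out_dir, "simulate", "events.json"),
        auto_unbox = TRUE, digits = NA)
      bundle$families <- fams
      bundle$homology <- pooled
      bundle$scheme <- fams[[1]]$history$scheme
      manifest$stages$simulate <- list(seed = sseed,
                                       n_families = length(fams))
    } else if (stage == "screen") {
      need_upstream("homology", stage)
      args <- cfg$screen
      if (is.null(args$focal_species)) {
        sch <- bundle$scheme
        args$focal_species <-
          names(sch$phylum_of)[sch$phylum_of == "B"][1]
      }
      if (is.null(args$seed)) args$seed <- sseed
      rep_ <- run_screen(bundle$homology, do.call(screen_config, args))
      write_screen_report(rep_, file.path(cfg$out_dir, "screen"))
      bundle$screen <- rep_
      manifest$stages$screen <- list(seed = args$seed,
                                     counts = as.list(rep_$stage_counts))
    } else if (stage == "infer") {
      need_upstream("families", stage)
      dir.create(file.path(cfg$out_dir, "infer"), showWarnings = FALSE)
      trees <- lapply(seq_along(bundle$families), function(i) {
        f <- bundle$families[[i]]
        tr <- if ((cfg$infer$bootstrap %||% 0) >= 1)
          nj_bootstrap(f$alignment, cfg$infer$bootstrap,
                       derive_seed(sseed, i),
                       correction = cfg$infer$correction %||% "poisson")
        else neighbor_joining(poisson_correct(p_distance(f$alignment)))
        write_newick(tr, file.path(cfg$out_dir, "infer",
                                   paste0(f$config$family_id, ".nwk")))
        tr
      })
      bundle$inferred <- trees
      manifest$stages$infer <- list(seed = sseed, n_trees = length(trees))
    } else if (stage == "classify") {
      need_upstream("families", stage)
      f1 <- bundle$families[[1]]$config
      hyp <- default_species_trees(f1$n_per_phylum, f1$n_choanoflagellate,
                                   f1$n_outgroup)
      trees <- bundle$inferred %||%
        lapply(bundle$families, function(f) f$history$tree)
      cls <- lapply(seq_along(trees), function(i)
        classify_family(trees[[i]], bundle$scheme,
                        hyp[c("sponge_early", "ctenophore_early")]))
      names(cls) <- vapply(bundle$families, function(f) f$config$family_id, "")
      jsonlite::write_json(
        lapply(cls, function(x) list(category = x$category,
                                     per_rooting = x$per_rooting)),
        file.path(cfg$out_dir, "classify.json"), auto_unbox = TRUE,
        digits = NA)
      bundle$classification <- cls
      manifest$stages$classify <-
        list(tally = as.list(table(vapply(cls, `[[`, "", "category"))))
    } else if (stage == "miscall") {
      sim_args <- cfg$sim; sim_args$seed <- 0L
      base <- do.call(sim_config, sim_args)
      res <- run_experiment(base, cfg$miscall$assumed %||% "sponge_early",
                            n_families = cfg$n_families, seed = sseed,
                            use_nj = cfg$miscall$use_nj %||% TRUE)
      jsonlite::write_json(
        list(coverage = as.data.frame(res$coverage),
             deficit_gap = as.list(res$deficit_gap),
             false_loss_rate = as.list(res$false_loss_rate),
             n_families = res$n_families, n_skipped = res$n_skipped),
        file.path(cfg$out_dir, "miscall.json"), auto_unbox = TRUE,
        digits = NA)
      bundle$miscall <- res
      manifest$stages$miscall <- list(seed = sseed,
                                      n_families = res$n_families)
    }
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  bundle$artifacts <- list.files(cfg$out_dir, recursive = TRUE)
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Render a human-readable pipeline summary
#'
#' Tabulates the screen cascade counts, the classification category tally,
#' and the miscall statistics of a pipeline bundle. An empty bundle renders
#' an empty-but-valid summary.
#'
#' @param bundle a `pipeline_bundle` (or any list with the same fields).
#' @return character vector of report lines (also printed invisibly).
#' @export
render_report <- function(bundle) {
  lines <- c("== dupliphy pipeline report ==")
  if (!is.null(bundle$screen)) {
    lines <- c(lines, "", "Screen cascade (gene counts):",
               paste0("  ", names(bundle$screen$stage_counts), ": ",
                      bundle$screen$stage_counts))
  }
  if (!is.null(bundle$classification)) {
    tal <- table(vapply(bundle$classification, `[[`, "", "category"))
    lines <- c(lines, "", "Family classification tally:",
               paste0("  ", names(tal), ": ", as.integer(tal)),
               paste0("  total: ", sum(tal)))
  }
  if (!is.null(bundle$miscall)) {
    m <- bundle$miscall
    lines <- c(lines, "", "Miscall experiment:",
               paste0("  families: ", m$n_families, " (skipped ",
                      m$n_skipped, ")"),
               paste0("  deficit gap [", names(m$deficit_gap), "]: ",
                      round(m$deficit_gap, 2)),
               paste0("  false-loss rate [", names(m$false_loss_rate), "]: ",
                      signif(m$false_loss_rate, 3)))
  }
  if (length(lines) == 1) lines <- c(lines, "(empty bundle)")
  lines
}
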