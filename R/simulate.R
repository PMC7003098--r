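#' Default competing species hypotheses for early animal branching
#'
#' Builds the two rooted species trees at the heart of the early-metazoan
#' rooting controversy over a shared species set: *sponge-early*
#' `(Po,(Ct,(Pl,(Cn,B))))`, where the clade Ctenophora + Eumetazoa is named
#' Neuralia, and *ctenophore-early* `(Ct,(Po,(Pl,(Cn,B))))`, where the clade
#' Porifera + Eumetazoa is named Benthozoa. Trees are ultrametric in time
#' units of expected substitutions/site: phylum stems attach at depths 1.0,
#' 0.8, 0.6 and 0.4; within-phylum diversification happens below depth 0.2.
#' Optional choanoflagellate (depth 1.3) and deeper outgroup (depth 1.6)
#' lineages provide rooting outgroups.
#'
#' @param n_per_phylum named integer vector of species counts for phyla
#'   `B`, `Cn`, `Pl`, `Ct`, `Po` (all required, each >= 1).
#' @param n_choanoflagellate,n_outgroup species counts for the outgroup
#'   lineages (0 = absent).
#' @return list with elements `sponge_early`, `ctenophore_early` (rooted
#'   `phylo` trees with named internal nodes) and `scheme` (a
#'   [clade_scheme()] covering the shared species set).
#' @examples
#' h <- default_species_trees()
#' write_newick(h$ctenophore_early)
#' @export
default_species_trees <- function(n_per_phylum = c(B = 1, Cn = 1, Pl = 1,
                                                   Ct = 1, Po = 1),
                                  n_choanoflagellate = 0, n_outgroup = 0) {
  need <- c("B", "Cn", "Pl", "Ct", "Po")
  if (!all(need %in% names(n_per_phylum)) || any(n_per_phylum[need] < 1))
    stop("n_per_phylum must name B, Cn, Pl, Ct, Po with counts >= 1",
         call. = FALSE)
  crown <- 0.2
  phylum_full <- c(B = "Bilateria", Cn = "Cnidaria", Pl = "Placozoa",
                   Ct = "Ctenophora", Po = "Porifera",
                   Cf = "Choanoflagellatea", Og = "Outgroup")
  # ladder clade of k species of one phylum, attached at `height`
  clade_nwk <- function(prefix, k, height) {
    sp <- paste0(prefix, seq_len(k))
    if (k == 1) return(paste0(sp, ":", height))
    hs <- crown * seq(k - 1, 1) / (k - 1)  # split heights, crown downward
    s <- paste0(sp[k], ":", hs[k - 1])
    for (i in seq(k - 1, 1)) {
      h_up <- if (i == 1) height else hs[i - 1]
      lab <- if (i == 1) phylum_full[[prefix]] else
        paste0(phylum_full[[prefix]], "_", i)
      s <- paste0("(", sp[i], ":", hs[i], ",", s, ")", lab, ":",
                  h_up - hs[i])
    }
    s
  }
  k <- n_per_phylum
  cnb <- paste0("(", clade_nwk("Cn", k[["Cn"]], 0.4), ",",
                clade_nwk("B", k[["B"]], 0.4), ")CnidariaBilateria:0.2")
  eum <- paste0("(", clade_nwk("Pl", k[["Pl"]], 0.6), ",", cnb,
                ")Eumetazoa:0.2")
  core <- function(first, second, inner_name) {
    paste0("(", clade_nwk(first, k[[first]], 1.0), ",(",
           clade_nwk(second, k[[second]], 0.8), ",", eum, ")",
           inner_name, ":0.2)Metazoa")
  }
  sponge_early <- core("Po", "Ct", "Neuralia")
  cteno_early <- core("Ct", "Po", "Benthozoa")
  wrap_outgroups <- function(s) {
    if (n_choanoflagellate > 0)
      s <- paste0("(", clade_nwk("Cf", n_choanoflagellate, 1.3), ",", s,
                  ":0.3)Choanozoa")
    if (n_outgroup > 0)
      s <- paste0("(", clade_nwk("Og", n_outgroup, 1.6), ",", s, ":",
                  if (n_choanoflagellate > 0) 0.3 else 0.6, ")Opisthokonta")
    read_newick(text = paste0(s, ";"))
  }
  sp_names <- c(
    stats::setNames(rep("Po", k[["Po"]]), paste0("Po", seq_len(k[["Po"]]))),
    stats::setNames(rep("Ct", k[["Ct"]]), paste0("Ct", seq_len(k[["Ct"]]))),
    stats::setNames(rep("Pl", k[["Pl"]]), paste0("Pl", seq_len(k[["Pl"]]))),
    stats::setNames(rep("Cn", k[["Cn"]]), paste0("Cn", seq_len(k[["Cn"]]))),
    stats::setNames(rep("B", k[["B"]]), paste0("B", seq_len(k[["B"]]))))
  if (n_choanoflagellate > 0)
    sp_names <- c(sp_names, stats::setNames(
      rep("Choanoflagellatea", n_choanoflagellate),
      paste0("Cf", seq_len(n_choanoflagellate))))
  if (n_outgroup > 0)
    sp_names <- c(sp_names, stats::setNames(
      rep("Outgroup", n_outgroup), paste0("Og", seq_len(n_outgroup))))
  list(sponge_early = wrap_outgroups(sponge_early),
       ctenophore_early = wrap_outgroups(cteno_early),
       scheme = clade_scheme(sp_names))
}

#' Simulation configuration for synthetic gene families
#'
#' Parametrizes the generative model: gene lineages evolve down a rooted
#' species hypothesis; *planted* duplications fire deterministically at a
#' stated relative position on a named species-tree edge (the edge is named
#' by the node below it; the root name refers to an implicit stem edge of
#' length `stem_length` above the root, so a stem-Metazoa duplication works
#' on metazoan-only trees); stochastic duplications and losses follow a
#' birth-death process with per-gene rates `lambda` and `mu` per unit branch
#' length; after the first planted duplication, its two descendant paralog
#' clades evolve at rate multipliers `r1` and `r2` (divergent
#' functionalization). Amino-acid sequences evolve by a 20-state
#' uniform-exchange substitution process, optionally with the target
#' composition `bias_target` mixed in with weight `bias_weight` on branches
#' inside `bias_phylum`.
#'
#' @param hypothesis `"ctenophore_early"` or `"sponge_early"` — the TRUE
#'   world the family evolves in.
#' @param n_per_phylum species counts per phylum (see
#'   [default_species_trees()]).
#' @param n_choanoflagellate,n_outgroup outgroup species counts.
#' @param planted data.frame with columns `edge` (species-tree node name
#'   below the edge) and `pos` (relative position in (0,1)).
#' @param lambda,mu birth (duplication) and death (loss) rates per gene per
#'   unit branch length; both >= 0.
#' @param r1,r2 rate multipliers (> 0) for the two clades descending from
#'   the first planted duplication.
#' @param seq_length sites in the simulated protein (>= 1).
#' @param model `"poisson_uniform"` (default) or `"empirical_matrix"`.
#' @param empirical_matrix path to a PAML-format rate matrix when
#'   `model = "empirical_matrix"`.
#' @param bias_phylum,bias_target,bias_weight optional compositional bias: a
#'   phylum label, a 20-vector of target frequencies, and a mixing weight in
#'   `[0, 1]`.
#' @param stem_length length of the implicit stem edge above the species
#'   root.
#' @param family_id identifier used in gene names `"Species|<id>_c<M>"`.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(hypothesis = c("ctenophore_early", "sponge_early"),
                       n_per_phylum = c(B = 1, Cn = 1, Pl = 1, Ct = 1, Po = 1),
                       n_choanoflagellate = 0, n_outgroup = 0,
                       planted = data.frame(edge = "Metazoa", pos = 0.5),
                       lambda = 0, mu = 0, r1 = 3, r2 = 1,
                       seq_length = 1000,
                       model = c("poisson_uniform", "empirical_matrix"),
                       empirical_matrix = NULL,
                       bias_phylum = NULL, bias_target = NULL,
                       bias_weight = 0,
                       stem_length = 0.3, family_id = "fam1", seed) {
  hypothesis <- match.arg(hypothesis)
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (lambda < 0 || mu < 0) stop("lambda and mu must be >= 0", call. = FALSE)
  if (r1 <= 0 || r2 <= 0) stop("r1 and r2 must be > 0", call. = FALSE)
  if (seq_length < 1) stop("seq_length must be >= 1", call. = FALSE)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("edge", "pos") %in% names(planted)))
    if (any(planted$pos <= 0 | planted$pos >= 1))
      stop("planted positions must lie strictly inside (0,1)", call. = FALSE)
  } else planted <- data.frame(edge = character(), pos = numeric())
  if (!is.null(bias_target)) {
    stopifnot(length(bias_target) == 20, all(bias_target >= 0))
    bias_target <- bias_target / sum(bias_target)
  }
  structure(list(hypothesis = hypothesis, n_per_phylum = n_per_phylum,
                 n_choanoflagellate = n_choanoflagellate,
                 n_outgroup = n_outgroup, planted = planted,
                 lambda = lambda, mu = mu, r1 = r1, r2 = r2,
                 seq_length = seq_length, model = model,
                 empirical_matrix = empirical_matrix,
                 bias_phylum = bias_phylum, bias_target = bias_target,
                 bias_weight = bias_weight, stem_length = stem_length,
                 family_id = family_id, seed = as.integer(seed)),
            class = "sim_config")
}

# species-tree node names whose descendant leaves all belong to `phylum`
nodes_under_phylum <- function(stree, scheme, phylum) {
  tips <- descendant_tips(stree)
  ids <- species_node_ids(stree)
  nm <- names(ids)
  keep <- vapply(ids, function(i)
    all(phylum_of(scheme, tips[[i]]) == phylum), logical(1))
  nm[keep & nzchar(nm)]
}

#' Simulate one gene family along a species hypothesis
#'
#' Runs the generative process described in [sim_config()]: one gene lineage
#' enters the stem above the species root; every speciation splits every
#' live lineage; planted duplications duplicate every live lineage at their
#' stated point; stochastic duplications and losses fire as a Poisson
#' process; losses prune the affected sublineage. A family extinct in all
#' species (< 2 surviving genes) is resampled by continuing the random
#' stream, up to 100 retries. True gene-tree branch lengths are time
#' multiplied by the branch's clade rate multiplier, i.e. expected
#' substitutions/site.
#'
#' @param cfg a [sim_config()].
#' @param species_tree optional rooted `phylo`; defaults to the tree for
#'   `cfg$hypothesis` from [default_species_trees()].
#' @param scheme optional [clade_scheme()] matching `species_tree`.
#' @return a `true_history`: list with `tree` (rooted binary `phylo`, leaves
#'   `"Species|fam_cM"`, internal labels `"n<k>"`), `events` (data.frame:
#'   `label`, `type`, `level`), `branch_rate` and `branch_time` (named by
#'   child label), `species_context` (species-tree node name below each
#'   branch, named by child label), `species_tree`, `scheme`, `config`,
#'   `retries`.
#' @export
simulate_family <- function(cfg, species_tree = NULL, scheme = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(species_tree)) {
    h <- default_species_trees(cfg$n_per_phylum, cfg$n_choanoflagellate,
                               cfg$n_outgroup)
    species_tree <- h[[cfg$hypothesis]]
    scheme <- h$scheme
  }
  if (is.null(scheme))
    stop("`scheme` is required when `species_tree` is supplied", call. = FALSE)
  ids <- species_node_ids(species_tree)
  known <- names(ids)[nzchar(names(ids))]
  bad <- setdiff(cfg$planted$edge, known)
  if (length(bad))
    stop("planted edge name(s) absent from species tree: ",
         paste(bad, collapse = ", "), call. = FALSE)
  with_seed(derive_seed(cfg$seed, 1L), {
    for (try in seq_len(100L)) {
      hist <- sim_family_once(cfg, species_tree, scheme)
      if (!is.null(hist)) {
        hist$retries <- try - 1L
        return(hist)
      }
    }
    stop("family went extinct in 100 consecutive attempts", call. = FALSE)
  })
}

# one attempt; NULL if < 2 genes survive
sim_family_once <- function(cfg, stree, scheme) {
  nt <- n_tips(stree)
  ch <- children_list(stree)
  root_id <- nt + 1L
  node_name <- c(stree$tip.label,
                 if (is.null(stree$node.label)) rep("", stree$Nnode)
                 else stree$node.label)
  edge_len <- numeric(nt + stree$Nnode)
  edge_len[stree$edge[, 2]] <- stree$edge.length
  edge_len[root_id] <- cfg$stem_length
  rate_total <- cfg$lambda + cfg$mu

  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$parent <- integer(); env$tlen <- numeric(); env$type <- character()
  env$sref <- character(); env$plant <- integer()
  env$losses <- list()
  new_node <- function(parent, type, sref, tlen, plant = NA_integer_) {
    env$n <- env$n + 1L
    env$parent[env$n] <- parent; env$type[env$n] <- type
    env$sref[env$n] <- sref; env$tlen[env$n] <- tlen
    env$plant[env$n] <- plant
    env$n
  }

  sim_edge <- function(parent_gid, t_start, sp_node) {
    len <- edge_len[sp_node]
    nm <- node_name[sp_node]
    pl <- cfg$planted[cfg$planted$edge == nm, , drop = FALSE]
    pl_pos <- sort(pl$pos * len)
    ord <- order(pl$pos)  # pair sorted positions with global planted indices
    pl_global <- which(cfg$planted$edge == nm)[ord]
    t <- t_start
    branch_start <- t_start
    repeat {
      nxt <- which(pl_pos > t + 1e-12)
      seg_end <- if (length(nxt)) pl_pos[nxt[1]] else len
      dt <- if (rate_total > 0) stats::rexp(1, rate_total) else Inf
      if (t + dt < seg_end) {
        t <- t + dt
        if (stats::runif(1) * rate_total < cfg$lambda) {
          gid <- new_node(parent_gid, "duplication", nm, t - branch_start)
          sim_edge(gid, t, sp_node); sim_edge(gid, t, sp_node)
        } else {
          env$losses[[length(env$losses) + 1L]] <- nm
          new_node(parent_gid, "loss", nm, t - branch_start)
        }
        return(invisible())
      }
      if (length(nxt)) {  # planted duplication
        t <- seg_end
        gid <- new_node(parent_gid, "duplication", nm, t - branch_start,
                        plant = pl_global[nxt[1]])
        sim_edge(gid, t, sp_node); sim_edge(gid, t, sp_node)
        return(invisible())
      }
      break
    }
    # reached the bottom of the edge
    if (sp_node <= nt) {
      new_node(parent_gid, "tip", node_name[sp_node], len - branch_start)
    } else {
      gid <- new_node(parent_gid, "speciation", nm, len - branch_start)
      for (k in ch[[sp_node]]) sim_edge(gid, 0, k)
    }
    invisible()
  }

  origin <- new_node(0L, "origin", node_name[root_id], 0)
  sim_edge(origin, 0, root_id)

  if (sum(env$type == "tip") < 2L) return(NULL)

  # children in creation order
  kids <- vector("list", env$n)
  for (i in seq_len(env$n)) if (env$parent[i] > 0L)
    kids[[env$parent[i]]] <- c(kids[[env$parent[i]]], i)

  # clade rate multipliers from the first planted duplication
  rate <- rep(1, env$n)
  focal <- which(!is.na(env$plant) & env$plant == 1L)
  if (length(focal)) {
    focal <- focal[1]
    assign_rate <- function(gid, r) {
      rate[gid] <<- r
      for (k in kids[[gid]]) assign_rate(k, r)
    }
    fk <- kids[[focal]]
    if (length(fk) >= 1) assign_rate(fk[1], cfg$r1)
    if (length(fk) >= 2) assign_rate(fk[2], cfg$r2)
  }

  # prune losses, splice unary nodes; glen = time x rate
  collapse <- function(gid) {
    gl <- env$tlen[gid] * rate[gid]
    tl <- env$tlen[gid]
    if (env$type[gid] == "loss") return(NULL)
    if (env$type[gid] == "tip")
      return(list(id = gid, glen = gl, tlen = tl, children = NULL))
    sub <- Filter(Negate(is.null), lapply(kids[[gid]], collapse))
    if (!length(sub)) return(NULL)
    if (length(sub) == 1L) {
      s <- sub[[1]]
      s$glen <- s$glen + gl; s$tlen <- s$tlen + tl
      return(s)
    }
    list(id = gid, glen = gl, tlen = tl, children = sub)
  }
  top <- collapse(origin)
  if (is.null(top) || is.null(top$children)) return(NULL)

  # emit newick; name tips per species in traversal order
  copy_count <- new.env(parent = emptyenv())
  tip_label <- character(env$n)
  emit <- function(node) {
    if (is.null(node$children)) {
      sp <- env$sref[node$id]
      m <- (get0(sp, envir = copy_count, ifnotfound = 0L)) + 1L
      assign(sp, m, envir = copy_count)
      lab <- paste0(sp, "|", cfg$family_id, "_c", m)
      tip_label[node$id] <<- lab
      paste0(lab, ":", format(node$glen, digits = 12))
    } else {
      paste0("(", paste(vapply(node$children, emit, ""), collapse = ","),
             ")n", node$id, ":", format(node$glen, digits = 12))
    }
  }
  nwk <- paste0(sub(":[^:]*$", "", emit(top)), ";")
  tree <- read_newick(text = nwk)

  # per-branch bookkeeping keyed by child label
  lab_of <- function(node) if (is.null(node$children))
    tip_label[node$id] else paste0("n", node$id)
  branch_rate <- c(); branch_time <- c(); sctx <- c()
  focal_label <- NA_character_
  walk <- function(node) {
    lb <- lab_of(node)
    branch_rate[lb] <<- if (node$tlen > 0) node$glen / node$tlen else 1
    branch_time[lb] <<- node$tlen
    sctx[lb] <<- env$sref[node$id]
    if (length(focal) && node$id == focal && !is.null(node$children))
      focal_label <<- lb
    for (k in node$children %||% list()) walk(k)
  }
  walk(top)

  ev_idx <- which(env$type %in% c("speciation", "duplication"))
  events <- data.frame(label = paste0("n", ev_idx),
                       type = env$type[ev_idx],
                       level = env$sref[ev_idx], stringsAsFactors = FALSE)
  if (length(env$losses))
    events <- rbind(events, data.frame(label = NA_character_, type = "loss",
                                       level = unlist(env$losses)))
  structure(list(tree = tree, events = events, branch_rate = branch_rate,
                 branch_time = branch_time, species_context = sctx,
                 focal_duplication = focal_label,
                 species_tree = stree, scheme = scheme, config = cfg),
            class = "true_history")
}

#' @export
print.true_history <- function(x, ...) {
  cat("<true_history>", n_tips(x$tree), "surviving genes;",
      sum(x$events$type == "duplication"), "duplications,",
      sum(x$events$type == "loss"), "losses\n")
  invisible(x)
}

# event type of an internal node of a true tree, by label
true_event_type <- function(history, label) {
  i <- match(label, history$events$label)
  ifelse(is.na(i), NA_character_, history$events$type[i])
}
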