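#' Read a PAML-format empirical amino-acid rate matrix
#'
#' Expects the standard layout: 19 lines of lower-triangular exchangeability
#' coefficients followed by a line (or lines) of 20 equilibrium frequencies,
#' in PAML amino-acid order (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @param path matrix file.
#' @return list with `Q` (20x20 generator scaled to one expected
#'   substitution per unit time, rows/cols in this package's alphabetical
#'   residue order) and `pi` (equilibrium frequencies).
#' @export
read_paml_matrix <- function(path) {
  toks <- scan(path, what = double(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 190 + 20)
    stop("malformed PAML rate matrix: expected 190 exchangeabilities + 20 frequencies",
         call. = FALSE)
  paml_order <- c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V")
  S <- matrix(0, 20, 20, dimnames = list(paml_order, paml_order))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- toks[k]; k <- k + 1L
  }
  pi <- toks[k:(k + 19L)]
  if (abs(sum(pi) - 1) > 1e-3)
    stop("malformed PAML rate matrix: frequencies do not sum to 1",
         call. = FALSE)
  pi <- pi / sum(pi)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  ord <- match(AA_ALPHABET, paml_order)
  list(Q = Q[ord, ord], pi = stats::setNames(pi[ord], AA_ALPHABET))
}

# equilibrium-resampling substitution model: a site substitutes iff it sees
# >= 1 event (rate 20/19 per unit length for the uniform model, so a unit
# branch carries one expected substitution), and the post-event state is a
# fresh draw from the branch's target frequencies.
evolve_branch_uniform <- function(seq, glen, freqs) {
  p_event <- 1 - exp(-glen * 20 / 19)
  hit <- stats::runif(length(seq)) < p_event
  if (any(hit))
    seq[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE, prob = freqs)
  seq
}

evolve_branch_matrix <- function(seq, glen, eig) {
  P <- eig$vectors %*% diag(exp(eig$values * glen)) %*% eig$inv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  out <- seq
  for (a in unique(seq)) {
    idx <- which(seq == a)
    out[idx] <- sample(AA_ALPHABET, length(idx), replace = TRUE,
                       prob = P[match(a, AA_ALPHABET), ])
  }
  out
}

#' Evolve amino-acid sequences along a true gene tree
#'
#' The root sequence is drawn from the model equilibrium; sequences then
#' evolve down the tree by a continuous-time substitution process over the
#' branch lengths of the true gene tree (which already include the clade
#' rate multipliers, see [simulate_family()]). Under the default uniform
#' model, the per-branch probability that a site substitutes has the closed
#' form `(19/20) * (1 - exp(-(20/19) * l))`. Compositional bias mixes
#' `bias_target` into the resampling frequencies, with weight `bias_weight`,
#' on every branch whose species context lies inside `bias_phylum`.
#'
#' @param history a `true_history` from [simulate_family()].
#' @param cfg the [sim_config()] (defaults to the one inside `history`).
#' @return an ungapped [aa_alignment()], one row per surviving gene.
#' @export
evolve_sequences <- function(history, cfg = history$config) {
  stopifnot(inherits(history, "true_history"))
  tree <- history$tree
  if (n_tips(tree) < 2) stop("need >= 2 leaves", call. = FALSE)
  L <- cfg$seq_length
  eig <- NULL; pi0 <- rep(1 / 20, 20)
  if (cfg$model == "empirical_matrix") {
    if (is.null(cfg$empirical_matrix))
      stop("empirical_matrix path required", call. = FALSE)
    m <- read_paml_matrix(cfg$empirical_matrix)
    ev <- eigen(m$Q)
    eig <- list(vectors = ev$vectors, values = ev$values,
                inv = solve(ev$vectors))
    pi0 <- m$pi
    if (!is.null(cfg$bias_phylum) && cfg$bias_weight > 0)
      stop("compositional bias is only supported under the uniform model",
           call. = FALSE)
  }
  biased_refs <- if (!is.null(cfg$bias_phylum) && cfg$bias_weight > 0) {
    c(nodes_under_phylum(history$species_tree, history$scheme,
                         cfg$bias_phylum))
  } else character()
  mix <- if (length(biased_refs))
    (1 - cfg$bias_weight) * rep(1 / 20, 20) + cfg$bias_weight * cfg$bias_target
  else NULL

  nt <- n_tips(tree)
  labels <- c(tree$tip.label, tree$node.label)
  with_seed(derive_seed(cfg$seed, 2L), {
    seqs <- vector("list", nt + tree$Nnode)
    root <- nt + 1L
    seqs[[root]] <- sample(AA_ALPHABET, L, replace = TRUE, prob = pi0)
    tro <- ape::reorder.phylo(tree, "cladewise")
    eo <- tro$edge; el <- tro$edge.length
    for (i in seq_len(nrow(eo))) {
      child <- eo[i, 2]
      ctx <- history$species_context[[labels[child]]]
      freqs <- if (!is.null(mix) && !is.null(ctx) && !is.na(ctx) &&
                   ctx %in% biased_refs) mix else rep(1 / 20, 20)
      seqs[[child]] <- if (cfg$model == "poisson_uniform")
        evolve_branch_uniform(seqs[[eo[i, 1]]], el[i], freqs)
      else evolve_branch_matrix(seqs[[eo[i, 1]]], el[i], eig)
    }
    m <- do.call(rbind, seqs[seq_len(nt)])
    rownames(m) <- tree$tip.label
    aa_alignment(m)
  })
}

#' Derive a noiseless homology table from a true history
#'
#' Emulates Compara orthology calls from the known truth: a cross-species
#' gene pair is an ortholog iff its gene-tree LCA is a speciation event;
#' within-species pairs are `within_species_paralog` with
#' `duplication_level` equal to the species-tree node naming the edge that
#' hosts their LCA duplication. One2one/one2many/many2many subtypes are
#' assigned by reciprocal ortholog counting (the `gene_a` column holds the
#' "one" side of a one2many record).
#'
#' @param history a `true_history`.
#' @return a [homology_table()].
#' @export
homology_table_from_truth <- function(history) {
  stopifnot(inherits(history, "true_history"))
  labels_to_events <- stats::setNames(history$events$type, history$events$label)
  table_from_labeled_tree(history$tree, labels_to_events,
                          stats::setNames(history$events$level,
                                          history$events$label))
}

# shared engine: build a homology table from a rooted gene tree whose
# internal node labels map to event types ("speciation"/"duplication") and,
# for duplications, to a duplication level.
table_from_labeled_tree <- function(tree, event_of, level_of) {
  nt <- n_tips(tree)
  tips <- descendant_tips(tree)
  sp <- split_leaf_labels(tree$tip.label)
  species_of_label <- stats::setNames(sp$species, sp$label)
  pairs <- list()
  kids <- children_list(tree)
  for (v in postorder_internal(tree)) {
    lab <- tree$node.label[v - nt]
    evt <- unname(event_of[lab])
    if (is.na(evt)) stop("internal node without event label: ", lab,
                         call. = FALSE)
    chv <- kids[[v]]
    if (length(chv) != 2) stop("gene tree must be binary", call. = FALSE)
    a <- tips[[chv[1]]]; b <- tips[[chv[2]]]
    grid <- expand.grid(ga = a, gb = b, stringsAsFactors = FALSE)
    grid$evt <- evt
    grid$level <- if (evt == "duplication") unname(level_of[lab]) else ""
    pairs[[length(pairs) + 1L]] <- grid
  }
  pr <- do.call(rbind, pairs)
  pr$sa <- species_of_label[pr$ga]; pr$sb <- species_of_label[pr$gb]
  orth <- pr[pr$evt == "speciation" & pr$sa != pr$sb, , drop = FALSE]
  par_ <- pr[pr$evt == "duplication" & pr$sa == pr$sb, , drop = FALSE]

  rows <- list()
  if (nrow(orth)) {
    # reciprocal counts: number of ortholog partners of each gene in each species
    cnt <- function(g, s) sum((orth$ga == g & orth$sb == s) |
                              (orth$gb == g & orth$sa == s))
    na <- mapply(cnt, orth$ga, orth$sb)  # partners of a in species(b)
    nb <- mapply(cnt, orth$gb, orth$sa)
    rel <- ifelse(na == 1 & nb == 1, "ortholog_one2one",
                  ifelse(na > 1 & nb > 1, "ortholog_many2many",
                         "ortholog_one2many"))
    swap <- rel == "ortholog_one2many" & na > 1  # put the "one" side first
    rows$orth <- data.frame(
      gene_a = ifelse(swap, orth$gb, orth$ga),
      species_a = ifelse(swap, orth$sb, orth$sa),
      gene_b = ifelse(swap, orth$ga, orth$gb),
      species_b = ifelse(swap, orth$sa, orth$sb),
      relation = rel, duplication_level = "", stringsAsFactors = FALSE)
  }
  if (nrow(par_))
    rows$par <- data.frame(gene_a = par_$ga, species_a = par_$sa,
                           gene_b = par_$gb, species_b = par_$sb,
                           relation = "within_species_paralog",
                           duplication_level = par_$level,
                           stringsAsFactors = FALSE)
  if (!length(rows))
    return(homology_table(data.frame(gene_a = character(),
                                     species_a = character(),
                                     gene_b = character(),
                                     species_b = character(),
                                     relation = character(),
                                     duplication_level = character())))
  homology_table(do.call(rbind, unname(rows)))
}
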