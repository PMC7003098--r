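test_that("default species hypotheses have the expected shape", {
  h <- default_species_trees()
  expect_true(ape::all.equal.phylo(
    h$ctenophore_early, ape::read.tree(text = "(Ct1,(Po1,(Pl1,(Cn1,B1))));"),
    use.edge.length = FALSE))
  expect_true(ape::all.equal.phylo(
    h$sponge_early, ape::read.tree(text = "(Po1,(Ct1,(Pl1,(Cn1,B1))));"),
    use.edge.length = FALSE))
  expect_true(setequal(h$sponge_early$tip.label, h$ctenophore_early$tip.label))
  expect_true("Benthozoa" %in% h$ctenophore_early$node.label)
  expect_true("Neuralia" %in% h$sponge_early$node.label)
  expect_equal(unname(phylum_of(h$scheme, c("Ct1", "B1"))), c("Ct", "B"))
  h2 <- default_species_trees(c(B = 2, Cn = 1, Pl = 1, Ct = 3, Po = 1),
                              n_choanoflagellate = 1, n_outgroup = 1)
  expect_true(all(c("Bilateria", "Ctenophora", "Choanozoa", "Opisthokonta")
                  %in% h2$ctenophore_early$node.label))
  expect_equal(ape::Ntip(h2$ctenophore_early), 2 + 1 + 1 + 3 + 1 + 1 + 1)
})

test_that("deterministic scenarios produce the expected copy numbers", {
  # lambda = mu = 0, one planted stem-metazoan duplication: 2 genes/species
  cfg <- sim_config(seed = 1, r1 = 1, r2 = 1)
  hist <- simulate_family(cfg)
  sp <- species_of(hist$tree$tip.label)
  expect_true(all(table(sp) == 2))
  expect_equal(sum(hist$events$type == "duplication"), 1L)
  # two mirror phylum clades: unrooted symmetric topology
  expect_equal(ape::Ntip(hist$tree), 10L)

  # no planted events: one gene per species, tree congruent with species tree
  cfg0 <- sim_config(seed = 1, planted = NULL)
  h0 <- simulate_family(cfg0)
  expect_true(all(table(species_of(h0$tree$tip.label)) == 1))
  g <- h0$tree
  g$tip.label <- species_of(g$tip.label)
  expect_true(ape::all.equal.phylo(g, h0$species_tree,
                                   use.edge.length = FALSE))

  # k planted duplications with mu = 0: every species holds 2^k genes
  cfg2 <- sim_config(seed = 1, planted = data.frame(
    edge = c("Metazoa", "Eumetazoa"), pos = c(0.5, 0.5)))
  h2 <- simulate_family(cfg2)
  cnt <- table(species_of(h2$tree$tip.label))
  expect_true(all(cnt[c("Pl1", "Cn1", "B1")] == 4))
  expect_true(all(cnt[c("Ct1", "Po1")] == 2))

  expect_error(simulate_family(sim_config(seed = 1, planted = data.frame(
    edge = "Nonsense", pos = 0.5))), "absent")
})

test_that("same seed gives bit-identical families and sequences", {
  cfg <- sim_config(seed = 77, lambda = 0.3, mu = 0.1)
  h1 <- simulate_family(cfg); h2 <- simulate_family(cfg)
  expect_identical(write_newick(h1$tree), write_newick(h2$tree))
  expect_identical(h1$events, h2$events)
  a1 <- evolve_sequences(h1, cfg); a2 <- evolve_sequences(h2, cfg)
  expect_identical(a1, a2)
  h3 <- simulate_family(sim_config(seed = 78, lambda = 0.3, mu = 0.1))
  expect_false(identical(write_newick(h1$tree), write_newick(h3$tree)))
})

test_that("pure-birth copy number matches the analytic mean and an independent simulator", {
  # root-to-leaf time = stem 0.3 + tree depth 1.0; expectation e^(lambda T)
  lambda <- 0.1; T <- 1.3
  n_rep <- 2000
  copies <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    h <- simulate_family(sim_config(seed = i, lambda = lambda, planted = NULL))
    copies[i] <- mean(table(factor(species_of(h$tree$tip.label),
                                   levels = c("B1", "Cn1", "Pl1", "Ct1",
                                              "Po1"))))
  }
  expected <- exp(lambda * T)
  se <- stats::sd(copies) / sqrt(n_rep)
  expect_lt(abs(mean(copies) - expected), 3 * se)
  # independent event-queue oracle for one root-to-leaf path
  set.seed(1234)
  oracle_one <- function() {
    n <- 1L; t <- 0
    repeat {
      dt <- stats::rexp(1, lambda * n)
      if (t + dt > T) return(n)
      t <- t + dt; n <- n + 1L
    }
  }
  oracle_mean <- mean(replicate(4000, oracle_one()))
  expect_lt(abs(oracle_mean - expected), 3 * se)
})

test_that("sequence evolution matches its closed-form substitution probability", {
  # one branch of length 0.1: P(site changed) = (19/20)(1 - exp(-0.1*20/19))
  cfg <- sim_config(seed = 9, planted = NULL, seq_length = 100000,
                    n_per_phylum = c(B = 1, Cn = 1, Pl = 1, Ct = 1, Po = 1))
  # build a 2-leaf history manually: use the Cn1/B1 cherry (0.4 each)
  hist <- simulate_family(cfg)
  aln <- evolve_sequences(hist, cfg)
  p_obs <- mean(aln["Cn1|fam1_c1", ] != aln["B1|fam1_c1", ])
  # two independent branches of 0.4 compose to t = 0.8
  t <- 0.8
  p_exp <- (19 / 20) * (1 - exp(-t * 20 / 19))
  se3 <- 3 * sqrt(p_exp * (1 - p_exp) / cfg$seq_length)
  expect_lt(abs(p_obs - p_exp), se3)

  # zero branch lengths: sequences identical to the root
  st <- read_newick(text = "(X1:0,Y1:0)RootNode;")
  sch <- clade_scheme(c(X1 = "B", Y1 = "Cn"))
  cfg0 <- sim_config(seed = 3, planted = NULL, seq_length = 500,
                     stem_length = 0)
  h0 <- simulate_family(cfg0, species_tree = st, scheme = sch)
  a0 <- evolve_sequences(h0, cfg0)
  expect_identical(a0[1, ], a0[2, ])
})

test_that("clade rate multipliers scale the true gene tree linearly", {
  cfg <- sim_config(seed = 21, r1 = 2, r2 = 1)
  ratios <- vapply(1:50, function(i) {
    h <- simulate_family(sim_config(seed = i, r1 = 2, r2 = 1))
    v <- ape::Ntip(h$tree) + match(h$focal_duplication, h$tree$node.label)
    kids <- h$tree$edge[h$tree$edge[, 1] == v, 2]
    parts <- lapply(kids, function(k) ora_tips(h$tree)[[k]])
    rate_heterogeneity(h$tree, parts)
  }, 1)
  expect_lt(abs(mean(ratios) - 2),
            3 * stats::sd(ratios) / sqrt(50) + 1e-9)
  # gene-tree total length grows by exactly the multiplied clade's time span
  h1 <- simulate_family(sim_config(seed = 5, r1 = 1, r2 = 1))
  h2 <- simulate_family(sim_config(seed = 5, r1 = 2, r2 = 1))
  clade1_time <- sum(h2$branch_time[h2$branch_rate == 2])
  expect_gt(clade1_time, 0)
  expect_equal(sum(h2$tree$edge.length),
               sum(h1$tree$edge.length) + clade1_time, tolerance = 1e-9)
})

test_that("noiseless homology tables equal the per-pair MRCA oracle", {
  for (seed in c(2, 3, 4, 5)) {
    cfg <- sim_config(seed = seed, lambda = 0.4, mu = 0.1)
    h <- simulate_family(cfg)
    if (ape::Ntip(h$tree) > 32) next
    tab <- homology_table_from_truth(h)
    ora <- oracle_truth_table(h)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    got_orth <- with(tab[is_ortholog_relation(tab$relation), ],
                     key(gene_a, gene_b))
    got_par <- tab[tab$relation == "within_species_paralog", ]
    exp_orth <- vapply(Filter(function(x) x[3] == "ortholog", ora),
                       function(x) key(x[1], x[2]), "")
    exp_par <- Filter(function(x) x[3] == "paralog", ora)
    expect_setequal(got_orth, exp_orth)
    expect_setequal(key(got_par$gene_a, got_par$gene_b),
                    vapply(exp_par, function(x) key(x[1], x[2]), ""))
    # duplication levels agree
    lv <- setNames(got_par$duplication_level,
                   key(got_par$gene_a, got_par$gene_b))
    for (x in exp_par) expect_equal(unname(lv[key(x[1], x[2])]), x[4])
  }
  # stem-metazoan duplication: every within-species pair at level Metazoa
  cfgM <- sim_config(seed = 1, r1 = 1, r2 = 1)
  tabM <- homology_table_from_truth(simulate_family(cfgM))
  par <- tabM[tabM$relation == "within_species_paralog", ]
  expect_equal(nrow(par), 5L)
  expect_true(all(par$duplication_level == "Metazoa"))
  # no-duplication family: all cross-species pairs one2one
  tab0 <- homology_table_from_truth(simulate_family(
    sim_config(seed = 1, planted = NULL)))
  expect_true(all(tab0$relation == "ortholog_one2one"))
  expect_equal(nrow(tab0), choose(5, 2))
})

test_that("compositional bias skews the biased phylum's residues", {
  target <- rep(0, 20); names(target) <- c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")
  target[c("A", "G")] <- 0.5
  cfg <- sim_config(seed = 11, seq_length = 5000, r1 = 1, r2 = 1,
                    bias_phylum = "Ct", bias_target = target,
                    bias_weight = 0.8)
  h <- simulate_family(cfg)
  aln <- evolve_sequences(h, cfg)
  ct_rows <- grep("^Ct", rownames(aln), value = TRUE)
  other <- setdiff(rownames(aln), ct_rows)
  f_ct <- aa_composition(aln[ct_rows, , drop = FALSE])
  f_ot <- aa_composition(aln[other, , drop = FALSE])
  expect_gt(f_ct[["A"]] + f_ct[["G"]], f_ot[["A"]] + f_ot[["G"]] + 0.05)
})
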