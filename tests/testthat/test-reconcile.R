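fx <- make_forced_rooting_fixture()
hyps <- list(sponge_early = fx$sponge_early,
             ctenophore_early = fx$ctenophore_early)

test_that("rooting enumeration yields 2n-3 trees that unroot to the input", {
  u4 <- ape::unroot(read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  r4 <- enumerate_rootings(u4)
  expect_length(r4, 5L)
  u10 <- ape::unroot(fx$cteno_world)
  r10 <- enumerate_rootings(u10)
  expect_length(r10, 17L)
  for (rt in r10[c(1, 5, 17)]) {
    expect_true(ape::is.rooted(rt))
    expect_true(ape::all.equal.phylo(ape::unroot(rt), u10,
                                     use.edge.length = FALSE))
    # branch lengths preserved through re-rooting
    expect_equal(sum(rt$edge.length), sum(u10$edge.length), tolerance = 1e-9)
  }
  expect_error(enumerate_rootings(fx$cteno_world), "rooted")
})

test_that("LCA reconciliation reproduces the forced-rooting fixture costs", {
  # gene tree congruent with the species tree: D = 0, L = 0
  g0 <- fx$sponge_early
  g0$tip.label <- paste0(g0$tip.label, "|x")
  r0 <- lca_reconcile(g0, fx$sponge_early)
  expect_equal(c(r0$D, r0$L), c(0L, 0L))
  # true ctenophore-early tree rooted at the planted duplication: D=1, L=0
  r1 <- lca_reconcile(fx$cteno_world, fx$ctenophore_early)
  expect_equal(c(r1$D, r1$L), c(1L, 0L))
  expect_equal(sum(r1$events == "duplication"), 1L)
  # the slow "single-copy" partition missing Ct2: D=0, one ctenophore loss
  r2 <- lca_reconcile(fx$slow_partition, fx$sponge_early)
  expect_equal(c(r2$D, r2$L), c(0L, 1L))
  # the loss falls where the ctenophore lineage should have branched
  v <- which(r2$losses > 0)
  expect_equal(r2$mapping_name[v], "Metazoa")
  expect_error(lca_reconcile(fx$cteno_world, ape::drop.tip(fx$sponge_early, "Ct")),
               "not in species tree")
})

test_that("reconciliation equals truth-derived event counts on loss-free families", {
  het <- default_hypotheses()
  n_checked <- 0L
  for (seed in 1:200) {
    cfg <- sim_config(seed = seed, lambda = 0.35, mu = 0,
                      hypothesis = sample(c("sponge_early",
                                            "ctenophore_early"), 1))
    h <- simulate_family(cfg)
    if (ape::Ntip(h$tree) > 20) next
    rec <- lca_reconcile(h$tree, h$species_tree)
    expect_equal(rec$D, sum(h$events$type == "duplication"))
    expect_equal(rec$L, 0L)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 150L)
  # with losses, parsimony never exceeds the true event counts
  for (seed in 1:40) {
    cfg <- sim_config(seed = seed, lambda = 0.3, mu = 0.25)
    h <- simulate_family(cfg)
    rec <- lca_reconcile(h$tree, h$species_tree)
    expect_lte(rec$D, sum(h$events$type == "duplication"))
    expect_lte(rec$L, sum(h$events$type == "loss"))
  }
})

test_that("reconciliation agrees with the containment-scan oracle on random rootings", {
  set.seed(61)
  het <- default_hypotheses(c(B = 2, Cn = 1, Pl = 1, Ct = 2, Po = 1))
  for (i in 1:30) {
    cfg <- sim_config(seed = i, lambda = 0.4, mu = 0.15,
                      n_per_phylum = c(B = 2, Cn = 1, Pl = 1, Ct = 2, Po = 1))
    h <- simulate_family(cfg)
    u <- ape::unroot(h$tree)
    k <- sample(nrow(u$edge), 1)
    rooted <- dupliphy:::root_on_edge(u, k)
    got <- lca_reconcile(rooted, h$species_tree)
    ora <- oracle_reconcile(rooted, h$species_tree)
    expect_equal(got$D, ora$D)
    expect_equal(got$L, ora$L)
  }
})

test_that("simple root-choice counting matches exhaustive edge scans", {
  sch <- clade_scheme(c(CtA = "Ct", CtB = "Ct", Po = "Po", Cn = "Cn",
                        B = "B"))
  t1 <- ape::unroot(read_newick(
    text = "((CtA:1,CtB:1):1,(Po:1,(Cn:1,B:1):1):1);"))
  rc <- count_root_choices(t1, sch)
  expect_equal(rc$n_edges, 7L)
  expect_equal(unname(rc$counts["Ct"]), 3L)
  expect_equal(unname(rc$counts["Po"]), 1L)
  # forced-rooting fixture: two pendant edges per phylum, nothing else pure
  rc2 <- count_root_choices(ape::unroot(fx$cteno_world), fx$scheme)
  expect_equal(unname(rc2$counts["Ct"]), 2L)
  expect_equal(unname(rc2$counts["Po"]), 2L)
  expect_equal(rc2$n_edges, 17L)
  # single-phylum tree: every edge is that phylum's choice
  schc <- clade_scheme(c(c1 = "Ct", c2 = "Ct", c3 = "Ct", c4 = "Ct"))
  t3 <- ape::unroot(read_newick(text = "((c1:1,c2:1):1,(c3:1,c4:1):1);"))
  rc3 <- count_root_choices(t3, schc)
  expect_equal(unname(rc3$counts["Ct"]), rc3$n_edges)
  # cost-based generalization is tabulated per rooting per hypothesis
  rc4 <- count_root_choices(ape::unroot(fx$cteno_world), fx$scheme, hyps)
  expect_equal(nrow(rc4$per_edge), 17L)
  expect_true(all(c("D_sponge_early", "L_ctenophore_early") %in%
                    names(rc4$per_edge)))
  expect_equal(min(rc4$per_edge$D_ctenophore_early), 1L)
})

test_that("best rooting recovers true roots and exposes forced-model costs", {
  # congruent single-copy family: true root edge recovered
  g0 <- fx$sponge_early
  g0$tip.label <- paste0(g0$tip.label, "|x")
  br0 <- best_rooting(g0, fx$sponge_early)
  expect_equal(c(attr(br0, "D"), attr(br0, "L")), c(0L, 0L))
  expect_true(ape::all.equal.phylo(br0, g0, use.edge.length = FALSE))
  # true ctenophore-early tree under its own hypothesis: inter-paralog edge
  br1 <- best_rooting(fx$cteno_world, fx$ctenophore_early)
  expect_equal(c(attr(br1, "D"), attr(br1, "L")), c(1L, 0L))
  expect_true(ape::all.equal.phylo(br1, fx$cteno_world, use.edge.length = FALSE))
  expect_length(attr(br1, "ties"), 1L)
  # under the wrong hypothesis the minimum cost implies extra events and the
  # chosen rooting differs from the true edge (tie broken by longest edge)
  br2 <- best_rooting(fx$cteno_world, fx$sponge_early)
  expect_gte(attr(br2, "D") + attr(br2, "L"), 2)
  expect_false(ape::all.equal.phylo(br2, fx$cteno_world, use.edge.length = FALSE))
  # exhaustive cost table confirms the reported minimum
  u <- ape::unroot(fx$cteno_world)
  costs <- vapply(enumerate_rootings(u), function(r) {
    x <- lca_reconcile(r, fx$sponge_early); x$D * 1000 + x$L }, 1)
  expect_equal(min(costs),
               attr(br2, "D") * 1000 + attr(br2, "L"))
})

test_that("duplication/loss costs are invariant under consistent relabeling", {
  cfg <- sim_config(seed = 13, lambda = 0.3, mu = 0.1)
  h <- simulate_family(cfg)
  rec <- lca_reconcile(h$tree, h$species_tree)
  swap <- function(x) chartr("BP", "PB", x)  # B1<->P1 style species swap
  g2 <- h$tree; g2$tip.label <- swap(g2$tip.label)
  s2 <- h$species_tree; s2$tip.label <- swap(s2$tip.label)
  rec2 <- lca_reconcile(g2, s2)
  expect_equal(c(rec$D, rec$L), c(rec2$D, rec2$L))
})

test_that("family classification matches the published duplication patterns", {
  sch6 <- clade_scheme(c(B1 = "B", Cn1 = "Cn", Pl1 = "Pl", Ct1 = "Ct",
                         Po1 = "Po", Cf1 = "Choanoflagellatea"))
  h6 <- default_species_trees(n_choanoflagellate = 1)
  hl6 <- h6[c("sponge_early", "ctenophore_early")]
  # MLX/MLXIP: duplicated sponge+eumetazoan pair, single ctenophore sister
  mlx <- read_newick(text = paste0(
    "(Cf1|MAX:1,(Ct1|Maxlike:1,((Po1|MLX:1,(Pl1|MLX:0.6,(Cn1|MLX:0.4,",
    "B1|MLX:0.4):0.2):0.3):0.2,(Po1|MLXIP:1,(Pl1|MLXIP:0.6,(Cn1|MLXIP:0.4,",
    "B1|MLXIP:0.4):0.2):0.3):0.2):0.3):0.5);"))
  expect_equal(classify_family(mlx, sch6, hl6)$category, "BENTHOZOA_SUPPORT")
  # with a duplicated ctenophore sister lineage, strict mode withholds support
  mlx2 <- read_newick(text = paste0(
    "(Cf1|MAX:1,((Ct1|MaxlikeA:1,Ct1|MaxlikeB:1):0.4,((Po1|MLX:1,",
    "(Pl1|MLX:0.6,(Cn1|MLX:0.4,B1|MLX:0.4):0.2):0.3):0.2,(Po1|MLXIP:1,",
    "(Pl1|MLXIP:0.6,(Cn1|MLXIP:0.4,B1|MLXIP:0.4):0.2):0.3):0.2):0.3):0.5);"))
  expect_false(classify_family(mlx2, sch6, hl6)$category ==
                 "BENTHOZOA_SUPPORT")
  expect_equal(classify_family(mlx2, sch6, hl6,
                               strict_single_copy_sister = FALSE)$category,
               "BENTHOZOA_SUPPORT")
  # Stomatin pattern: both paralog clades contain a ctenophore
  sch5 <- fx$scheme
  stom <- read_newick(text = paste0(
    "((Ct|SA:1,(Po|SA:0.8,(Pl|SA:0.6,(Cn|SA:0.4,B|SA:0.4):0.2):0.2):0.2):0.3,",
    "(Ct|SB:1,(Po|SB:0.8,(Pl|SB:0.6,(Cn|SB:0.4,B|SB:0.4):0.2):0.2):0.2):0.3);"))
  expect_equal(classify_family(stom, sch5, hyps)$category,
               "CTENOPHORE_SHARED_UNINFORMATIVE")
  # Tmc487/Tmc56 pattern: duplication wholly inside Eumetazoa, sponge outside
  tmc <- read_newick(text = paste0(
    "(Ct|Z2:1.2,(Po|Z2:1,((Pl|T487:0.6,(Cn|T487:0.4,B|T487:0.4):0.2):0.2,",
    "(Pl|T56:0.6,(Cn|T56:0.4,B|T56:0.4):0.2):0.2):0.2):0.2);"))
  expect_equal(classify_family(tmc, sch5, hyps)$category,
               "EUMETAZOA_DUPLICATION")
  # Amx pattern: choanoflagellate genes inside every paralog clade
  amx <- read_newick(text = paste0(
    "(((Cf1|Amx:1,(B1|Amx:0.8,Po1|Amx:0.8):0.2):0.3,(Cf1|CG11103:1,",
    "(B1|CG11103:0.8,Po1|CG11103:0.8):0.2):0.3):0.2,(Cf1|CG10795:1.2,",
    "(B1|CG10795:1,Po1|CG10795:1):0.2):0.3);"))
  expect_equal(classify_family(amx, sch6, hl6)$category,
               "PRE_CHOANOZOAN_UNINFORMATIVE")
  # Neuralia mirror with an outgroup-fixed root
  neu <- read_newick(text = paste0(
    "(Cf1|MAX:1,(Po1|Maxlike:1,((Ct1|A:1,(Pl1|A:0.6,(Cn1|A:0.4,",
    "B1|A:0.4):0.2):0.3):0.2,(Ct1|B:1,(Pl1|B:0.6,(Cn1|B:0.4,",
    "B1|B:0.4):0.2):0.3):0.2):0.3):0.5);"))
  expect_equal(classify_family(neu, sch6, hl6)$category, "NEURALIA_SUPPORT")
})

test_that("classification equals the brute-force reimplementation on random families", {
  het <- default_hypotheses(c(B = 1, Cn = 1, Pl = 1, Ct = 2, Po = 1))
  phymap <- het$scheme$phylum_of
  scenarios <- list(
    list(edge = "Metazoa", hyp = "ctenophore_early"),
    list(edge = "Benthozoa", hyp = "ctenophore_early"),
    list(edge = "Eumetazoa", hyp = "sponge_early"),
    list(edge = "Ctenophora", hyp = "ctenophore_early"),
    list(edge = NULL, hyp = "sponge_early"))
  n_done <- 0L
  for (i in 1:20) {
    sc <- scenarios[[(i %% length(scenarios)) + 1L]]
    planted <- if (is.null(sc$edge)) NULL else
      data.frame(edge = sc$edge, pos = 0.5)
    cfg <- sim_config(seed = 400 + i, hypothesis = sc$hyp, planted = planted,
                      lambda = 0.25, mu = 0.1,
                      n_per_phylum = c(B = 1, Cn = 1, Pl = 1, Ct = 2, Po = 1))
    h <- simulate_family(cfg)
    if (ape::Ntip(h$tree) < 3 || ape::Ntip(h$tree) > 12) next
    got <- classify_family(h$tree, het$scheme, het$hyps)$category
    exp_ <- oracle_classify(h$tree, phymap, het$hyps)
    expect_equal(got, exp_, label = paste("seed", 400 + i))
    n_done <- n_done + 1L
  }
  expect_gte(n_done, 10L)
})

test_that("planted scenarios are recovered perfectly from noiseless true trees", {
  run_cat <- function(edge, hypothesis, n_ct = 1, seed = 1) {
    np <- c(B = 1, Cn = 1, Pl = 1, Ct = n_ct, Po = 1)
    cfg <- sim_config(hypothesis = hypothesis, n_per_phylum = np,
                      planted = data.frame(edge = edge, pos = 0.5),
                      r1 = 1, r2 = 1, seed = seed)
    h <- default_hypotheses(np)
    classify_family(simulate_family(cfg)$tree, h$scheme, h$hyps)$category
  }
  reps <- 25  # deterministic scenario; full 500-replicate sweeps run in the
              # acceptance suite
  for (s in seq_len(reps)) {
    expect_equal(run_cat("Metazoa", "ctenophore_early", seed = s),
                 "CTENOPHORE_SHARED_UNINFORMATIVE")
    expect_equal(run_cat("Benthozoa", "ctenophore_early", seed = s),
                 "BENTHOZOA_SUPPORT")
    expect_equal(run_cat("Eumetazoa", "ctenophore_early", seed = s),
                 "EUMETAZOA_DUPLICATION")
    expect_equal(run_cat("Ctenophora", "ctenophore_early", n_ct = 2,
                         seed = s), "PHYLUM_SPECIFIC")
  }
})

test_that("diagnostic column partitioning recovers known column ancestry", {
  aln <- aa_alignment(c(A1 = "AAAACCCC", A2 = "AAAACCCC",
                        B1 = "GGGGCCCC", B2 = "GGGGCCCC",
                        P1 = "AAGGCCCC"))
  d <- diagnostic_columns(aln, c("A1", "A2"), c("B1", "B2"), "P1")
  expect_equal(d$assignment[1:4], c("A-like", "A-like", "B-like", "B-like"))
  # probe matching both consensuses is neither
  expect_true(all(d$assignment[5:8] == "neither"))
  expect_equal(unname(d$counts), c(2L, 2L, 4L))
  expect_error(diagnostic_columns(aln, character(), "B1", "P1"), "empty")
  expect_error(diagnostic_columns(aln, c("A1"), c("A1"), "P1"), "disjoint")

  # simulated mixture with labeled column ancestry, low mutation rate
  set.seed(5)
  L <- 300
  consA <- sample(c("A", "C", "D", "E"), L, replace = TRUE)
  consB <- vapply(consA, function(x)
    sample(setdiff(c("A", "C", "D", "E"), x), 1), "")
  mut <- function(x, rate = 0.05) {
    hit <- stats::runif(L) < rate
    x[hit] <- sample(c("A", "C", "D", "E"), sum(hit), replace = TRUE)
    x
  }
  truth <- sample(c("A", "B"), L, replace = TRUE)
  probe <- ifelse(truth == "A", consA, consB)
  m <- rbind(A1 = mut(consA), A2 = mut(consA), A3 = mut(consA),
             B1 = mut(consB), B2 = mut(consB), B3 = mut(consB),
             probe = mut(probe))
  dx <- diagnostic_columns(aa_alignment(m), c("A1", "A2", "A3"),
                           c("B1", "B2", "B3"), "probe")
  called <- dx$assignment != "neither"
  agree <- mean((dx$assignment[called] == "A-like") ==
                  (truth[called] == "A"))
  expect_gte(agree, 0.9)
})
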