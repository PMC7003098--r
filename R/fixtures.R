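#' Deterministic gene-tree fixtures for the forced-rooting thought experiment
#'
#' Builds the four-panel fixture set illustrating how a stem-metazoan gene
#' duplication behaves under the two competing worlds: (A) the true gene
#' tree in a sponge-early world; (B) the true gene tree in a
#' ctenophore-early world, with paralog clade one evolving at rate `r1` and
#' clade two at `r2`; (C) the sponge-early re-rooted "single-copy" partition
#' of the slow clade two, which is missing the ctenophore gene Ct2 and so
#' carries a false-positive loss signature; and (D) the remaining genes
#' rooted sponge-early with the sponge Po1 as outgroup, in which Ct1 and Ct2
#' unite into an apparent ctenophore-specific duplication with spurious rate
#' and composition heterogeneity.
#'
#' Trees are ultrametric in time (phylum stems at depths 1.0/0.8/0.6/0.4)
#' before rate scaling; the planted duplication sits `stem_offset` above the
#' metazoan root. Leaves are `"Ct|Ct1"`, `"Po|Po2"`, ... (species named by
#' phylum, one species per phylum; gene copy 1 in clade one, copy 2 in
#' clade two).
#'
#' @param r1,r2 rate multipliers of paralog clades one and two.
#' @param stem_offset time from the planted duplication down to the metazoan
#'   radiation.
#' @return list with `sponge_world`, `cteno_world`, `slow_partition`, `fast_partition` (`phylo`),
#'   `sponge_early`, `ctenophore_early` (species hypotheses over the fixture
#'   species), and `scheme`.
#' @export
make_forced_rooting_fixture <- function(r1 = 3, r2 = 1, stem_offset = 0.15) {
  scheme <- clade_scheme(c(B = "B", Cn = "Cn", Pl = "Pl", Ct = "Ct",
                           Po = "Po"))
  sponge_early <- read_newick(text = paste0(
    "(Po:1.0,(Ct:0.8,(Pl:0.6,(Cn:0.4,B:0.4)CnidariaBilateria:0.2)",
    "Eumetazoa:0.2)Neuralia:0.2)Metazoa;"))
  cteno_early <- read_newick(text = paste0(
    "(Ct:1.0,(Po:0.8,(Pl:0.6,(Cn:0.4,B:0.4)CnidariaBilateria:0.2)",
    "Eumetazoa:0.2)Benthozoa:0.2)Metazoa;"))
  # rooted paralog clade in one world, all branch lengths scaled by `r`
  clade <- function(first, copy, r, tag) {
    second <- if (first == "Ct") "Po" else "Ct"
    lf <- function(ph) paste0(ph, "|", ph, copy)
    paste0("(", lf(first), ":", 1.0 * r, ",(", lf(second), ":", 0.8 * r,
           ",(", lf("Pl"), ":", 0.6 * r, ",(", lf("Cn"), ":", 0.4 * r, ",",
           lf("B"), ":", 0.4 * r, ")s", tag, "3:", 0.2 * r, ")s", tag, "2:",
           0.2 * r, ")s", tag, "1:", 0.2 * r, ")s", tag, "0:",
           stem_offset * r)
  }
  two_clades <- function(first) read_newick(text = paste0(
    "(", clade(first, 1, r1, "a"), ",", clade(first, 2, r2, "b"), ")D1;"))
  sponge_world <- two_clades("Po")
  cteno_world <- two_clades("Ct")
  clade2_rest <- c("Po|Po2", "Pl|Pl2", "Cn|Cn2", "B|B2")
  slow_partition <- ape::keep.tip(cteno_world, clade2_rest)
  fast_partition <- ape::root(ape::drop.tip(cteno_world, clade2_rest),
                     outgroup = "Po|Po1", resolve.root = TRUE)
  list(sponge_world = sponge_world, cteno_world = cteno_world, slow_partition = slow_partition, fast_partition = fast_partition,
       sponge_early = sponge_early, ctenophore_early = cteno_early,
       scheme = scheme)
}
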