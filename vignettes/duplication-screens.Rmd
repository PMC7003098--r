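---
title: "Resolving early animal branching with gene duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving early animal branching with gene duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupliphy)
library(ape)
```

## The problem

Whether sponges (Porifera, `Po`) or comb jellies (Ctenophora, `Ct`) are the
sister lineage of all other animals is unresolved: phylogenies built from
single-copy orthologs support both answers depending on genes and models.
`dupliphy` implements a complementary strategy: instead of avoiding ancient
paralogy, it looks for gene families *duplicated* during the early metazoan
radiation. A duplication shared by some phyla but not others is a shared
derived character: a family duplicated in sponges and eumetazoans (Bilateria
`B` + Cnidaria `Cn` + Placozoa `Pl`), with a single-copy ctenophore gene
branching immediately outside the duplicated pair, supports a clade of
Porifera + Eumetazoa ("Benthozoa"); the mirrored pattern with a sponge
outside supports Ctenophora + Eumetazoa ("Neuralia").

The strategy has a systematic failure mode that the package also models.
Genome-wide ortholog-calling pipelines implicitly assume a rooted species
tree (in practice, sponge-early). If the world is actually
ctenophore-early, every family carrying a stem-metazoan duplication gets
mis-rooted: the ctenophore gene of the slowly evolving paralog clade is
flipped into the fast clade, the slow clade acquires a *false-positive gene
loss* in ctenophores, and the fast clade acquires spurious rate and
amino-acid-composition heterogeneity. Aggregated over a genome this
manufactures an ortholog-coverage deficit specific to ctenophores.

## Package anatomy

* **core_io** — alignments (FASTA/NEXUS), Newick trees, Compara-style
  homology tables; gap-normalized identity and residue composition.
* **simulate** — a fully seeded generative model of gene families under the
  two competing rooted hypotheses.
* **screen** — the model-agnostic paralogy screen over homology tables.
* **nj_infer** — p-distances, Poisson correction, deterministic
  neighbor-joining, seeded bootstrap (the draft-tree stage of the screen).
* **reconcile** — rooting enumeration, LCA reconciliation with
  duplication/loss counting, root-choice counting, duplication-timing
  classification, diagnostic residue partitioning.
* **miscall** — tree-based ortholog calling and the forced-rooting
  experiment quantifying the artifact.
* **cli_report** — `run_pipeline()` / `render_report()` tie the stages
  together; the exported functions are the command surface of the package.

## The generative model

`sim_config()` fixes the study conditions; `simulate_family()` realizes one
family.

* **Species hypotheses.** `default_species_trees()` returns ultrametric
  sponge-early and ctenophore-early trees over one shared species set.
  Depths are in expected substitutions/site: the phylum stems attach at
  1.0, 0.8, 0.6 and 0.4, within-phylum diversification below 0.2,
  choanoflagellates at 1.3 and a deeper outgroup at 1.6. A root-to-tip
  depth of 1.0 puts deep metazoan divergences near (but not past)
  saturation for amino acids, which is the regime the rooting problem
  lives in.
* **Planted duplications** fire deterministically at a relative position on
  a named species-tree edge (edges are named by the node below them; the
  root name refers to an implicit stem of length 0.3, so stem-Metazoa
  duplications exist even on metazoan-only trees). Every lineage alive at
  the planted point duplicates, so `k` planted duplications with no losses
  give every species exactly `2^k` genes.
* **Birth–death events.** Stochastic duplications (rate `lambda`) and
  losses (rate `mu`) per gene per unit branch length; losses prune the
  affected sublineage; a family surviving in fewer than two genes is
  resampled by continuing the random stream (the screens only ever see
  surviving families).
* **Rate asymmetry.** The two clades descending from the *first* planted
  duplication get rate multipliers `r1` and `r2` (defaults 3 and 1).
  Divergent functionalization of paralogs makes one copy evolve faster;
  the published material depicts this asymmetry without quantifying it, so
  the 3:1 default is this package's choice of a clearly asymmetric but not
  absurd ratio, fixed once here and used everywhere. True gene-tree branch
  lengths are time × multiplier, i.e. expected substitutions/site.
* **Sequences.** Sites evolve independently under a 20-state resampling
  process: a site substitutes iff it sees at least one event (event rate
  20/19 per unit branch length, so branch length equals expected
  substitutions/site), and the post-event residue is a fresh draw from the
  branch's target frequencies. For a branch of length `l` the probability
  a site differs across it is exactly `(19/20)(1 − exp(−(20/19) l))` —
  the closed form frozen into the tests. Compositional bias mixes a target
  frequency vector (weight `bias_weight`) into branches inside a named
  phylum. An empirical PAML-format rate matrix can replace the uniform
  model (`read_paml_matrix()`), in which case transition probabilities come
  from the eigendecomposition of the scaled generator and bias is not
  supported.
* **Noiseless homology tables.** `homology_table_from_truth()` labels a
  cross-species pair orthologous iff its gene-tree LCA is a speciation
  event, assigns within-species paralogs the species-tree level of their
  LCA duplication, and derives one2one/one2many/many2many subtypes by
  reciprocal counting.

What the generator does *not* emulate: indels and alignment error, rate
variation across sites, codon structure, correlated rates, and real
genome-annotation noise. Green tests therefore certify the logic of the
screen and of the miscalling artifact under the stated model — not
robustness of the method to every pathology of real data.

## Reconciliation and classification

`lca_reconcile()` is the standard last-common-ancestor mapping: a gene-tree
node mapping to the same species-tree node as one of its children is a
duplication; losses are counted per child edge (`distance − 1` below
speciations, `distance` below duplications). `enumerate_rootings()` places
the root on each of the `2n − 3` edges; `best_rooting()` minimizes `(D, L)`
lexicographically — losses are the central artifact here and must never be
traded against duplications silently, though a weighted cost is available —
with ties broken by the longest original edge and then canonical leaf-name
order. That tie-break is not cosmetic: it is exactly how a long, fast
ctenophore branch wins the rooting contest under a mis-specified
hypothesis, reproducing the artifact deterministically even on true trees.

`classify_family()` turns duplications into statements about branching
order. If separable non-metazoan outgroup genes exist the tree is rooted on
them; otherwise every minimum-cost rooting under every supplied hypothesis
is evaluated. Per duplication node with child phylum sets S1 and S2, in
this order: outgroup taxa in both clades → pre-choanozoan (uninformative);
one phylum in total → phylum-specific; sponges in both clades, eumetazoans
in both, no ctenophore inside and a ctenophore lineage immediately outside
→ Benthozoa support (mirrored for Neuralia); ctenophores in both clades →
ctenophore-shared (uninformative); a duplication wholly inside Eumetazoa
spanning ≥ 2 eumetazoan phyla per clade → eumetazoan duplication. The
support rules are tested before the broader ctenophore-shared rule — under
a literal last-to-first reading the Neuralia rule could never fire — and
"immediately outside" means the duplication node's sister subtree holds
only the candidate phylum (single-copy per species under the default strict
flag, switchable). A family's verdict aggregates its duplication nodes with
positive evidence taking precedence over uninformative classes.

Two classification conventions were genuinely open and are resolved as
follows. First, a minimum-cost rooting whose duplications pin *no* category
does not veto rootings that do; `AMBIGUOUS_ROOT` means either that two
admissible rootings assert different categories or that no admissible
rooting asserts any. Without this, every stem-Benthozoa family would be
vacuously ambiguous: the tied sponge-early rootings that slice through the
duplication see nothing, while the informative rooting sees the support
pattern. Second, a consequence worth knowing: a Neuralia-type duplication
*without* an outgroup is intrinsically equivocal, because one of its tied
rootings genuinely asserts ctenophore-shared — the package reports
`AMBIGUOUS_ROOT` there, and Neuralia support is recovered when outgroup
genes fix the root.

## The screen

`run_screen()` applies the cascade: within-species paralogy edges of a
focal species (duplication levels at too-recent taxonomic levels are
severed — or genes dropped outright under `drop_mode = "remove"`), groups
as connected components (the weakest rule consistent with transitive
pairwise paralogy), a per-gene ortholog requirement against anchor taxa
(per-group mode available), size binning (default keep 2–3 genes), seeded
`floor(fraction × n)` sampling, and only then annotation of sponge /
ctenophore presence. The annotation species are never read by the filters;
the test suite enforces this by deleting every ortholog record touching
them and checking the cascade is unchanged. Stage counts are monotone
non-increasing by construction; the genome-scale counts reported for real
Ensembl releases are not reproducible offline and are not targets here.
`trichoplax_anchor_config()` packages the placozoan-anchored five-criteria
variant.

## The miscall experiment

`run_experiment()` runs the full loop per family: simulate under the TRUE
hypothesis → evolve sequences → NJ on Poisson-corrected p-distances (or the
true tree, for controls) → `best_rooting()` under the ASSUMED hypothesis →
`call_orthologs()` → aggregate. Reported statistics: per-species ortholog
coverage against a cnidarian and a sponge reference; the ctenophore deficit
gap (minimum over other lineages minus the ctenophore value, positive =
deficit); per-phylum false-loss rates (a gene that truly has orthologs but
received no call); and, per family, the clade rate ratio and composition
chi-square. Families whose analysis degenerates (e.g. saturated distances)
are logged and skipped. Correctly specified runs on true trees give exactly
zero false losses and 100% coverage — the experiment's negative control.

## Numerical choices and degenerate inputs

* NJ ties in the Q-criterion break at the lowest index pair; negative
  branch lengths are clamped to zero with the total deficit recorded in
  attribute `"clamped"`.
* Bootstrap supports are computed against the point-estimate topology (not
  a consensus), matching how supports annotate a single drawn tree; rows
  are sorted internally so supports cannot depend on input row order.
* `gap_normalized_identity()` divides by shared non-gap columns; the
  total-column denominator exists as an option. Columns containing `X`
  leave both numerator and denominator. A pair with no shared non-gap
  columns is an error, not a 0.
* p-distances of exactly 1 make the Poisson correction undefined and raise
  an error; inside `run_experiment()` such families are skipped and
  counted.
* Multifurcating gene trees are rejected; resolve polytomies upstream (NJ
  output is binary).
* Coordinates are 0-based half-open internally and 1-based in
  human-readable output.

## Problem sizes used by the tests

The test and acceptance suites run entirely on synthetic data generated at
test time: 100 random additive matrices (n ≤ 12) for NJ recovery, 200
loss-free families for reconciliation-vs-truth equality, 500 seeded
replicates per planted scenario for category recovery, and 200 replicates
of the five-family forced-rooting experiment for the coverage-minimum
property. Reconciliation-vs-truth equality is asserted in the loss-free
regime, where the true event counts and the most parsimonious
reconciliation provably coincide; with losses, parsimony can only
undercount (adjacent losses merge, duplications with one extinct child
vanish), so the suite asserts `D` and `L` as upper-bounded by the truth
instead.

## Known limitations

Reconciliation is parsimony-based (no probabilistic duplication-loss
model); transfers and multifurcations are out of scope. The sequence model
has no indels or site-rate variation, so NJ accuracy on simulated data will
exceed accuracy on comparably divergent real alignments. Classification
encodes the field's phylum-level logic; finer taxon sampling questions
(e.g. within-ctenophore order-level sampling) are expressible only through
the clade scheme.
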