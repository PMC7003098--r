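# dupliphy

Gene-duplication screens and gene-tree/species-tree reconciliation for
resolving the branching order of the earliest animal lineages.

## The problem

Whether Porifera (sponges, `Po`) or Ctenophora (comb jellies, `Ct`) is the
sister group of all other animals remains contested: single-copy-ortholog
phylogenies support either answer depending on genes and models. `dupliphy`
is a toolkit for the complementary strategy of *choosing* ancient gene
paralogies rather than avoiding them. A gene family duplicated in the stem
of a candidate clade — say, present as a duplicated pair in sponges and in
Eumetazoa (Bilateria `B` + Cnidaria `Cn` + Placozoa `Pl`) with a single
ctenophore gene branching immediately outside — is a shared derived
character for that clade ("Benthozoa" = Porifera + Eumetazoa; the mirrored
pattern supports "Neuralia" = Ctenophora + Eumetazoa).

The toolkit also models why naive orthology pipelines miss this signal. For
an unrooted family tree with `n` genes there are `2n − 3` possible root
placements. Orthology pipelines implicitly force a rooted species model; if
the assumed model is wrong, the minimum duplication/loss rooting of a truly
duplicated family flips a ctenophore paralog into the wrong clade. The
isolated "single-copy" subclade then shows a **false-positive gene loss**
in ctenophores, the other subclade shows spurious rate and amino-acid
composition heterogeneity, and genome-wide the ctenophore lineage shows an
**ortholog-coverage deficit** — all without any real loss having occurred.

## What the package provides

| Stage | Functions |
|---|---|
| IO & statistics | `read_alignment()`, `read_newick()`, `read_homology_table()`, `gap_normalized_identity()`, `aa_composition()` |
| Synthetic data | `default_species_trees()`, `sim_config()`, `simulate_family()`, `evolve_sequences()`, `homology_table_from_truth()`, `make_forced_rooting_fixture()` |
| Paralogy screen | `screen_config()`, `run_screen()`, `paralogy_groups()`, `require_orthologs()`, `bin_by_size()`, `sample_groups()`, `annotate_presence()`, `trichoplax_anchor_config()` |
| Draft trees | `p_distance()`, `poisson_correct()`, `neighbor_joining()`, `nj_bootstrap()` |
| Reconciliation | `enumerate_rootings()`, `lca_reconcile()`, `best_rooting()`, `count_root_choices()`, `classify_family()`, `diagnostic_columns()` |
| Miscall experiment | `call_orthologs()`, `ortholog_coverage()`, `rate_heterogeneity()`, `composition_heterogeneity()`, `run_experiment()` |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `render_report()` |

The core statistic is parsimony LCA reconciliation: map every gene-tree
node to the last common ancestor (in a rooted species tree *S*) of its
descendants' species; a node mapping to the same species-tree node as one
of its children is a duplication, and losses are counted per child edge
(`dist(M(v), M(c)) − 1` below speciations, `dist` below duplications).
`best_rooting()` minimizes `(D, L)` lexicographically over all `2n − 3`
rootings; `classify_family()` converts the duplications of every
minimum-cost rooting under both competing hypotheses into one of eight
duplication-timing categories (`BENTHOZOA_SUPPORT`, `NEURALIA_SUPPORT`,
`EUMETAZOA_DUPLICATION`, `PHYLUM_SPECIFIC`, two uninformative classes,
`NO_DUPLICATION`, `AMBIGUOUS_ROOT`).

## Worked example

Build the canonical thought-experiment family — a stem-metazoan duplication
in a ctenophore-early world, fast paralog clade one (rate 3) and slow clade
two (rate 1) — and force it into a sponge-early model:

```r
library(dupliphy)
fx <- make_forced_rooting_fixture()                       # trees, hypotheses, scheme

# under the TRUE (ctenophore-early) hypothesis the root is recovered on the
# inter-paralog edge with one duplication and no losses:
br <- best_rooting(fx$cteno_world, fx$ctenophore_early)
c(attr(br, "D"), attr(br, "L"))
#> [1] 1 0

# forcing the sponge-early model costs extra events (D=3, L=6) and the
# tie-break lands the root on the longest (fast ctenophore) branch:
bw <- best_rooting(fx$cteno_world, fx$sponge_early)
c(attr(bw, "D"), attr(bw, "L"))
#> [1] 3 6

# ortholog calls from the forced tree starve the ctenophore genes:
calls <- call_orthologs(bw, fx$sponge_early)
ortholog_coverage(calls, "Ct", "Cn", focal_genes = c("Ct|Ct1", "Ct|Ct2"))
#> [1] 0
ortholog_coverage(calls, "B", "Cn")
#> [1] 100

# the re-rooted "single-copy" slow clade carries a false-positive loss:
rc <- lca_reconcile(fx$slow_partition, fx$sponge_early)
c(rc$D, rc$L)
#> [1] 0 1

# and the family itself is correctly read as a metazoan-wide duplication,
# uninformative for the sponge-vs-ctenophore question:
classify_family(fx$cteno_world, fx$scheme,
                list(sponge_early = fx$sponge_early,
                     ctenophore_early = fx$ctenophore_early))$category
#> [1] "CTENOPHORE_SHARED_UNINFORMATIVE"
```

So one mis-specified rooting assumption converts a clean duplication into a
ctenophore "loss" plus a coverage deficit — the artifact the screen in
`run_screen()` is designed to be agnostic to, and the one `run_experiment()`
quantifies at scale.

## Vignette

`vignettes/duplication-screens.Rmd` documents the generative model and its
assumptions, the classification rules and the genuinely open design choices
behind them, numerical conventions, and what the synthetic-data tests do
and do not establish about real data.
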