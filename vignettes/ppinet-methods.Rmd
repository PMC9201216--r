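---
title: "Patient PPI-network clustering: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient PPI-network clustering: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinet)
```

## The model

`ppinet` operationalizes a network view of genetic heterogeneity in
case/control exome cohorts: a disorder may be driven not by one recurrent
variant but by damage scattered across a *disease module* — a localized,
densely interacting neighborhood of the protein–protein interactome. If
that view holds, affected individuals should carry deleterious variants in
different genes of the same module, their personal PPI networks should
overlap, and clustering patients by network similarity should recover a
case-enriched subgroup whose shared genes occupy a distinct interactome
region.

The pipeline has five stages, each exposed as ordinary functions and
orchestrated by `ppin_analysis()`:

1. site-quality filtering (`quality_filter`),
2. deleteriousness filtering (`deleteriousness_filter`),
3. per-variant 2×3 case/control Fisher genotype testing
   (`gtest_variants`),
4. per-patient seed-gene selection and network construction
   (`select_seed_genes`, `build_sample_network`),
5. Jaccard/UPGMA clustering with per-node Fisher enrichment, layered
   networks, unique genes, and the separation score
   (`upgma`, `significant_clusters`, `build_layered_network`,
   `unique_genes`, `separation_score`, `overrepresentation_test`).

## Statistical components

**Exact 2×3 Fisher test.** All tables with the observed margins are
enumerated; each table's probability is the multivariate hypergeometric
mass, and the two-sided p-value sums the probabilities of tables no more
probable than the observed one. Probability ties are resolved with a
relative tolerance of 1e-12, computed in log space. When the enumeration
would exceed a cap (`max_tables`, default 1e6 — never reached at cohort
scale), `fisher_exact_mc()` draws tables from the fixed-margin null with
Patefield's algorithm (`stats::r2dtable`) and reports
`(1 + #{P(T_sim) ≤ P(T_obs)}) / (reps + 1)`, which is never exactly zero
and is deterministic given its seed. The exact test is conservative on the
sparse tables this design produces (most sites have one or two carriers),
so its empirical type-I error at α = 0.05 sits well below 0.05 — the
acceptance suite measures it on a null cohort.

**2×2 cluster enrichment.** Every dendrogram node with at least
`min_cluster_size` (default 3) members is tested two-sided against the
rest of the cohort via `fisher_exact_2x2()` (hypergeometric sum, same tie
tolerance). No multiplicity correction is applied by default — raw
per-node p-values are reported, with Bonferroni available via
`ppin_control(correction = "bonferroni")`.

**Headline cluster choice.** Among significant nodes of a dominance class
the pipeline reports the *most significant* node. We initially followed
the alternative rule "report maximal significant nodes" (closest to the
root), but on strongly structured cohorts it degenerates: every ancestor
of a tight enriched block inherits nominal significance, up to near-root
nodes that are "significant" only because a handful of samples merge last
(e.g. a 137-of-143-member node tested against a 6-member complement).
The minimum-p node stays on the enriched block itself; the full node table
(with a `maximal` flag) is always available in `fit$clusters` so users can
apply either convention.

**Seed genes.** A patient's candidate genes are those with at least one
surviving variant carried het or hom-alt; genes are ranked by the minimum
genotype-test p over the patient's variants in the gene, ties broken
lexicographically, and the top `seed_gene_count` (default 60) become
seeds. At desk scale each sample carries far fewer qualifying genes than
60, so the cap rarely binds; it matters for full-exome inputs where
thousands of variants survive.

**Network construction.** With the maximum path length fixed at 2, a
patient network contains the mapped seeds plus every *imputed* protein
adjacent to ≥ 2 distinct seeds. Edges are seed–seed and seed–imputed
interactome edges; imputed–imputed edges lie on no seed-to-seed path of
length ≤ 2 and are excluded by default (`keep_imputed_edges` re-enables
them). The network is then restricted to its largest connected component —
ties broken by seed count, then by the lexicographically smallest node
set — matching the single connected graphs that layered visualizations
assume (`largest_component = FALSE` disables this).

**Distances and clustering.** The Jaccard distance is computed on node
sets: nodes (genes) are the biological payload, and the unique-gene
analysis downstream is node-based. An edge-set variant is available
(`jaccard_on = "edges"`). UPGMA is implemented in-package so that ties
merge deterministically (by lexicographically smallest member id); heights
are average cross-pair distances and are non-decreasing, so the dendrogram
is ultrametric. The Newick serialization assigns each branch the parent
height minus the child height, with leaves at height zero.

**Separation score.** For gene sets A and B,
`s_AB = d_AB − (d_AA + d_BB)/2`, where `d_AA` averages each A-gene's
hop distance to its nearest other A-gene and `d_AB` averages, over all
|A| + |B| genes, the distance to the nearest gene of the opposite set
(shared genes contribute zero). Distances are unweighted hop counts —
confidence scores act only as a load-time cutoff (default 400, STRING's
"medium"). Unreachable pairs are excluded from the means and counted
(`n_unreachable`); if every cross-set pair is unreachable the score is
reported as undefined (`NA`), never as a number.

## The synthetic-cohort generator

No patient-level exome data of this kind are publicly deposited, so the
package treats the generator as a first-class, tested module. It emulates:

* a **61-case / 82-control** cohort (the study design scale),
* an interactome with a hub-dominated degree distribution *and* dense
  local communities,
* a planted, connected, localized **disease module** preferentially hit by
  deleterious variants in cases,
* realistic nuisance processes: site-quality failures, variant-density
  clusters, missing genotypes, and background deleterious variants in
  random genes.

**Interactome topology.** The generator grows a preferential-attachment
backbone (`attachment_degree = 3`, complete core, `m` edges per new node —
edge count `choose(m+1, 2) + m(n−m−1)`) and overlays 30 disjoint
20-gene communities wired internally with probability 0.9. The overlay is
essential, not cosmetic: scale-free growth alone has vanishing local
clustering, so no 15-gene connected subgraph is dense, and a "module"
carved from such a graph cannot make its carriers' networks overlap — the
length-2 imputation mechanism needs common neighbors. Dense communities
are exactly what protein complexes and core pathways look like in curated
interactomes. `n_communities = 0` recovers a pure preferential-attachment
graph for topology experiments.

**Module planting.** `plant_disease_module()` selects a connected induced
subgraph by random-walk expansion: the start node is drawn from the
degree-weighted (walk-stationary) distribution, and each step adds a
frontier node with probability proportional to the fourth power of its
edge count into the current set. The strong cohesion bias keeps the walk
inside one dense community, so the planted module is localized — the
property the whole analysis is designed to detect. Across seeds the
induced module density is typically 0.5–0.9.

**Variant planting.** A hit sample receives 1–3 heterozygous variants in
distinct random module genes, with weights (0.1, 0.2, 0.7): affected
carriers typically bear several damaged module genes, which is what makes
two carriers' networks overlap (a single module seed cannot trigger
length-2 imputation of the module neighborhood on its own). Each event
draws one of ten per-gene sites, so carriers may or may not share a site
and site-level quality failures do not wipe out a gene for all carriers
at once. Every sample also receives `background_variants_per_sample = 150`
variants in random non-module genes, of which
`fraction_deleterious_background = 0.05` pass the deleteriousness filter —
roughly 7–8 passing background genes per sample, keeping each patient's
network anchored on (for carriers) the module rather than on background
noise, at desk scale. Passing annotation scores are drawn uniformly inside
the passing region (PolyPhen ∈ [0.957, 1], SIFT ∈ [0, 0.049],
CADD ∈ [15.1, 40], MAF ∈ [0, 0.049]); failing background variants violate
exactly one randomly chosen threshold, drawn clear of the boundary, so
filter outcomes are unambiguous and auditable against the planted truth.

**Nuisance realism.** About 5% of sites (configurable) fail site-quality
filtering overall, the failure split evenly across the five quality
fields; five 3-variant clusters within 10 bp exercise the density rule;
non-carrier genotypes go missing at rate 0.01. Quality noise is
deliberately interpreted as an *overall* ~5% site loss: a 5%-per-field
rate would compound to a ~23% quality funnel, unlike post-calling exome
data, and would erode the planted 80%/5% hit-rate contrast the design
specifies.

**What the generator does not emulate.** Linkage disequilibrium,
population structure, per-gene mutation-rate variation, multi-allelic
sites, annotation-score correlation, and realistic per-sample variant
loads (hundreds of thousands). Passing tests therefore demonstrate the
pipeline's correctness and its ability to recover a planted, localized
signal under controlled noise — not calibrated performance on real exomes.

## Numerical and degenerate-input choices

* Probability ties in exact tests: relative tolerance 1e-12 (log-space).
* UPGMA ties: lexicographic by smallest member id; sample order in input
  files never affects results (samples are sorted on read).
* Jaccard of two empty networks: 1 with a warning.
* Samples with no qualifying gene or no seed mapping to the interactome
  are excluded from clustering and listed in `excluded_samples`.
* Missing genotypes are excluded from genotype tables (no imputation);
  missing annotation scores fail filtering under a distinct `unannotated`
  reason.
* Degenerate Fisher margins (an empty row/column) give p = 1.
* Interactome duplicate edges keep the maximum score; self-loops drop.

## Problem sizes in the test suite

Unit tests run on toy graphs (≤ 50 nodes) and small cohorts (26 samples,
200-gene interactome). The acceptance tests use: all 2×2 tables with
margins ≤ 15 against an enumeration oracle; 25 random 2×3 tables (margins
≤ 12) against brute-force enumeration, with Monte Carlo agreement at 1e5
replicates; 100 random distance matrices (n = 4–8) against
`stats::hclust` + `cophenetic`; 100 random graphs (≤ 50 nodes) against
exhaustive path enumeration; separation scores on a 200-node random graph
against hand-rolled BFS; and ten full 61/82 end-to-end replicates for
planted-module recovery. These sizes keep the whole suite under a couple
of minutes on one CPU while exercising every contract.

## Known limitations

* The exact 2×3 test is conservative for sparse tables; nominal α
  overstates the realized rejection rate at singleton-carrier sites.
* Gene-level seed ranking uses the minimum variant p per gene, which
  favors genes with many variants; no per-gene length normalization is
  attempted.
* The separation score is reported without a degree-preserving
  randomization null; its sign, not a z-score, is the interpretable
  output.
* Cluster p-values are nominal and nodes are nested, so the per-node
  Fisher tests are not independent; the optional Bonferroni correction is
  conservative in compensation.
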