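# ppinet

Patient protein–protein interaction (PPI) network clustering for
case/control exome studies.

## The problem

Univariate variant-by-variant association tests are underpowered for rare,
heterogeneous disorders: different patients can carry deleterious variants
in *different* genes that converge on one disease mechanism. `ppinet`
implements a multivariate alternative for case/control exome cohorts, the
kind of design used to study severe early-onset preeclampsia: instead of
asking whether any single variant separates cases from controls, it asks
whether **subsets of patients share protein-interaction networks** built
from their own damaged genes. It is aimed at statistical geneticists and
systems-biology analysts with a multi-sample VCF, a variant annotation
table, a phenotype file, and a STRING-style interactome edge list.

## The method

1. **Variant filtering.** Sites are removed when ≥3 variants fall within a
   10-bp window, ≥4 alignments map equally well, depth < 10, site quality
   < 30, QD < 1.5, or Phred-scaled strand-bias FS > 200. Surviving exonic
   variants are kept as *deleterious* when PolyPhen-2 HDIV ≥ 0.957,
   SIFT < 0.05, CADD > 15 and reference MAF < 0.05.
2. **Genotype testing.** Each variant's 2×3 table of hom-ref / het /
   hom-alt counts in cases vs controls is tested with a two-sided exact
   Fisher test (all fixed-margin tables enumerated under the multivariate
   hypergeometric null; Monte Carlo sampling via Patefield's algorithm for
   tables too large to enumerate).
3. **Seed genes and patient networks.** For each patient, the top *k* = 60
   genes in which that patient carries a qualifying variant (ranked by
   genotype-test p) seed a personal PPI network on the interactome: seeds
   connected directly or through a single *imputed* intermediary protein
   (path length ≤ 2), restricted to the largest connected component.
4. **Clustering.** Patients are compared by the Jaccard distance between
   their network node sets, `d(G1, G2) = 1 − |V1 ∩ V2| / |V1 ∪ V2|`, and
   clustered with UPGMA (average linkage). Every dendrogram node of size
   ≥ 3 is tested for case/control enrichment with a two-sided 2×2 Fisher
   exact test; per dominance class the most significant node is the
   headline cluster.
5. **Layered networks, unique genes, separation.** Each cluster's member
   networks are unioned into a layered network with per-node/edge support
   counts; genes unique to the case- vs control-dominated layers are
   extracted and compared with the interactome separation score
   `s_AB = d_AB − (d_AA + d_BB)/2` (nearest-neighbor shortest-path
   distances; positive values mean topologically separated gene sets) and
   a hypergeometric over-representation test.

Because cohort genotype data of this kind are not publicly deposited, the
package ships a first-class synthetic-cohort generator: a scale-free
interactome with dense community structure, a planted connected "disease
module", and a 61-case / 82-control cohort whose cases carry deleterious
module variants at a configurable rate. Every pipeline stage is validated
against this planted truth.

## Worked example

```r
library(ppinet)

cfg <- sim_config(rng_seed = 42)                    # 61 cases / 82 controls
g   <- generate_interactome(cfg)
mod <- plant_disease_module(g, cfg$module_size, rng_seed = 42)
sim <- generate_cohort(cfg, g, mod, "demo")

fit <- ppin_analysis(sim$paths$vcf, sim$paths$annotations,
                     sim$paths$phenotypes, g)
print(fit)
```

```
ppin_analysis
  cohort: 61 cases / 82 controls
  variants: 17541 input -> 16638 quality-pass -> 900 deleterious
  networks: 143 samples (0 excluded)
  clusters: 98 tested, 39 significant at alpha = 0.05
  case-dominated cluster: 35 cases / 4 controls, p = 1.2e-12
  control-dominated cluster: 1 cases / 11 controls, p = 0.0134
  separation score (unique case vs control genes): s_AB = 0.4109
```

The cohort's sites funnel from 17,541 calls to 900 predicted deleterious
variants; all 143 patients yield a network. The dendrogram
contains a strongly case-dominated cluster (35 of 61 cases against only 4
controls, Fisher p ≈ 1.2e-12). The genes unique to that cluster's layered
network recover 14 of the 15 planted module genes
(`overrepresentation_test` p ≈ 3.4e-06 against the interactome universe),
and the positive separation score (`s_AB = 0.41`) confirms the case and
control layers occupy distinct interactome neighborhoods:

```r
fit$separation
#> separation_result
#>   d_AA = 1.020057  d_BB = 1.222222  d_AB = 1.532067
#>   s_AB = 0.4109267 (sets topologically separated)
```

`write_ppin_outputs(fit, "out")` serializes the dendrogram (Newick), the
cluster table (TSV/JSON), layered networks (GraphML with `role` and
`support` attributes), unique genes, the separation result, and a report
echoing every resolved threshold. Identical inputs and seeds reproduce
every output byte for byte.

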