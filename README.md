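# domnet

Signed weighted molecular correlation networks for direct-infusion HR-MS
profiles of dissolved organic matter (DOM).

## The problem

During plant litter decomposition, the water-leachable organic matter
(DOM) carries a molecular record of both the litter source and the
microbial community working on it. Direct-infusion HR-MS resolves
thousands of exact masses per leachate sample; after molecular-formula
assignment, each sum formula's relative intensity across samples becomes
one feature. `domnet` is for researchers who want to move from such peak
lists to:

* a **signed weighted correlation network** over sum formulas, with
  modules (co-varying molecular families) and per-sample module
  eigengenes;
* a **3-D classical-MDS embedding** of the network;
* **pathway coverage statistics** against a KEGG-style compound table,
  with the per-formula intensity deduplication rule (one intensity
  contribution per sum formula per pathway);
* **convergence/divergence trends** — PCA trajectories and between-group
  Euclidean distance changes over the decomposition series;
* a **module × pathway overlay** separating pathways concentrated in one
  module from those spread ubiquitously.

The edge weight between features $i$ and $j$ is the signed
soft-threshold adjacency

$$A_{ij} = \left(\tfrac{1}{2}(1 + cor_{ij})\right)^p, \qquad p = 9
\text{ by default},$$

with $cor_{ij}$ the Pearson correlation of relative intensities across
samples: anticorrelated molecules get near-zero weight, and the power
sharpens the contrast so the connectivity distribution can approach a
scale-free form. Modules come from average-linkage hierarchical
clustering of $1 - A$; module eigengenes are PC1 sample scores of each
module's standardized features.

A synthetic-data generator emulates a 4-litter × 2-site × 3-replicate ×
5-timepoint decomposition design (120 leachate samples) with planted
correlation blocks — litter-specific, convergent, and noise — so every
stage can be verified against ground truth. See the methods vignette
(`vignettes/domnet-methods.Rmd`) for the model, parameter rationale, and
limitations.

## Worked example

```r
library(domnet)

sim <- generate_feature_matrix(study_design(seed = 42))
sim
#> Synthetic DOM feature matrix: 200 features x 120 samples; 4 planted blocks

A    <- signed_adjacency(correlation_matrix(sim$matrix), power = 9)
mods <- detect_modules(A, min_module_size = 30)
mods
#> Module set: 4 modules over 200 features
#> colors
#>      blue     brown turquoise    yellow
#>        50        50        50        50

eig <- module_eigenvalues(sim$matrix, mods)
round(eig$var_explained, 3)
#>      blue     brown turquoise    yellow
#>     0.809     0.798     0.836     0.673

db <- generate_pathway_db(rownames(sim$matrix), seed = 43)
match_formulas(rownames(sim$matrix), db)
#> Formula matches: 42 matched formulas (21% match rate), mean 3.19 structure suggestions

group_distance_trend(sim$matrix, sim$metadata)
#> Between-group distance trend (full mode): +417.3% from day 2 to day 22

classical_mds(1 - A, k = 3)
#> Classical MDS embedding: 200 points in 3 dimensions; 51.2 % of positive eigenvalue mass captured

truth <- setNames(sim$truth$block, sim$truth$feature)
adjusted_rand_index(mods$colors, truth[names(mods$colors)])
#> [1] 1
```

Reading the output: the four detected modules coincide exactly with the
four planted feature blocks (adjusted Rand index 1); each module
eigengene captures 67–84 % of its module's variance; about a fifth of
the formulas hit the synthetic annotation table with ~3 isomeric
structure suggestions each, mirroring realistic exact-mass ambiguity;
and the litter groups diverge strongly over the series because the
planted litter-specific blocks ramp up from a shared starting
composition.

The same stages run from the shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/domnet.R", package = "domnet"))')" \
    run --seed 42 --out runs/demo
```

`run_pipeline()` / the `run` subcommand chain simulate → network → embed
→ coverage → trend → overlay into a directory of TSV tables plus a JSON
run report, byte-identical across runs with the same config and seed.

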