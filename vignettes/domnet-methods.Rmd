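---
title: "Methods: signed molecular correlation networks for DOM HR-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed molecular correlation networks for DOM HR-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`domnet` analyses direct-infusion HR-MS profiles of dissolved organic
matter (DOM) from decomposing plant litter. Each detected exact mass is
reduced to a CHNOS sum formula; each formula's relative intensity across
samples is one feature. The package then asks two questions: which groups
of molecules co-vary across the decomposition series (network modules),
and which biochemical functions those molecules witness (pathway
coverage).

The statistical core is a signed weighted correlation network. For
features $i, j$ with Pearson correlation $cor_{ij}$ across samples, the
edge weight is

$$A_{ij} = \left(\tfrac{1}{2}\,(1 + cor_{ij})\right)^{p},$$

so $A \in [0, 1]$, perfectly anticorrelated features get weight 0, and
uncorrelated features get $0.5^p \approx 0.002$ at the default $p = 9$.
The signed map matters for DOM: molecules produced while others are
consumed should be far apart in the network, not adjacent as they would
be under an unsigned $|cor|^p$ map. The soft-threshold power is
conventionally chosen so that the connectivity distribution
$k_i = \sum_{j \ne i} A_{ij}$ approximates a power law; `scale_free_fit()`
reports the $R^2$ of the log-log regression of the binned connectivity
density so users can check this for their own data. On the synthetic
designs shipped with the package the planted block structure is
deliberately *not* scale-free, and the reported $R^2$ is correspondingly
low; the diagnostic is exposed, not enforced.

Modules are found by average-linkage hierarchical clustering of node
dissimilarities $D = 1 - A$, cutting the dendrogram at a constant height
(default 0.995 of the maximum merge height) and keeping clusters of at
least `min_module_size` (default 30) features. Modules are named by the
conventional size-ordered color palette (turquoise, blue, brown, ...);
unassigned features are grey. Each module is summarized by its
eigengene: features are standardized across samples, and the eigengene is
the first right singular vector of the standardized block — the sample
scores of PC1 — scaled to unit variance and oriented so that it
correlates positively with the module's mean standardized profile. The
fraction of variance explained by PC1 is reported alongside.

The whole-network geometry is visualized by classical (Torgerson) MDS of
$1 - A$ into three dimensions.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| S/N threshold | 4 (strict `>`) | ratio | peaks at or below the acquisition noise floor are discarded |
| acquisition window | 175–1000 | m/z | direct-infusion Orbitrap scan range for DOM |
| blank window | 2 | ppm | blank masses never match by exact float equality |
| assignment tolerance | 2 | ppm | typical Orbitrap mass accuracy after calibration |
| element ranges | C 1–100, H 0–200, N 0–5, O 0–80, S 0–2 | atoms | spans DOM formula space without combinatorial blow-up |
| H/C, O/C windows | 0.3–2.5, ≤ 1.2 | ratio | standard DOM plausibility screen; each rule switchable |
| soft power $p$ | 9 | – | steep enough to suppress weak correlations while keeping the map smooth |
| min module size | 30 | features | smaller clusters are rarely interpretable molecular families |
| cut height | 0.995 × tree max | – | separates everything that is distinctly more similar than the bulk |
| ubiquity threshold | 0.5 | fraction | a pathway with no module holding > 50 % of its molecules is "spread" |

Formula assignment enumerates compositions exhaustively: for every
(C, N, O, S) combination in range the hydrogen count is solved from the
residual mass, which is exact for tolerances far below 0.5 u and turns a
five-dimensional search into a fast four-dimensional one. The test suite
verifies candidate sets against a literal five-dimensional enumeration.
Relative mass error is measured against the candidate mass,
$10^6 (m_\text{obs} - m_\text{cand}) / m_\text{cand}$. Ties in $|ppm|$
are broken by fewer heteroatoms (N+S), then lower H — a documented
determinism device, not a chemical claim. All ions are treated as singly
deprotonated ($[M-H]^-$, proton mass 1.007276466 u), the dominant species
in negative-ESI DOM.

# The synthetic-data generator

The generator emulates a lab-scale litter decomposition study: 4 litter
types (beech, oak, pine, grass) × 2 sites × 3 replicates, leachates
sampled on days 2, 4, 8, 15 and 22 — 120 leachate samples. Day-0 initial
litter samples can be added with `include_day0 = TRUE`; the default
feature matrix is the 120 leachate samples, matching the network input
size of the emulated design. Features carry real, plausible CHNOS
formulas so that the peak-list, assignment and annotation stages operate
on the same objects a real study would.

Features are organized in planted blocks with known drivers:

* **litter-specific** — an indicator for one litter type times a linear
  ramp over the leachate days (litter-specific signals consolidate as
  decomposition progresses);
* **convergence** — the same ramp shared by a subset of litters;
  a *decreasing* variant models initial similarity that fades;
* **time** — a global ramp;
* **noise** — no planted structure.

Per feature, log-intensity is `baseline + alpha * z + sigma * eps` with
`z` the standardized block driver and `eps` i.i.d. standard normal.
Intensities are exponentiated (lognormal noise: HR-MS intensities are
positive and right-skewed) and each sample is normalized to sum 1. The
amplitude is parameterized as $\alpha = \sigma\sqrt{r/(1-r)}$ so that the
log-scale within-block correlation equals the target $r$ (default 0.9);
with $\sigma = 0$ block features are exact multiples of each other and
the empirical correlation is exactly 1. The default
$\sigma = 0.3$ corresponds to roughly 30 % multiplicative CV, a typical
replicate variability for direct-infusion Orbitrap intensities. On the
raw intensity scale the lognormal transform attenuates the correlation
slightly below the log-scale target; the generator's contract therefore
promises the target only within ±0.15 at default noise, which the tests
check empirically.

Two consequences of closure (column normalization) are worth knowing.
First, raw-scale correlations are computed on *relative* intensities, so
all features share the column total; "noise" features end up positively
correlated with one another through the common $1/T_s$ factor and
typically form their own module rather than dissolving into grey. The
ground-truth labels treat the noise block as its own class, so module
recovery is scored correctly either way. Second, between-group distances
grow strongly along the series because litter-specific blocks ramp from a
common start; the percent-change statistic on the default design is
therefore large and positive (divergence), not the single-digit change a
real between-community comparison would show. The generator plants
qualitative structure — litter-specific, convergent, unstructured — with
known membership; it does not calibrate effect sizes to any particular
instrument or study.

What the generator does **not** emulate: isotopologue patterns, adducts
other than $[M-H]^-$, charge states > 1, mass-dependent intensity bias,
batch effects, or missingness structure. Passing tests on synthetic data
therefore demonstrate algorithmic correctness against a known truth, not
instrument realism.

The annotation generator mirrors the matching statistics of real
KEGG-style lookups: a configurable fraction of formulas (default 0.2) is
annotated, each annotated formula receives `1 + Poisson(1.9)` compound
records (mean 2.9 structure suggestions per matched formula — isomers are
indistinguishable by exact mass), and pathway sizes are drawn so that
detected members cover only part of each pathway.

# Pathway statistics

Matching is by exact canonical formula string; isomers cannot be
distinguished. Per pathway, summed relative intensity allows **one
contribution per sum formula per pathway**: a formula matching three
isomeric compounds in one pathway contributes its intensity once; a
formula matching compounds in two different pathways contributes once to
each. The tests assert this rule is invariant to duplicating annotation
records.

Coverage is the number of distinct detected member *compounds* divided by
the pathway size (switchable to formula counting): one formula may
witness several members, and pathway size counts members. Coverage
dispersion across sample groups (litter × day by default) uses a
detection threshold on group-mean relative intensity (default $10^{-4}$,
i.e. 0.01 % of the total ion current) — without a detection floor every
formula is "present" everywhere and the dispersion is trivially zero.
The cross-dataset comparison consumes an external coverage table (e.g.
from 16S-based functional predictions) as given; computing such
predictions is out of scope.

# Numerical choices and degenerate inputs

* Zero-variance features are excluded before correlation (undefined
  Pearson r), with a warning.
* `detect_modules` with `min_module_size > n` returns all-grey with a
  warning; identical features collapse to a single module.
* Size ties in module color assignment are broken by dendrogram cluster
  id, making color names deterministic.
* The optional "hybrid" cut reassigns grey features to the module with
  the highest mean adjacency when it exceeds a threshold (default 0.1) —
  a simplified, deterministic variant of dynamic hybrid tree cutting.
* A topological-overlap (TOM) dissimilarity is provided as an option;
  the default clusters $1 - A$ literally.
* Classical MDS truncates negative eigenvalues (non-Euclidean $1 - A$
  inputs) to zero, Torgerson-style, and reports the full eigenvalue
  vector plus the fraction of positive-eigenvalue mass captured. Axis
  signs are fixed by making the largest-magnitude loading positive.
* Eigengene orientation falls back to the sign of the summed feature
  loadings when the mean profile is constant.
* The percent-change trend statistic is defined only when the initial
  distance is positive; both day-0 and later-day anchoring are supported
  via `initial_day`.
* Single-feature modules return their standardized profile with a
  warning rather than failing.

Sample-size choices in the test and acceptance runs use the full default
design (200 features × 120 samples) for module recovery and the pipeline,
and small analytically tractable configurations (4–10 points, 5 × 4
tables, toy annotation tables) wherever an independent oracle — exhaustive
enumeration, hand arithmetic, eigendecomposition, rigid-alignment
geometry, `choose()`-based hypergeometric tails — verifies the
implementation.

# Known limitations

* Exact reproduction of any particular study's network (node count,
  module partition) is not attempted: assignment settings of real
  studies live in third-party tools, and the clustering cut that a given
  web application used is not recoverable. The cut parameters here are
  explicit and deterministic instead.
* Normalization to column sums is an assumption; other conventions
  (e.g. maximum-peak scaling) can be had with `normalize = "none"` plus
  user scaling.
* The enrichment p-values in the overlay are an optional extension (BH
  across the table); the overlay's primary outputs are descriptive
  counts, fractions, and the concentration index.
* Pearson correlation on compositional data inherits closure artifacts;
  the package follows the field's practice rather than switching to a
  log-ratio covariance, and documents the consequence above.
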