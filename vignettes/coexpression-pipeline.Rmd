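---
title: "Across-contrast co-expression network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-contrast co-expression network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

This vignette documents the statistical machinery behind `coexnet`: the
models each stage assumes, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The analysis in one paragraph

The pipeline targets factorial bulk RNA-seq designs of the kind used in
feed-efficiency studies: two breeds, two residual-feed-intake (RFI)
groups, three consecutive diet phases (growing high-concentrate H1,
zero-grazed grass ZG, finishing high-concentrate H2), sampled in liver
and skeletal muscle, with the same animals re-measured across phases and
tissues. Six differential-expression contrasts (RFI, breed, diet × two
tissues) each contribute their top-5% DEG set; together with a curated
transcription-factor list and a secretome list these define the node
candidates of six PCIT co-expression runs whose significant edges are
merged into one contrast-labelled network, clustered MCODE-style and
summarised by hubs, TF first neighbours and cross-contrast overlaps.
Transcription factors are additionally ranked by the RIF metrics for
differential wiring between the two levels of each contrast.

## Differential expression

Counts are modelled per gene as negative binomial with
`Var = μ + φ μ²`. Each contrast subsets one tissue's samples, filters to
genes with ≥ `cpm_threshold` (default 1) CPM in at least
`min_fraction` (default 0.5) of those samples — the count of qualifying
samples must reach `ceiling(min_fraction · n)` — TMM-normalises, and fits
`~ group (+ covariates)` by iteratively reweighted least squares through
edgeR, testing the group coefficient by likelihood ratio against χ²(1).
Dispersion is estimated per gene and shrunk toward the common trend with
`prior_df = 20` prior degrees of freedom.

Three modelling choices deserve a note:

* **Contrast pooling.** The RFI contrast pools both breeds and all diet
  phases of a tissue; the breed contrast pools both RFI groups and
  phases; the diet contrast compares the two high-concentrate phases
  (H1 + H2, the "HC" class) against ZG. The two HC phases differ in
  animal age, so the diet model carries the numeric `timepoint`
  (phase order 1, 2, 3) as a covariate. A three-level factor would be
  collinear with the diet class; the numeric coding keeps the diet effect
  identifiable while absorbing the linear time trend.
* **Top-5% rule.** Each contrast's DEG set has exactly
  `floor(0.05 · N)` members, with ties on adjusted p broken by raw p,
  then |log2FC| (descending), then gene ID, so selection is deterministic.
* **Calibration.** On null simulated data the oracle NB-GLM fit (true
  dispersions held fixed) produces uniform p-values, which the test suite
  verifies by a Kolmogorov–Smirnov check; dispersion *estimation* with
  shrinkage perturbs the p-value distribution slightly (detectable by KS
  at 2,000 genes) while leaving the type-I error at the 0.05 threshold
  nominal — the suite requires the fraction of null p < 0.05 to stay
  within [0.03, 0.07]. This is the expected price of moderated dispersion
  estimation, not a defect of the generator.

## RIF regulator scoring

For a regulator *i* and DE targets *j*, with `e1, e2` the per-condition
mean log2(CPM+1) of each target and `r1, r2` the within-condition
regulator–target Pearson correlations,

$$\mathrm{RIF1}_i = \frac{1}{n}\sum_j a_j d_j (r1_{ij} - r2_{ij})^2,
\qquad a_j = \tfrac{e1_j + e2_j}{2},\; d_j = e1_j - e2_j,$$

$$\mathrm{RIF2}_i = \frac{1}{n}\sum_j (e1_j\, r1_{ij})^2 - (e2_j\, r2_{ij})^2.$$

RIF1 is large for regulators whose co-expression with abundant, strongly
differentially expressed targets changes between conditions; RIF2 for
regulators whose ability to predict target abundance changes. Both are
z-standardised across regulators, and `|z| ≥ 1.96` is flagged — the
conventional two-sided 5% cut; the choice of cut only affects flagging,
not the scores. Expression enters on the log2(CPM+1) scale: correlations
of raw counts would be dominated by the mean–variance relationship,
whereas log-CPM keeps Pearson correlation a sensible association measure.
Condition pairs mirror the six DE contrasts. Swapping the condition
labels negates both raw metrics exactly; the suite asserts this
antisymmetry along with hand-computed single-regulator values.

## PCIT network inference

For every node trio the three first-order partial correlations

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
{\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}$$

yield an information-theoretic tolerance
`ε = mean(|partial/direct|)`, averaged over the trio's edges with
non-zero direct correlation (a zero direct correlation would make the
ratio undefined, so that term is skipped; if all three are zero the trio
eliminates nothing). The edge (x, y) is eliminated when some third node
dominates it in magnitude: `|r_xy| < ε |r_xz|` and `|r_xy| < ε |r_yz|`.
All comparisons use absolute correlations — the algorithm's semantics are
about magnitude of association, not sign. With fewer than three nodes
every edge is retained. The kernel is compiled (C++); a brute-force R
triple loop serves as its oracle in the tests up to n = 30.

Reported edges must additionally satisfy **both** significance rules:
`|r| ≥ abs_r` (default 0.80) and `|r| ≥ mean(|r|) + sd_mult · SD(|r|)`
(default 2) over all off-diagonal pairs of that run's matrix. The two
rules come from different parts of the method's description and neither
is stated to dominate, so they are conjoined; if the spread of `|r|` is
degenerate (SD = 0) only the absolute rule applies, with a warning.

Each contrast's PCIT run uses the node universe
*DEGs of that contrast ∪ all TFs ∪ all secretome genes*, restricted to
genes expressed in that tissue, with correlations computed over **all**
samples of the tissue on log2(CPM+1). The contrast identity of an edge is
the run that produced it; merging the six runs yields a multigraph keyed
by (gene pair, label), so a pair significant in two contrasts carries two
labelled edges — this is also how per-contrast hub degrees are counted.

## MCODE-style clustering

The labelled multigraph is collapsed to a simple graph. Vertex weights
are `k · density` of the highest k-core of the closed neighbourhood;
seeds are processed in decreasing weight (ties by gene ID, for
determinism) and expansion admits unvisited neighbours with weight above
`(1 − vwp)` times the seed's. Defaults mirror the Cytoscape
implementation's published defaults: degree cutoff 2, node-score cutoff
(`vwp`) 0.2, haircut on, fluff off. Haircut is implemented as the 2-core
of the cluster subgraph, i.e. iterated removal of singly connected
members. Clusters score `density × size`; each cluster's internal edges
are re-expanded to their contrast labels for the composition report.

## The synthetic-data generator

`simulate_counts()` draws, in a fixed order determined entirely by the
seed:

* baseline relative abundances ~ LogNormal(log 5, 1.2), normalised;
* gene dispersions φ ~ Gamma(shape 2, mean 0.1), the standard bulk
  RNA-seq regime (Var = μ + φμ²);
* library sizes ~ LogNormal(log 3·10⁶, 0.25) — a few million reads;
* per-contrast DE genes (default 60 per contrast, |log2FC| = 2, signs
  random, overlap across contrasts allowed), applied to the first level
  of each contrast on the log2-mean scale;
* latent module factors f ~ N(0, 1) per sample; module members add
  `loading · f + N(0, noise_sd)` (defaults 1.0 and 0.3) to their
  log2-mean — co-expression is induced on the mean scale rather than by
  duplicating counts, so downstream correlations are realistically noisy;
* one wired regulator (a TF) coupling to the first module's factor with
  `+0.8` in High-RFI and `−0.8` in Low-RFI samples (`flip` mode;
  `on_off` sets the second condition to zero); its 20 targets also carry
  a +1 log2FC RFI effect so they behave like DE targets.

Default layout: 2,000 genes, 100 TFs, 80 secretome genes (10 overlapping
the TF list), 3 modules of 20 genes planted among the non-TF secretome
genes — secretome genes enter every PCIT run's node universe, which makes
the planted modules visible to every contrast and lets module-recovery
precision be measured on each run. Cell size defaults to 10 animals per
breed × RFI cell, in the 8–11 range of per-group sample sizes typical of
such trials.

What the generator does **not** emulate: read-level artefacts (it starts
at counts), batch effects beyond library size, correlated animals
(repeated measures are recorded in the sample table but counts are drawn
independently), tissue-specific expression profiles, and compositional
coupling between genes (fold-changes are not renormalised per sample).
Passing tests therefore demonstrate algorithmic correctness and
statistical behaviour under a clean NB factorial model — not robustness
to the full messiness of real RNA-seq data.

## Numerical choices and degenerate inputs

* Zero library sizes, empty matrices, empty gene universes, fewer than 3
  samples per condition, unknown contrast labels and self-loops raise
  errors naming the offender; constant-expression genes get correlation 0
  with a warning; undefined partial correlations (unit conditioning
  correlation) return 0 and warn.
* Missing p-values are excluded from the BH denominator and returned NA.
* A TMM factor that cannot be computed falls back to 1 with a warning and
  factors are re-scaled to geometric mean 1. Note that TMM factors
  measure *composition* differences: a sample that is an exact depth
  scaling of another gets factor 1, because M-values are library-size
  normalised.
* All orderings that affect output (seed order, tie-breaks, edge sorting)
  are resolved by gene/cluster ID so reruns are bit-identical; the
  pipeline writes an md5 manifest and the suite asserts rerun identity.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scale a desk machine handles in
seconds: 2,000-gene simulations for calibration and the end-to-end run,
200–600-gene simulations for the wiring and module-recovery properties
(50 and 25 seeds respectively), and brute-force PCIT verification up to
30 nodes over 20 random matrices. These sizes were chosen as the smallest
at which the statistical properties under test are stable.

## Known limitations

* Real-data headline numbers of the motivating study design (thousands of
  DEGs, tens of thousands of connections) require the original sequencing
  data; the package reproduces the *procedures* and verifies them on
  synthetic ground truth instead.
* The PCIT kernel is O(n³) in the number of nodes; the per-contrast
  node-universe construction keeps n in the hundreds for desk-scale runs,
  but a full-transcriptome run (n ≳ 10⁴) would need hours.
* Pathway annotation is a generic hypergeometric over-representation test
  over user-supplied GMT sets; no curated pathway database ships with the
  package.
* `de_test` relies on edgeR's GLM machinery; exact replication of other
  dispersion-estimation flavours (e.g. quasi-likelihood) is out of scope.
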