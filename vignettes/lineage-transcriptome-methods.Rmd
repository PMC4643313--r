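---
title: "Methods: staging and quantifying embryonic lineage transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging and quantifying embryonic lineage transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagemap)
```

This vignette is the package's account of its statistical machinery: the
models and rules each function implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology was genuinely open.

## The analysis problem

Lineage-resolved embryo RNA-seq profiles small groups of cells (roughly
8–20) from dissected or sorted embryonic lineages across an ordered series
of developmental stages, with a few biological replicates per stage. Counts
are overdispersed relative to Poisson, library sizes vary between samples,
and the scientific questions are comparative: which genes change between
stages, how do co-regulated genes group into stage-specific modules, where
does a sample sit along developmental progression, when is a regulatory
network maximally active, and how do signalling perturbations shift lineage
composition in the embryo.

## Expression units

**Size factors** use the median-of-ratios estimator: for each gene expressed
in every sample, the ratio of a sample's count to the gene's geometric mean
is computed, and the sample's factor is the median ratio. Genes with any
zero count are excluded from the reference set (their geometric mean is
zero). The estimator is defined only up to a constant, so factors are
rescaled to geometric mean 1; planted library-size factors in the simulator
are mean-centered in log space for the same reason, making the two directly
comparable.

**FPKM** is the plain formula `count / ((length/1e3) * (total/1e6))`. The
per-sample total defaults to the column sum of the analyzed matrix rather
than an external "mapped fragments" figure; callers who have true totals can
supply them.

**The variance-stabilizing transform** assumes NB variance `μ + αμ²` with a
common dispersion α and applies the closed form of the stabilizing integral,
`VST(x) = (2/√α) asinh(√(αx))` on size-factor-normalized counts, with limit
`2√x` at α = 0. It is strictly increasing, maps 0 to 0, and on simulated NB
replicates holds the variance flat (within two-fold) over a 100-fold mean
range. The common α is estimated by a pooled method-of-moments median with a
floor of 1e-8; the formula-level choice is ours since only the transform
family is standard.

**Mean-relative (stage-scaled) expression** averages replicates within
stage, takes `log2(x + 1)` (pseudocount 1 and base 2 are defaults; both
configurable) and centers each gene on its cross-stage mean. Rows sum to
zero by construction, so "preferential activity" (strictly positive relative
expression) is automatically a contrast against the gene's own average
level.

## Differential expression

The test is an exact conditioned NB test. For a contrast between stage
groups A and B, a gene's counts are summed within each group. Under the null
of a shared normalized mean, the group sums are NB with means proportional
to the summed size factors and effective sizes `S²/(α Σs²)` (the size of a
sum of independent NB variables with per-sample means `q·s_j`). Conditional
on the observed total T, the two-sided p-value is the total conditional
probability of splits `(a, T−a)` at most as probable as the observed one.
This choice of two-sidedness (probability ordering) matches the exact-test
convention for discrete distributions; the whole split range `0..T` is
enumerated, which is exact and fast at the totals that arise here.

Per-gene dispersions are method-of-moments estimates pooled over
within-condition variances, `α̂ = (v − μ·mean(1/s)) / μ²`, floored at 1e-8.
A mean–dispersion trend `α(μ) = a₀ + a₁/μ` is fitted by gamma-family
regression and the working dispersion is the **maximum** of the gene-wise
estimate and the trend — a deliberately conservative sharing rule, chosen
because with n = 4 replicates gene-wise moments are noisy and underestimated
dispersions inflate false positives; on null simulations the resulting raw
p < 0.05 fraction sits near 0.03–0.05.

Multiple testing uses Benjamini–Hochberg within each contrast. Whether a
published "p < 0.05" gate refers to raw or adjusted values is often
ambiguous; the selection gate here defaults to **adjusted** p (standard for
genome-wide screens) and exposes `p_col = "pval"` for the raw reading.

## Dynamic genes and expression modules

A gene is *dynamic* when (a) it is significant in at least `min_contrasts`
(default 1) pairwise stage contrast — i.e. transcribed differentially
between at least two stages — and (b) its stage-mean FPKM exceeds 10 in at
least one stage. The FPKM > 10 floor is the conventional robust-detection
threshold for low-input libraries. An alternative reading of "differential
between at least two stages" (significant in ≥ 2 contrasts) is available via
`min_contrasts = 2`.

Modules are found by agglomerative clustering of the dynamic genes'
mean-relative profiles. Distance is 1 − Pearson correlation between
profiles — grouping genes by profile *shape* ("maximally expressed in
morulae", "common to morula and ICM", ...) regardless of amplitude — with
average linkage, and the tree is cut into exactly k clusters (default
k = 10); a height cut is available. Euclidean distance is offered for
amplitude-sensitive clustering. Labels are renumbered along dendrogram leaf
order so the labeling is deterministic and heatmaps are reproducible; with
continuous data, tied merge heights have probability zero, and permuting
gene order yields the same partition up to relabeling (tested).

## Diffusion-map staging

The embedding builds a Gaussian kernel `exp(−d²/2σ²)` on Euclidean sample
distances, density-normalizes it with anisotropy exponent 1 (dividing by the
product of kernel row sums, which removes sampling-density effects), and
row-normalizes to a stochastic matrix. Diffusion components are the
eigenvectors for the largest non-unit eigenvalues, computed via the
symmetric conjugate for numerical stability. Defaults: `σ = "auto"` (median
nonzero pairwise distance — scale-free and robust for a few dozen samples),
three components, input = variance-stabilized expression of dynamic genes.
Eigenvector sign is arbitrary, so components are oriented along the supplied
stage order when a design is given (first nonzero loading positive
otherwise); sign conventions change no distance or correlation magnitude.

## Network activity projection

Curated interaction networks (SIF or edge-list; signs `activation` /
`inhibition`) are reduced to the induced subgraph on dynamic genes plus
anchor regulators (default Pou5f1, Nanog, Sox2). Anchors are kept even when
isolated — they are the fixed focus of the reduction — while other isolated
nodes are dropped by default. Symbol matching is case-insensitive because
curated resources mix species symbol casing.

A node is active at a stage iff its mean-relative expression there is
**strictly** positive: a perfectly flat gene is centered to zero everywhere
and must not appear "preferentially active" at any stage. An edge is active
iff both endpoints are. The per-stage active node/edge counts form a
connectivity profile whose argmax (ties broken by stage order) is the
network's activity peak. A companion rule, `core_coexpression_stages()`,
returns the exact set of stages at which every member of a core regulatory
set exceeds an expression floor (default FPKM 10).

## Pathway scores and enrichment

A pathway's score per condition is the sum of member FPKM normalized for
pathway size, i.e. the mean over members. Members absent from the
expression matrix are excluded from the size normalization by default (and
reported); `count_missing = TRUE` counts them as zeros — the stricter
reading when absence means non-expression rather than non-measurement.
Scaled scores divide each pathway row by its cross-condition mean (rows with
zero mean are set to 0 and flagged). Over-representation is the upper-tail
hypergeometric probability `P(X ≥ k)` with all sets intersected with the
universe first; DAG-aware conditional testing is out of scope because no
ontology topology ships with the package.

## Immunofluorescence quantification

Marker channels are divided by the same cell's DAPI intensity, so staining
and illumination scale per cell cancels; cells with non-positive DAPI are
dropped and counted. Positivity defaults to an Otsu threshold per embryo on
log10 normalized intensities — absolute levels vary between embryos, and
log-normal intensity modes become symmetric on the log scale — with fixed
and quantile rules available; embryos with fewer than 3 cells fall back to a
global threshold with a warning, and every run records the thresholds used.

Cells are classified NANOG-only (N+/G−), GATA6-only (G+/N−), coexpressing
(N+/G+), double-negative (otherwise): mutually exclusive, exhaustive.
NANOG-high means NANOG-positive with normalized NANOG at least 1.5× the
average over all cells of the same embryo (inclusive comparison; the
per-embryo scope is the default since the averaging scope is a free choice,
with per-treatment scope exposed).

Treatment statistics operate on **per-embryo fractions** — the embryo is the
experimental unit; per-cell testing would pseudo-replicate — via one-way
fixed-effects ANOVA and Tukey HSD pairwise p-values from the
studentized-range distribution. Degenerate inputs are defined explicitly:
identical values everywhere give F = 0 and p = 1; zero within-group variance
with unequal means reports p floored at 1e-15.

## The synthetic-data generator

The generator exists so that every pipeline stage can be scored against
recorded ground truth. Counts are NB with mean
`baseline_i × profile_i(stage) × libfactor_j` and variance `μ + αμ²`
(`α = 0` gives Poisson): per-gene baselines are log-normal around
`baseline_mean` (default 50, spread 1 log unit — low and intermediate
expression for most genes, a long right tail for a few); a configurable
fraction of genes (default 65%) is expressed at all, so per-sample detection
rates land in the 60–70% regime characteristic of small-cell-number
libraries; library-size factors are log-normal (sd 0.15) centered to
geometric mean 1; gene lengths are uniform on 0.5–5 kb so FPKM is exactly
invertible from ground truth. Defaults: 4 replicates per stage (a realistic
embryo-study replication level; the choice is the package's, not a
published value), dispersion 0.1, 10% dynamic genes in 10 modules, and a
stage set mirroring a mouse series (E2.5 → diapause) though any ordered
labels are accepted.

Two planted-structure catalogues serve different validation goals:

* `default_module_profiles()` — stage peaks, their log-scale antipodal
  valleys, and early/late half-plateaus (then adjacent plateaus and ramps
  for larger k). These are chosen for *identifiability*: centered log
  profiles have pairwise |correlation| ≤ ~0.6, so module recovery measures
  the clustering, not an accident of profile collinearity.
* `wave_module_profiles()` — Gaussian bumps whose peaks sweep the stage
  axis. These encode a *trajectory*: adjacent stages share partially
  overlapping modules, so transcriptome distance grows with stage
  separation, which is the premise of staging by diffusion map. Maximally
  distinct shapes deliberately lack this property, which is why staging
  simulations use waves while module-recovery simulations use the default
  catalogue.

The IF simulator draws per-cell intensities log-normal around class-specific
channel means (strong positive/negative separation, sd 0.3 log units), with
a per-embryo intensity multiplier shared by all channels (cancelled exactly
by DAPI normalization) and Dirichlet jitter of per-embryo class proportions.
The default treatment arms emulate a lineage-segregation inhibitor
experiment: an ERK-inhibited arm with an expanded NANOG-only compartment and
suppressed GATA6-only compartment, and a WNT-inhibited arm with suppressed
GATA6-only cells and an enlarged NANOG-positive compartment. The WNT effect
is planted through the *positive-compartment size* because the NANOG-high
rule is adaptive — its threshold scales with the embryo mean, so uniform
intensity shifts within positives cancel, and an enlarged positive
compartment is what measurably raises the NANOG-high fraction.

What the generator does **not** emulate: zero inflation and dropout beyond
all-or-nothing silent genes, GC/length biases and 3′ coverage bias from
preamplification, batch effects, within-stage heterogeneity or doublets in
the IF tables, and spatial intensity artefacts. Passing recovery tests
therefore demonstrates correctness of the algorithms under the stated
generative model, not robustness to every artefact of real embryo data.

## Problem sizes and numerical choices

Validation simulations use 2,000 genes × 16 samples (200 dynamic genes, 10
modules), 100 repeated 400-gene simulations for network-peak recovery, and
1,000 replicates for ANOVA calibration — sizes at which every documented
property is stable across seeds while the full suite runs in well under a
minute per component. Numerical tie-breaks and floors: dispersions floored
at 1e-8; activity requires strictly positive relative expression; the
connectivity argmax takes the earliest stage on ties; Otsu takes the lowest
maximizing threshold; exact-test probability comparisons use a 1e-7
relative tolerance to absorb floating-point noise in `p(a) ≤ p(obs)`.

## Known limitations

Single-factor designs only (no covariates or batch terms); no fold-change
shrinkage; global-bandwidth diffusion maps (no locally adaptive σ); no
Boolean network dynamics — activity projection is a static overlay; GO/KEGG
content, identifier mapping and orthology are user-supplied inputs by
design.
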