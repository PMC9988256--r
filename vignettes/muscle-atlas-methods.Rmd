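---
title: "Models and methods behind the myoatlas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the myoatlas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the numerical choices and
the synthetic study design that `myoatlas` implements, in the spirit of the
methods sections of the established expression-analysis packages it builds
on. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The study design being modeled

The pipeline targets a repeated-measures atlas: `n` individuals each
contribute biopsies from seven leg-muscle sites (GR, STM, STD, RF, VL, VM,
GL), which fall into three latent groups — the hamstring-graft muscles
(G1: GR, STM, STD), the quadriceps (G2: RF, VL, VM) and the lower-leg GL
(G3). Two design facts drive every model choice:

* **Individuals are blocks.** Inter-individual variation in muscle
  transcriptomes is larger than inter-muscle variation, so every
  association test uses the mixed model `y ~ muscle + (1 | individual)`
  rather than a fixed-effects ANOVA.
* **Cell-type composition is a confounder.** Muscles differ in vascularity
  and fiber-type make-up; a gene can differ between muscles either because
  myonuclei transcribe it differently (muscle-intrinsic) or because the
  tissue contains different cell-type proportions. The pipeline estimates
  composition from marker genes and explicitly separates the two.

## Preprocessing

Samples need more than 5 million assigned reads (strict inequality). Genes
are kept when they have 10 or more reads in at least 16 samples — 16 being
the size of the smallest per-muscle group in the reference design.
Normalization is TMM (`edgeR::calcNormFactors`: 30% two-sided log-ratio
trim, 5% absolute-intensity trim, precision weights, reference column the
one whose upper quartile is closest to the mean upper quartile); factors
have geometric mean 1. Log expression is
`log2((count + 0.5) / (effective library size in millions))`.

The per-gene variance decomposition fits a fixed-effects linear model over
the supplied design factors and reports each factor's Type II partial sum
of squares as a percentage of the summed table (car::Anova). When a gene is
fit perfectly (zero residual — common for constructed test genes), the
Type II sums of squares are computed directly by drop-term refits.
Constant factors are dropped with a warning.

## Cell-type composition scores

For each marker set, marker rows of the log-expression matrix are
standardized and the per-sample scores are the first right-singular vector
of the marker × sample matrix, scaled by `d₁/√m` (m = number of markers).
That scaling makes a set of identical standardized genes return exactly
that standardized profile, and a singleton set return the standardized gene
itself. The sign is oriented so the score correlates positively with the
set's mean standardized expression — higher score means higher marker
expression. Scores are zero-mean by construction (standardized rows are
orthogonal to the constant vector).

Association testing fits `score ~ muscle + (1 | individual)` by REML
(lme4), tests the muscle term with an F statistic on Satterthwaite
denominator degrees of freedom (lmerTest), and controls BH-FDR across the
cell-type family. Pairwise muscle contrasts are computed from the fixed
effects and their covariance, with Tukey adjustment via the studentized
range. One documented approximation: all 21 contrasts use the muscle-term
denominator df rather than per-contrast Satterthwaite df. For balanced and
near-balanced designs these agree closely (the test suite checks the
contrasts against `emmeans`); the fully per-contrast route would multiply
the per-gene cost by an order of magnitude in the genome-wide stage.
Degenerate (constant) responses return F = 0, p = 1; designs with a single
individual fall back to a fixed-effects fit with a warning; singular fits
are flagged, never dropped.

## Differential expression

Weights come from `limma::voom` with a muscle-indicator fixed-effects
design — the standard two-stage practice of estimating the mean–variance
trend under the fixed-effects design and then using the weights in the
richer model. Each gene is then fit with the weighted mixed model above;
BH-FDR is applied across genes.

The cell-type-driver filter computes, for every significant gene and every
cell type, the Pearson correlation between the gene's expression and the
cell-type score across samples, applies BH over the whole
(gene × cell type) grid, and flags genes with r > 0.5 and q < 0.05 for at
least one cell type. The correlation is signed, following the definition of
the filter: a gene tracking the *depletion* of a cell type is not flagged.
The per-pair DEG percentage matrix uses the within-gene Tukey-adjusted
contrast p-values, then BH per muscle pair across genes; this two-step
choice (rather than a single family over all genes × pairs) is a
configurable decision.

Transcript-level testing reuses the identical machinery on transcript rows
restricted to genes in the filtered gene set; transcripts of flagged genes
inherit the cell-type label.

## Consensus co-expression network

**Correlation.** Biweight midcorrelation: observations are weighted by
`(1 − u²)²` with `u = (x − med)/(9·mad)` and zero weight beyond 9 MADs.
Columns with zero MAD fall back to Pearson normalization for their pairs
(recorded in an attribute); constant columns get zero correlation.

**Adjacency and TOM.** Signed-hybrid adjacency `a = cor^β` for positive
correlations, zero otherwise (β = 8 default). Topological overlap
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
connectivity sums excluding the diagonal; the result is symmetric in
[0, 1] with unit diagonal, and is checked against a brute-force oracle in
the tests.

**Per-individual networks and consensus.** Each individual's network uses
only that individual's ≤7 samples; correlations on so few observations are
noisy by design, and the consensus is what stabilizes them. Calibration
multiplies each TOM by `reference/own`, where `own` is its 0.95 quantile of
off-diagonal entries and `reference` is the *median* of those quantiles
across individuals; the consensus entry is the elementwise 0.40 quantile of
the calibrated TOMs. The median reference makes the calibration exactly
undo a rescaling of any single input whose quantile does not cross the
median — the natural robustness property of quantile-matching calibration —
while keeping identical inputs a fixed point. (No symmetric reference rule
can satisfy both properties for arbitrary rescalings; the median is the
robust compromise and is configurable.)

**Tree cut.** Average-linkage clustering of `1 − TOM`, cut by the package's
dynamic-hybrid-style criterion. A branch is accepted as a module when:

1. it has at least `min_module_size` leaves;
2. its *core scatter* — the mean of its lowest ~√size internal merge
   heights, normalized to the [5th percentile, cut height] range — is below
   `0.64 + 0.065·deepSplit`;
3. its *local gap* — the height jump from its top merge to where it joins
   the rest of the tree — exceeds `(1 − maxCoreScatter)·0.28`; in
   featureless noise trees merge heights form a continuum and every local
   gap is tiny, which is what rejects noise;
4. its top merge is not itself a gap-sized outlier over the branch interior
   (that pattern means two distinct modules joined just below the cut, and
   triggers a split instead).

Rejected branches are split and their children assessed recursively, which
also trims chained stragglers off real modules. Genes in no accepted branch
get the reserved `"unassigned"` label (the conventional grey module). The
thresholds were calibrated once on the two regimes the criteria must
separate — pure-noise dendrograms (local gaps ≤ 0.003 normalized) and
planted correlation blocks (gaps ≥ 0.15) — and are fixed.

**Eigengenes, merging, hubs.** Module eigengenes use the same scaled-PC1
summary as the cell-type scores, across all samples. Modules are merged
when their eigengene dissimilarity `1 − cor` falls below 0.2 (average
linkage, recomputed and iterated until stable); anticorrelated modules
never merge. Intramodular connectivity is the within-module adjacency sum;
hubs are the top 10% per module — no published threshold exists, so the
fraction is a documented, configurable default.

**Enrichment factor and sweep.** Gene pairs (restricted to genes that are
both assigned and pathway-annotated; unannotated genes are excluded, a
logged and configurable choice) are classified into: same module and same
pathway (n₁), same module only (n₂), same pathway only (n₃), neither (n₄);
EF = (n₁·n₄)/(n₂·n₃), with n₂·n₃ = 0 reported as an infinite-EF flag. The
parameter sweep runs the full consensus pipeline on the grid of powers
(6–22), minimum module sizes (15/20/30), deep splits (0/2/4) and merge cut
heights (0.1–0.3), scores each *merged consensus* assignment (the sweep is
scored after merging, on the consensus network — one of two defensible
conventions, kept configurable), and returns the EF argmax with ties broken
toward the smaller power, then smaller minimum size, deep split and cut
height.

Module–muscle association fits the eigengenes with the atlas mixed model,
BH across modules, plus a likelihood-ratio test of the individual random
effect (`lmerTest::ranova`). Modules containing at least five markers of a
single cell type are flagged as composition-driven; top modules require the
third quartile of their member genes' DEA F values to *strictly* exceed 5.5
(and, when per-module annotation q-values are supplied, q < 0.01).

## Quantitative histology

**Myofiber filters.** Objects are excluded when boundary segmentation
certainty < 5th percentile, interior certainty > 95th percentile,
cross-sectional area outside the muscle-specific [10th, 99th] percentiles
(CSA distributions differ between muscles; all other criteria pool
muscles), or circularity below the 1st percentile. All comparisons are
strict, so values exactly at a threshold are retained and constant features
exclude nothing. The circularity rule is stated in the source protocol as
excluding objects *above* the 1st percentile, which would discard 99% of
fibers; the package implements the evident intent (exclude below) and
offers `strict_to_text = TRUE` for the literal reading. Per sample, the
section with the most retained fibers is kept (ties by section identifier)
and samples need at least 100 fibers.

**Fiber typing.** Per sample and channel, MFIs are divided by the
root-mean-square (scaling without centering — removing slide-to-slide
staining intensity exactly, which the tests verify as label invariance
under per-sample rescaling) and natural-log transformed. Mean-shift runs in
the pooled 3-D log space with bandwidth h = 0.02 *as a fraction of the
per-channel data range* — i.e. on min-max-scaled coordinates, matching the
range-scaling convention of the reference mean-shift implementation; on raw
log units a 0.02 ball is far below any plausible MFI spread. The kernel is
Gaussian (truncated at 3h), seeded from grid bins of size h, with modes
merged within h/2 and points assigned to the nearest surviving mode; a flat
kernel is available but fragments clusters at desk-scale object counts
(thousands rather than the ~10⁶ of a full imaging study). Clusters holding
less than 1% of all fibers are discarded; per-sample proportions are
reported over the surviving clusters with the sample's total fiber count as
denominator, so proportions plus the discarded mass sum to one.

**Capillaries and foci.** An object is a capillary iff CD31⁺ and ENG⁺,
3 µm² < area < 51 µm², circularity > 0.5 (all strict); density is
capillaries per µm² tissue, and the CD31⁺ area fraction is also reported. A
speckle is an RNA focus iff area < 3.5 µm² and circularity > 0.98; with a
negative control, foci must additionally exceed the intensity threshold at
which approximately all control foci are negative (the control maximum by
default; a configurable percentile). Both scorers are exact deterministic
functions of the table and are tested against row-by-row oracles.

## The synthetic-data generator

The generator emulates the atlas's generative structure so that each stage
faces data with the statistical features its model assumes:

* counts are negative-binomial with
  `mean = library × softmax(baseline + muscle + individual + batch + DE +
  module factor + log(celltype mixture))`;
* cell-type fractions are Dirichlet with group-specific concentrations
  (total concentration 100, giving realistic ~2–3% fraction SDs); the
  default prior gives endothelial cells ~1.5× higher expected fraction in
  G2/G3 and distinguishes G3 through its non-muscle cell types, the
  structure that makes the seven muscles cluster into the three groups;
* marker genes carry an 8-fold signature in exactly one cell type;
* planted modules share a sample-level latent factor, normalized to unit
  variance so the `cor` parameter is the realized within-block correlation;
  group-shifted factors make some modules muscle-related;
* default scale is 2,000 genes × 20 individuals × 7 muscles with 12 of 140
  individual-muscle cells dropped at random (as in a 128-sample atlas),
  library sizes 8–12 million, NB dispersion 0.1, individual effect SD 0.4 >
  muscle effect SD 0.1 (individuals dominate muscles, as observed in real
  atlases); batches are balanced over individuals and muscles
  (Latin-square style) with zero effect by default, feeding only the
  variance-decomposition stage.

What the generator does **not** emulate: gene-length effects and GC bias,
isoform structure, count outliers/swaps, spatially correlated histology
artifacts, or marker sets that overlap between cell types. Passing tests
therefore demonstrate correctness of the procedures under the assumed
generative structure, not robustness to every artifact of real data.

Myofiber objects are drawn from three log-normal MFI clusters
(fast/slow/2X-like centers, log-SD 0.05, per-sample per-channel scale
log-SD 0.2) with mixture weights 0.45/0.35/0.20 and 5% contamination
(extreme size, low boundary certainty — removed almost entirely by the
percentile filters). Vessel and foci tables plant exact rule-satisfying
object counts so scoring can be compared to construction.

## Problem sizes and runtimes

The test suite exercises the full default design (2,000 genes,
20 individuals, 5 planted modules) for module recovery; DE calibration uses
1,000 genes under a global null plus 1,000 genes with 50 planted two-fold
effects; cell-type calibration uses 100+ null replicates; the parameter
sweep runs a reduced 3 × 2 × 2 grid on an 800-gene, 12-individual design;
fiber typing uses ~3,600 fibers over 12 samples. These sizes were chosen as
the smallest at which the relevant asymptotics (consensus stabilization,
FDR calibration, density-mode recovery) are clearly expressed.

## Known limitations

* The tree-cut criteria are a self-contained variant of the dynamic-hybrid
  family, calibrated for TOM dissimilarities; other dissimilarity scales
  may need different deep-split presets.
* Pairwise-contrast df share the muscle-term denominator df (see above).
* The consensus calibration reference (median of quantiles) is exactly
  scale-invariant only for non-pivotal rescalings; full quantile
  normalization across networks is not implemented.
* Mean-shift at h = 0.02 assumes the between-cluster separation dominates
  the per-channel range; data containing a single diffuse population will
  fragment unless the bandwidth is raised (see the single-cluster test,
  which uses h = 0.3).
* Functional enrichment of modules is consumed as optional per-module
  q-values, never computed: annotation retrieval is out of scope.
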