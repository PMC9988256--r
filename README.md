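# myoatlas

Analysis toolkit for multi-muscle bulk RNA-seq atlases of human skeletal
muscle, with matched quantitative histology. It implements, as a tested and
reusable pipeline, the computational procedures needed to ask how much of
the expression difference between anatomically distinct muscles is
intrinsic to the muscle and how much reflects cell-type composition:

- **Cell-type composition scores from marker genes.** The expression of the
  genes marking each muscle-resident cell type (fast/slow myofibers,
  endothelial cells, pericytes, immune cells, FAPs) is summarized by the
  first principal component of the standardized marker-by-sample matrix;
  the per-sample PC1 score acts as a relative-abundance proxy and is
  compared between muscles with the linear mixed model
  *score ~ muscle + (1 | individual)* (Satterthwaite F test, BH-FDR across
  cell types, Tukey-adjusted pairwise muscle contrasts).
- **Precision-weighted per-gene mixed-model differential expression.**
  Counts are filtered (≥10 reads in ≥16 samples), TMM-normalized, and
  transformed to log2-CPM with voom precision weights from the
  mean–variance trend; each gene is fit with the same mixed model, with
  weights. Significant genes whose expression correlates with a cell-type
  score (Pearson r > 0.5, FDR < 0.05 over the gene-by-cell-type grid) are
  flagged as *cell-type driven*; the rest form the muscle-intrinsic set.
- **Per-individual consensus co-expression network.** For each individual,
  a signed-hybrid weighted network (biweight midcorrelation raised to power
  β = 8) is converted to a topological overlap matrix (TOM); the TOMs are
  calibrated by 0.95-quantile matching and combined by the elementwise
  40th percentile. Modules come from a dynamic-hybrid-style cut of the
  average-linkage tree of 1 − TOM (min module size 20, deep split 0),
  merged at eigengene dissimilarity 0.2. Network parameters can be chosen
  by a full sweep scored with a pathway-knowledge **enrichment factor**
  EF = (n₁·n₄)/(n₂·n₃), where gene pairs are classified by shared module
  and shared pathway membership. Module eigengenes are tested for muscle
  association with the same mixed model; hub genes are the top 10% by
  intramodular connectivity.
- **Quantitative histology.** Per-object tables from segmented
  immunofluorescence images are scored with the study's rules: myofiber
  percentile filters (boundary/interior segmentation certainty, per-muscle
  cross-sectional area, circularity), per-sample RMS scaling of the three
  myosin-heavy-chain channel intensities, natural-log transform, and
  mean-shift clustering (bandwidth 0.02) with a 1% minimum cluster rule;
  capillaries are CD31⁺∩ENG⁺ objects with 3 µm² < area < 51 µm² and
  circularity > 0.5 (density per µm² tissue); RNA foci are speckles
  < 3.5 µm² with circularity > 0.98, averaged per myofiber.

Because the study design this models (20 individuals × 7 leg-muscle
biopsies: GR, STM, STD, RF, VL, VM, GL, in three latent groups) involves
controlled-access human data, the package ships a seeded synthetic-data
generator that reproduces the design's statistical structure —
negative-binomial counts with individual and muscle effects, Dirichlet
cell-type mixtures with marker signatures, planted co-expression modules
driven by sample-level latent factors, three-cluster myofiber intensity
structure, and rule-satisfying vessel/foci object tables — with full ground
truth, so every stage is testable end to end.

## Worked example

A desk-scale atlas (8 individuals, 600 genes, 3 planted modules, planted
endothelial excess in groups G2/G3):

```r
library(myoatlas)

design <- study_design(n_individuals = 8)
params <- generative_params(
  n_genes = 600, markers_per_celltype = 10,
  planted_modules = lapply(c(1.2, -1.2, 0), function(s)
    list(size = 40, cor = 0.8, group_shift = s)),
  n_de_genes = 20, de_log2fc = 1, seed = 7)
sim    <- simulate_bulk_counts(design, params)

counts <- sim$counts[, sample_qc(sim$counts)]
filt   <- filter_low_expressed(counts)
f      <- tmm_norm_factors(filt)
eigen  <- celltype_eigenvectors(cpm_log(filt, f), simulate_marker_sets(params))
celltype_association(eigen, sim$metadata)$table
#>                   cell_type      F        q
#> myofiber_fast myofiber_fast 13.379 3.17e-07
#> immune               immune  4.866 2.81e-03
#> myofiber_slow myofiber_slow  3.633 1.23e-02
#> endothelial     endothelial  3.450 1.24e-02
#> pericyte           pericyte  1.267 3.55e-01
#> fap                     fap  0.746 6.16e-01
```

The fast-myofiber and endothelial scores differ significantly between
muscles (q < 0.05) — the planted group structure — while pericytes and
FAPs, which were simulated without group differences, do not.

```r
vw   <- voom_weights(filt, f, sim$metadata$muscle)
toms <- per_individual_toms(vw$expr, sim$metadata, power = 8)
cons <- consensus_tom(toms)
mods <- merge_modules(vw$expr, cut_modules(1 - cons, network_params()), 0.2)
table(mods$assignment)
#>         M1         M2 unassigned
#>         39         39        522

module_muscle_association(mods$me, sim$metadata)$table
#>    module     F        q muscle_related
#> M1     M1  8.35 8.52e-06           TRUE
#> M2     M2 10.91 1.02e-06           TRUE
```

The two group-shifted planted modules surface as muscle-related consensus
modules (the third, group-neutral block needs the full 20-individual
consensus to separate from noise; at the default scale all five planted
modules are recovered with adjusted Rand index 1.0). The full pipeline —
simulation through histology, with a JSON manifest and per-file checksums —
runs from a single YAML-configurable call:

```r
manifest <- run_pipeline(read_pipeline_config(list(seed = 1)))
report(manifest)
```

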