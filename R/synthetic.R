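#' Study design for a multi-muscle transcriptome atlas
#'
#' Describes the sampling layout the generator emulates: 20 individuals with
#' biopsies from seven muscle sites of the leg (gracilis GR; semitendinosus
#' middle/distal STM, STD; rectus femoris RF; vastus lateralis VL and medialis
#' VM; gastrocnemius lateralis GL), which fall into three latent groups
#' (G1 = GR/STM/STD hamstring-graft muscles, G2 = quadriceps RF/VL/VM,
#' G3 = GL). A small fraction of individual-by-muscle cells is missing, as in
#' real atlases where not every biopsy yields usable RNA (128 of 140 here).
#'
#' @param n_individuals number of individuals (default 20).
#' @param muscles ordered character vector of muscle labels.
#' @param group_map named character vector mapping each muscle to a latent
#'   group label.
#' @param n_batches number of library-preparation batches.
#' @param missingness_rate fraction of individual-by-muscle cells absent
#'   (default 12/140).
#' @return object of class `study_design`.
#' @export
study_design <- function(n_individuals = 20,
                         muscles = c("GR", "STM", "STD", "RF", "VL", "VM", "GL"),
                         group_map = c(GR = "G1", STM = "G1", STD = "G1",
                                       RF = "G2", VL = "G2", VM = "G2",
                                       GL = "G3"),
                         n_batches = 4,
                         missingness_rate = 12 / 140) {
  n_individuals <- .assert_count(n_individuals, "n_individuals")
  if (anyDuplicated(muscles)) stop("duplicate muscle labels")
  if (!all(muscles %in% names(group_map)))
    stop("every muscle must map to exactly one group")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must be in [0, 1)")
  structure(list(n_individuals = n_individuals, muscles = muscles,
                 group_map = group_map[muscles], n_batches = n_batches,
                 missingness_rate = missingness_rate),
            class = "study_design")
}

#' Generative parameters for the synthetic bulk RNA-seq atlas
#'
#' Defaults are desk-scale but keep the statistical structure the downstream
#' models assume: negative-binomial counts whose log-mean combines a gene
#' baseline, per-muscle and per-individual random effects, a cell-type mixture
#' term driven by group-specific Dirichlet fractions with marker genes
#' up-weighted in exactly one cell type, sample-level latent factors planting
#' correlated co-expression blocks, and optional planted group-differential
#' genes for power assessment. All effect SDs are on the natural-log scale.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_celltypes number of cell types (default 6; named after the major
#'   muscle-resident populations).
#' @param markers_per_celltype marker genes per cell type (default 30).
#' @param celltype_fraction_prior group-by-celltype Dirichlet concentration
#'   matrix (rows G1-G3). The default gives endothelial cells ~1.5-fold
#'   higher expected fraction in G2/G3 than G1, shifts the fast/slow
#'   myofiber balance across groups, and distinguishes G3 by its non-muscle
#'   cell types (pericytes, immune, endothelial).
#' @param muscle_effect_sd SD of per-gene-by-muscle effects (default 0.1).
#' @param individual_effect_sd SD of per-gene-by-individual effects
#'   (default 0.4; larger than the muscle SD, as in real atlases where
#'   inter-individual variation dominates).
#' @param batch_effect_sd SD of per-gene-by-batch effects (default 0; the
#'   pipeline accepts batch-corrected counts, the batch column feeds only the
#'   variance decomposition).
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param library_size_range min/max sequencing depth per sample.
#' @param planted_modules list of `list(size=, cor=, group_shift=)` blocks;
#'   `cor` is the target within-block correlation, `group_shift` moves the
#'   block's latent factor mean across groups (G1/G2/G3 coded -1/0/+1).
#' @param n_de_genes number of planted group-differential genes (default 50).
#' @param de_log2fc planted log2 fold change of those genes in G2 muscles
#'   (default 0, i.e. null design unless requested).
#' @param marker_strength fold up-weighting of a marker gene's signature in
#'   its own cell type (default 8).
#' @param seed integer RNG seed.
#' @return object of class `generative_params`.
#' @export
generative_params <- function(n_genes = 2000,
                              n_celltypes = 6,
                              markers_per_celltype = 30,
                              celltype_fraction_prior = NULL,
                              muscle_effect_sd = 0.1,
                              individual_effect_sd = 0.4,
                              batch_effect_sd = 0,
                              nb_dispersion = 0.1,
                              library_size_range = c(8e6, 12e6),
                              planted_modules = NULL,
                              n_de_genes = 50,
                              de_log2fc = 0,
                              marker_strength = 8,
                              seed = 1) {
  n_genes <- .assert_count(n_genes, "n_genes")
  n_celltypes <- .assert_count(n_celltypes, "n_celltypes")
  if (is.null(celltype_fraction_prior)) {
    ct <- c("myofiber_fast", "myofiber_slow", "endothelial", "pericyte",
            "immune", "fap")[seq_len(min(n_celltypes, 6))]
    if (n_celltypes > 6) ct <- c(ct, paste0("celltype_", 7:n_celltypes))
    celltype_fraction_prior <- rbind(
      G1 = c(45, 25, 8, 6, 6, 10),
      G2 = c(33, 35, 12, 6, 6, 8),
      G3 = c(26, 30, 13, 10, 12, 9))[, seq_len(6), drop = FALSE]
    if (n_celltypes != 6) {
      base <- matrix(10, 3, n_celltypes,
                     dimnames = list(c("G1", "G2", "G3"), NULL))
      base[, seq_len(min(6, n_celltypes))] <-
        celltype_fraction_prior[, seq_len(min(6, n_celltypes))]
      celltype_fraction_prior <- base
    }
    colnames(celltype_fraction_prior) <- ct
  }
  if (any(celltype_fraction_prior <= 0)) stop("concentrations must be > 0")
  if (nb_dispersion <= 0) stop("dispersion must be > 0")
  if (is.null(planted_modules)) {
    shifts <- c(1.2, -1.2, 0, 0, 0)
    planted_modules <- lapply(seq_len(5), function(k)
      list(size = 50, cor = 0.8, group_shift = shifts[k]))
  }
  sizes <- vapply(planted_modules, `[[`, numeric(1), "size")
  n_markers <- n_celltypes * markers_per_celltype
  if (n_markers > n_genes) stop("marker sets exceed the gene pool")
  if (n_markers + sum(sizes) + n_de_genes > n_genes)
    stop("planted markers, modules and DE genes exceed n_genes")
  structure(list(n_genes = n_genes, n_celltypes = n_celltypes,
                 markers_per_celltype = markers_per_celltype,
                 celltype_fraction_prior = celltype_fraction_prior,
                 muscle_effect_sd = muscle_effect_sd,
                 individual_effect_sd = individual_effect_sd,
                 batch_effect_sd = batch_effect_sd,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 planted_modules = planted_modules,
                 n_de_genes = n_de_genes, de_log2fc = de_log2fc,
                 marker_strength = marker_strength, seed = seed),
            class = "generative_params")
}

## deterministic gene index layout: [markers | module blocks | DE genes | rest]
.gene_layout <- function(params) {
  n_markers <- params$n_celltypes * params$markers_per_celltype
  gene_ids <- sprintf("gene_%04d", seq_len(params$n_genes))
  marker_idx <- split(seq_len(n_markers),
                      rep(seq_len(params$n_celltypes),
                          each = params$markers_per_celltype))
  names(marker_idx) <- colnames(params$celltype_fraction_prior)
  offset <- n_markers
  module_idx <- list()
  for (k in seq_along(params$planted_modules)) {
    sz <- params$planted_modules[[k]]$size
    module_idx[[paste0("planted_", k)]] <- offset + seq_len(sz)
    offset <- offset + sz
  }
  de_idx <- if (params$n_de_genes > 0) offset + seq_len(params$n_de_genes)
            else integer(0)
  list(gene_ids = gene_ids, marker_idx = marker_idx,
       module_idx = module_idx, de_idx = de_idx)
}

#' Simulate bulk RNA-seq counts for a multi-muscle atlas
#'
#' Draws negative-binomial counts whose expected value is
#' `library_size * softmax(baseline + muscle + individual + batch + DE +
#' module factor + log(celltype mixture))`, with per-sample cell-type
#' fractions from a group-specific Dirichlet. Deterministic given
#' `params$seed`.
#'
#' @param design a [study_design()].
#' @param params a [generative_params()].
#' @return list with `counts` (gene x sample integer matrix), `metadata`
#'   (data.frame: sample, individual, muscle, group, batch), and `truth`
#'   (fractions, marker sets, module labels, planted DE genes, latent
#'   factors).
#' @export
simulate_bulk_counts <- function(design, params) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "generative_params"))
  set.seed(params$seed)
  lay <- .gene_layout(params)
  G <- params$n_genes

  ## sample grid with missingness
  grid <- expand.grid(individual = sprintf("ind_%02d",
                                           seq_len(design$n_individuals)),
                      muscle = design$muscles, stringsAsFactors = FALSE)
  n_drop <- round(design$missingness_rate * nrow(grid))
  if (n_drop > 0) grid <- grid[-sample(nrow(grid), n_drop), , drop = FALSE]
  ## batches balanced over individuals and muscles (Latin-square style), as
  ## in designs that distribute samples evenly across library batches
  ind_num <- as.integer(factor(grid$individual))
  mus_num <- as.integer(factor(grid$muscle, levels = design$muscles))
  md <- data.frame(sample = paste(grid$individual, grid$muscle, sep = "_"),
                   individual = grid$individual, muscle = grid$muscle,
                   group = unname(design$group_map[grid$muscle]),
                   batch = paste0("batch_", 1 + (ind_num + mus_num) %%
                                    design$n_batches),
                   stringsAsFactors = FALSE)
  S <- nrow(md)

  ## cell-type fractions per sample
  prior <- params$celltype_fraction_prior
  frac <- t(vapply(md$group, function(g) {
    x <- rgamma(ncol(prior), shape = prior[g, ])
    x / sum(x)
  }, numeric(ncol(prior))))
  dimnames(frac) <- list(md$sample, colnames(prior))

  ## effects
  baseline <- rnorm(G, log(50), 1.2)
  musc_eff <- matrix(rnorm(G * length(design$muscles),
                           sd = params$muscle_effect_sd),
                     G, dimnames = list(NULL, design$muscles))
  ind_lab <- unique(md$individual)
  ind_eff <- matrix(rnorm(G * length(ind_lab),
                          sd = params$individual_effect_sd),
                    G, dimnames = list(NULL, ind_lab))
  batch_lab <- unique(md$batch)
  batch_eff <- matrix(rnorm(G * length(batch_lab),
                            sd = params$batch_effect_sd),
                      G, dimnames = list(NULL, batch_lab))

  ## planted DE: additive shift in G2 muscles
  de_shift <- numeric(G)
  de_shift[lay$de_idx] <- log(2) * params$de_log2fc
  de_term <- outer(de_shift, as.numeric(md$group == "G2"))

  ## planted module latent factors (per sample), additive on log-mean
  group_code <- c(G1 = -1, G2 = 0, G3 = 1)[md$group]
  sigma0 <- sqrt(log1p(params$nb_dispersion))
  mod_term <- matrix(0, G, S)
  factors <- matrix(0, length(params$planted_modules), S,
                    dimnames = list(names(lay$module_idx), md$sample))
  for (k in seq_along(params$planted_modules)) {
    pm <- params$planted_modules[[k]]
    z <- pm$group_shift * group_code + rnorm(S)
    z <- z / sd(z)  # unit variance so the target correlation is met
    loading <- sqrt(pm$cor / (1 - pm$cor)) * sigma0
    mod_term[lay$module_idx[[k]], ] <-
      matrix(rep(loading * z, each = pm$size), ncol = S)
    factors[k, ] <- z
  }

  ## cell-type mixture term: markers carry an elevated signature in one type
  mix <- matrix(1, G, S)
  for (c in seq_along(lay$marker_idx)) {
    mix[lay$marker_idx[[c]], ] <-
      matrix(rep(1 + (params$marker_strength - 1) * frac[, c],
                 each = length(lay$marker_idx[[c]])), ncol = S)
  }

  log_mu <- baseline + musc_eff[, md$muscle] + ind_eff[, md$individual] +
    batch_eff[, md$batch] + de_term + mod_term + log(mix)
  lib <- runif(S, params$library_size_range[1], params$library_size_range[2])
  p <- exp(sweep(log_mu, 2, apply(log_mu, 2, function(x) {
    m <- max(x); m + log(sum(exp(x - m)))
  })))
  mu <- sweep(p, 2, lib, `*`)
  counts <- matrix(rnbinom(G * S, mu = mu, size = 1 / params$nb_dispersion),
                   G, S, dimnames = list(lay$gene_ids, md$sample))

  module_labels <- setNames(rep("none", G), lay$gene_ids)
  for (k in seq_along(lay$module_idx))
    module_labels[lay$module_idx[[k]]] <- names(lay$module_idx)[k]

  truth <- list(
    fractions = frac,
    marker_sets = lapply(lay$marker_idx, function(i) lay$gene_ids[i]),
    module_labels = module_labels,
    module_factors = factors,
    de_genes = lay$gene_ids[lay$de_idx],
    de_log2fc = params$de_log2fc,
    individual_effects = ind_eff,
    muscle_effects = musc_eff)
  list(counts = counts, metadata = md, truth = truth)
}

#' Marker gene sets matching the generator's planted layout
#'
#' Deterministic: uses the same gene index layout as [simulate_bulk_counts()],
#' so membership agrees with the truth record of any simulation run with the
#' same parameters. Sets are disjoint from each other and from planted module
#' blocks.
#'
#' @param params a [generative_params()].
#' @return named list of gene identifier vectors, one per cell type.
#' @export
simulate_marker_sets <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  lay <- .gene_layout(params)
  lapply(lay$marker_idx, function(i) lay$gene_ids[i])
}

#' Simulate a segmented myofiber object table
#'
#' Emulates per-object measurements from immunofluorescence myofiber typing:
#' three myosin-heavy-chain channel mean intensities (MFI) drawn log-normally
#' around cluster centers with a per-sample, per-channel multiplicative scale
#' (slide-to-slide staining intensity), cross-sectional area, circularity and
#' segmentation-certainty scores. A configurable fraction of contamination
#' objects mimics segmentation artifacts (extreme size, low boundary
#' certainty).
#'
#' @param n_samples number of samples.
#' @param n_fibers_per_sample fibers per sample.
#' @param cluster_centers matrix (clusters x 3 channels) of raw MFI centers.
#' @param cluster_weights mixture weights over clusters.
#' @param noise_sd log-scale SD of MFI around its center (default 0.05).
#' @param contamination_rate fraction of artifact objects (default 0.05).
#' @param sections_per_sample sections per sample (fibers split 60/40/... ).
#' @param muscles muscle labels cycled over samples (drives per-muscle CSA
#'   filtering downstream).
#' @param sample_scale_sd log-scale SD of the per-sample per-channel intensity
#'   scale (default 0.2).
#' @param seed RNG seed.
#' @return list with `objects` (data.frame) and `truth` (per-object true
#'   cluster label, 0 for contamination).
#' @export
simulate_myofiber_objects <- function(n_samples = 20,
                                      n_fibers_per_sample = 300,
                                      cluster_centers = rbind(
                                        c(12000, 1500, 1200),
                                        c(1800, 11000, 2000),
                                        c(1500, 2500, 10000)),
                                      cluster_weights = c(0.45, 0.35, 0.20),
                                      noise_sd = 0.05,
                                      contamination_rate = 0.05,
                                      sections_per_sample = 1,
                                      muscles = c("GR", "STM", "STD", "RF",
                                                  "VL", "VM", "GL"),
                                      sample_scale_sd = 0.2,
                                      seed = 1) {
  cluster_centers <- as.matrix(cluster_centers)
  if (nrow(cluster_centers) < 1) stop("at least one cluster center required")
  if (contamination_rate < 0 || contamination_rate > 1)
    stop("contamination_rate must be in [0,1]")
  set.seed(seed)
  K <- nrow(cluster_centers)
  cluster_weights <- rep_len(cluster_weights, K)
  cluster_weights <- cluster_weights / sum(cluster_weights)
  chans <- c("mfi_myhc1", "mfi_myhc2a", "mfi_myhc2x")

  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    n <- n_fibers_per_sample
    n_cont <- rbinom(1, n, contamination_rate)
    n_real <- n - n_cont
    lab <- sample.int(K, n_real, replace = TRUE, prob = cluster_weights)
    scale_c <- exp(rnorm(3, sd = sample_scale_sd))
    mfi <- cluster_centers[lab, , drop = FALSE] *
      matrix(rep(scale_c, each = n_real), ncol = 3) *
      exp(matrix(rnorm(n_real * 3, sd = noise_sd), ncol = 3))
    real <- data.frame(
      area_um2 = rlnorm(n_real, log(3000), 0.35),
      circularity = rbeta(n_real, 12, 3),
      boundary_certainty = rbeta(n_real, 10, 2),
      interior_certainty = rbeta(n_real, 2, 10))
    real[chans] <- mfi
    real$true_cluster <- lab
    if (n_cont > 0) {
      cont <- data.frame(
        area_um2 = rlnorm(n_cont, log(3000), 0.35) *
          sample(c(0.02, 20), n_cont, replace = TRUE),
        circularity = rbeta(n_cont, 2, 8),
        boundary_certainty = rbeta(n_cont, 1, 20),
        interior_certainty = rbeta(n_cont, 10, 2))
      cont[chans] <- matrix(rlnorm(n_cont * 3, log(800), 0.5), ncol = 3)
      cont$true_cluster <- 0L
      real <- rbind(real, cont)
    }
    n_tot <- nrow(real)
    sec_w <- rev(seq_len(sections_per_sample))
    sec <- rep(paste0("sec_", seq_len(sections_per_sample)),
               length.out = sections_per_sample)[
                 sample.int(sections_per_sample, n_tot, replace = TRUE,
                            prob = sec_w / sum(sec_w))]
    real$section_id <- sec
    real$sample_id <- sprintf("hsamp_%02d", s)
    real$muscle <- muscles[1 + (s - 1) %% length(muscles)]
    out[[s]] <- real
  }
  objects <- do.call(rbind, out)
  objects$object_id <- sprintf("obj_%06d", seq_len(nrow(objects)))
  truth <- objects$true_cluster
  objects$true_cluster <- NULL
  cols <- c("object_id", "sample_id", "section_id", "muscle", "area_um2",
            "circularity", chans, "boundary_certainty", "interior_certainty")
  list(objects = objects[, cols], truth = truth)
}

#' Simulate a segmented vessel object table for capillary scoring
#'
#' Plants a known number of objects satisfying all three capillary rules
#' (CD31+ and ENG+, area strictly between 3 and 51 um^2, circularity > 0.5);
#' the remaining objects each violate at least one rule.
#'
#' @param n_sections number of sections (one sample per section).
#' @param objects_per_section objects per section.
#' @param tissue_area_um2 tissue area per section.
#' @param capillary_fraction fraction of rule-satisfying objects.
#' @param seed RNG seed.
#' @return list with `objects` (data.frame incl. cd31_pos/eng_pos flags),
#'   `truth` (logical planted-capillary flag) and `tissue_area_um2`.
#' @export
simulate_vessel_objects <- function(n_sections = 5, objects_per_section = 200,
                                    tissue_area_um2 = 1e6,
                                    capillary_fraction = 0.25, seed = 1) {
  if (tissue_area_um2 <= 0) stop("tissue area must be positive")
  set.seed(seed)
  out <- vector("list", n_sections)
  for (s in seq_len(n_sections)) {
    n <- objects_per_section
    n_cap <- round(capillary_fraction * n)
    cap <- data.frame(area_um2 = runif(n_cap, 5, 45),
                      circularity = runif(n_cap, 0.55, 0.95),
                      cd31_pos = rep(TRUE, n_cap),
                      eng_pos = rep(TRUE, n_cap),
                      planted = rep(TRUE, n_cap))
    n_other <- n - n_cap
    viol <- sample.int(4, n_other, replace = TRUE)
    oth <- data.frame(area_um2 = runif(n_other, 5, 45),
                      circularity = runif(n_other, 0.55, 0.95),
                      cd31_pos = rep(TRUE, n_other),
                      eng_pos = rep(TRUE, n_other),
                      planted = rep(FALSE, n_other))
    oth$area_um2[viol == 1] <- runif(sum(viol == 1), 0.2, 2.9)
    oth$area_um2[viol == 2] <- runif(sum(viol == 2), 52, 200)
    oth$circularity[viol == 3] <- runif(sum(viol == 3), 0.05, 0.45)
    flagless <- viol == 4
    oth$cd31_pos[flagless] <- sample(c(TRUE, FALSE), sum(flagless),
                                     replace = TRUE)
    oth$eng_pos[flagless] <- !oth$cd31_pos[flagless]
    df <- rbind(cap, oth)
    df$sample_id <- sprintf("vsamp_%02d", s)
    df$section_id <- sprintf("vsec_%02d", s)
    out[[s]] <- df
  }
  objects <- do.call(rbind, out)
  objects$object_id <- sprintf("ves_%06d", seq_len(nrow(objects)))
  truth <- objects$planted
  objects$planted <- NULL
  cols <- c("object_id", "sample_id", "section_id", "area_um2",
            "circularity", "cd31_pos", "eng_pos")
  list(objects = objects[, cols], truth = truth,
       tissue_area_um2 = setNames(rep(tissue_area_um2, n_sections),
                                  sprintf("vsec_%02d", seq_len(n_sections))))
}

#' Simulate an RNA-foci object table
#'
#' True foci have area < 3.5 um^2 and circularity > 0.98 (with high probe
#' intensity); false positives violate at least one geometric rule and carry
#' low intensity, as in a negative-control experiment.
#'
#' @param n_fibers number of segmented myofibers (must be > 0).
#' @param foci_per_fiber_mean Poisson mean of true foci per fiber.
#' @param false_positive_rate expected false positives per true focus.
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return list with `objects`, `truth` (logical true-focus flag) and
#'   `n_fibers`.
#' @export
simulate_foci_objects <- function(n_fibers = 100, foci_per_fiber_mean = 2,
                                  false_positive_rate = 0,
                                  sample_id = "fsamp_01", seed = 1) {
  if (n_fibers <= 0) stop("n_fibers must be positive")
  set.seed(seed)
  k <- rpois(n_fibers, foci_per_fiber_mean)
  n_true <- sum(k)
  true <- data.frame(fiber_id = rep(seq_len(n_fibers), k),
                     area_um2 = runif(n_true, 0.2, 3.2),
                     circularity = runif(n_true, 0.982, 0.999),
                     intensity = rlnorm(n_true, log(100), 0.3),
                     is_true = TRUE)
  n_fp <- rpois(1, n_true * false_positive_rate)
  if (n_fp > 0) {
    big <- runif(n_fp) < 0.5
    fp <- data.frame(fiber_id = sample.int(n_fibers, n_fp, replace = TRUE),
                     area_um2 = ifelse(big, runif(n_fp, 3.6, 8),
                                       runif(n_fp, 0.2, 3.2)),
                     circularity = ifelse(big, runif(n_fp, 0.982, 0.999),
                                          runif(n_fp, 0.90, 0.979)),
                     intensity = rlnorm(n_fp, log(20), 0.3),
                     is_true = FALSE)
    true <- rbind(true, fp)
  }
  objects <- true
  objects$sample_id <- sample_id
  objects$object_id <- sprintf("foc_%06d",
                               seq_len(max(1, nrow(objects)))[seq_len(nrow(objects))])
  truth <- objects$is_true
  objects$is_true <- NULL
  cols <- c("object_id", "sample_id", "fiber_id", "area_um2", "circularity",
            "intensity")
  list(objects = objects[, cols], truth = truth,
       n_fibers = setNames(n_fibers, sample_id))
}

#' Derive a pathway-knowledge network from planted modules
#'
#' Builds one pathway per planted co-expression block and reassigns a
#' configurable fraction of genes to random pathways, emulating a noisy
#' curated database. With `pathway_noise = 0` pathways equal the planted
#' modules; with `pathway_noise = 1` membership is random and the enrichment
#' factor of the true modules is ~1 in expectation.
#'
#' @param truth truth record from [simulate_bulk_counts()].
#' @param pathway_noise fraction of genes reassigned at random.
#' @param seed RNG seed.
#' @return named list of gene sets (GMT-like structure).
#' @export
simulate_knowledge_network <- function(truth, pathway_noise = 0, seed = 1) {
  stopifnot(pathway_noise >= 0, pathway_noise <= 1)
  set.seed(seed)
  labels <- truth$module_labels[truth$module_labels != "none"]
  genes <- names(labels)
  path <- labels
  reassign <- runif(length(path)) < pathway_noise
  path[reassign] <- sample(unique(labels), sum(reassign), replace = TRUE)
  sets <- split(genes, path)
  names(sets) <- sub("^planted_", "pathway_", names(sets))
  sets
}
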