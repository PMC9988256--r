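## shared fixtures, built once per test run and memoized

.fx <- new.env(parent = emptyenv())

## desk-scale atlas: 8 individuals, 600 genes, 3 planted modules,
## 20 planted DE genes (log2FC 1 in G2)
fx_small <- function() {
  if (is.null(.fx$small)) {
    design <- study_design(n_individuals = 8)
    params <- generative_params(
      n_genes = 600, markers_per_celltype = 10,
      planted_modules = lapply(c(1.2, -1.2, 0), function(s)
        list(size = 40, cor = 0.8, group_shift = s)),
      n_de_genes = 20, de_log2fc = 1, seed = 7)
    sim <- simulate_bulk_counts(design, params)
    filt <- filter_low_expressed(sim$counts)
    factors <- tmm_norm_factors(filt)
    .fx$small <- list(design = design, params = params, sim = sim,
                      filt = filt, factors = factors,
                      logcpm = cpm_log(filt, factors),
                      markers = simulate_marker_sets(params))
  }
  .fx$small
}

## voom + per-gene mixed DE (with contrasts) + cell-type flags on fx_small
fx_small_de <- function() {
  if (is.null(.fx$small_de)) {
    fx <- fx_small()
    vw <- voom_weights(fx$filt, fx$factors, fx$sim$metadata$muscle)
    eig <- celltype_eigenvectors(fx$logcpm, fx$markers)
    deg <- per_gene_mixed_de(vw$expr, vw$weights, fx$sim$metadata)
    deg <- flag_celltype_driven(deg, vw$expr, eig)
    .fx$small_de <- list(voom = vw, eigen = eig, deg = deg)
  }
  .fx$small_de
}

## full default study scale: 20 individuals x 7 muscles, 2000 genes,
## 5 planted modules
fx_default <- function() {
  if (is.null(.fx$default)) {
    design <- study_design()
    params <- generative_params(seed = 11)
    sim <- simulate_bulk_counts(design, params)
    filt <- filter_low_expressed(sim$counts)
    factors <- tmm_norm_factors(filt)
    vw <- voom_weights(filt, factors, sim$metadata$muscle)
    .fx$default <- list(design = design, params = params, sim = sim,
                        filt = filt, factors = factors, voom = vw,
                        markers = simulate_marker_sets(params))
  }
  .fx$default
}

## consensus modules on fx_default (atlas parameters)
fx_default_modules <- function() {
  if (is.null(.fx$default_modules)) {
    fx <- fx_default()
    toms <- suppressMessages(
      per_individual_toms(fx$voom$expr, fx$sim$metadata, power = 8))
    cons <- consensus_tom(toms)
    assign0 <- cut_modules(1 - cons, network_params())
    merged <- merge_modules(fx$voom$expr, assign0, 0.2)
    .fx$default_modules <- list(consensus = cons,
                                assignment = merged$assignment,
                                me = merged$me)
  }
  .fx$default_modules
}

## independent brute-force TOM oracle (double loop over the formula)
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    out[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

## independent pair-enumeration oracle for the enrichment factor
oracle_ef <- function(assignment, pathways) {
  annotated <- unique(unlist(pathways))
  genes <- intersect(names(assignment)[assignment != "unassigned"],
                     annotated)
  n <- c(n1 = 0, n2 = 0, n3 = 0, n4 = 0)
  for (i in seq_along(genes)) for (j in seq_len(i - 1)) {
    g1 <- genes[i]; g2 <- genes[j]
    sm <- assignment[g1] == assignment[g2]
    sp <- any(vapply(pathways, function(p) g1 %in% p && g2 %in% p,
                     logical(1)))
    cls <- if (sm && sp) 1 else if (sm) 2 else if (sp) 3 else 4
    n[cls] <- n[cls] + 1
  }
  n
}

## symmetric random adjacency with zero-one range
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

## uniform myofiber object table for filter/section tests
make_objects <- function(n, muscle = "GR", sample_id = "s1",
                         section_id = "sec_1") {
  data.frame(object_id = sprintf("o%04d", seq_len(n)),
             sample_id = sample_id, section_id = section_id,
             muscle = muscle,
             area_um2 = seq(100, 5000, length.out = n),
             circularity = seq(0.5, 0.99, length.out = n),
             mfi_myhc1 = 1000, mfi_myhc2a = 1000, mfi_myhc2x = 1000,
             boundary_certainty = seq(0.01, 0.99, length.out = n),
             interior_certainty = seq(0.01, 0.99, length.out = n),
             stringsAsFactors = FALSE)
}

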