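.default_config <- function() {
  list(
    seed = 1,
    output_dir = "myoatlas_out",
    pathway_noise = 0,
    stages = list(simulate = TRUE, preprocess = TRUE, celltype = TRUE,
                  de = TRUE, network = TRUE, histology = TRUE),
    inputs = list(counts = NULL, metadata = NULL, markers = NULL,
                  pathways = NULL),
    design = list(n_individuals = 20,
                  muscles = c("GR", "STM", "STD", "RF", "VL", "VM", "GL"),
                  n_batches = 4, missingness_rate = 12 / 140),
    generative = list(n_genes = 2000, n_celltypes = 6,
                      markers_per_celltype = 30, muscle_effect_sd = 0.1,
                      individual_effect_sd = 0.4, batch_effect_sd = 0,
                      nb_dispersion = 0.1, n_de_genes = 50, de_log2fc = 1,
                      marker_strength = 8, n_modules = 5,
                      module_size = 50, module_cor = 0.8),
    preprocess = list(min_assigned_reads = 5e6, min_count = 10,
                      min_samples = 16, prior_count = 0.5),
    network = list(power = 8, min_module_size = 20, deep_split = 0,
                   merge_cut_height = 0.2, calibration_quantile = 0.95,
                   consensus_quantile = 0.40, min_samples = 4,
                   hub_fraction = 0.10),
    histology = list(bandwidth = 0.02, min_cluster_fraction = 0.01,
                     min_fibers_per_sample = 100, n_samples = 20,
                     n_fibers_per_sample = 300, contamination_rate = 0.05,
                     vessel_sections = 5, vessel_objects = 200,
                     tissue_area_um2 = 1e6, capillary_fraction = 0.25,
                     foci_fibers = 100, foci_per_fiber_mean = 2,
                     foci_false_positive_rate = 0.1))
}

.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file (or takes a list), checks it against the known schema
#' (unknown keys are rejected), and fills unset values with the atlas
#' defaults.
#'
#' @param config path to a YAML file, a list, or NULL for pure defaults.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), config)
  structure(cfg, class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the atlas pipeline end to end
#'
#' Executes the enabled stages in order: synthetic-data generation (or
#' ingestion of user tables), preprocessing (sample QC, expression filter,
#' TMM, log-CPM, variance decomposition), cell-type composition, weighted
#' mixed-model differential expression with cell-type-driver exclusion,
#' consensus co-expression network with module-muscle association, and
#' quantitative histology. Writes TSV outputs, a run log and a JSON manifest
#' (config, seed, per-file MD5 checksums); a rerun with the same config and
#' seed is bit-identical.
#'
#' @param config a [read_pipeline_config()] result, a YAML path, or NULL.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  unlink(log_path)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  stage <- function(name, enabled, fun) {
    if (!enabled) { logf("stage ", name, ": skipped"); return(NULL) }
    logf("stage ", name, ": start")
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("stage ", name, ": done")
    res
  }

  env <- new.env()

  stage("simulate", cfg$stages$simulate, function() {
    if (!is.null(cfg$inputs$counts)) {
      env$counts <- round(read_matrix_tsv(cfg$inputs$counts))
      env$metadata <- read.delim(cfg$inputs$metadata,
                                 stringsAsFactors = FALSE)
      env$markers <- read_gmt(cfg$inputs$markers)
      env$pathways <- if (!is.null(cfg$inputs$pathways))
        read_gmt(cfg$inputs$pathways) else NULL
      env$truth <- NULL
    } else {
      design <- do.call(study_design, cfg$design)
      gen <- cfg$generative
      shifts <- rep(c(1.2, -1.2, 0), length.out = max(1, gen$n_modules))
      modules <- if (gen$n_modules > 0)
        lapply(seq_len(gen$n_modules), function(k)
          list(size = gen$module_size, cor = gen$module_cor,
               group_shift = shifts[k])) else list()
      gen <- gen[setdiff(names(gen),
                         c("n_modules", "module_size", "module_cor"))]
      params <- do.call(generative_params,
                        c(gen, list(planted_modules = modules,
                                    seed = stage_seed(cfg$seed, 1))))
      sim <- simulate_bulk_counts(design, params)
      env$counts <- sim$counts
      env$metadata <- sim$metadata
      env$truth <- sim$truth
      env$markers <- simulate_marker_sets(params)
      env$pathways <- simulate_knowledge_network(
        sim$truth, pathway_noise = cfg$pathway_noise,
        seed = stage_seed(cfg$seed, 2))
      emit(write_matrix_tsv(env$counts,
                            file.path(cfg$output_dir, "counts.tsv"),
                            id_col = "gene"))
      emit(.write_tsv(env$metadata,
                      file.path(cfg$output_dir, "metadata.tsv")))
      write_gmt(env$markers,
                emit(file.path(cfg$output_dir, "markers.gmt")))
      write_gmt(env$pathways,
                emit(file.path(cfg$output_dir, "pathways.gmt")))
      jsonlite::write_json(
        list(module_labels = as.list(sim$truth$module_labels),
             de_genes = sim$truth$de_genes),
        emit(file.path(cfg$output_dir, "truth.json")), auto_unbox = TRUE)
    }
  })

  stage("preprocess", cfg$stages$preprocess, function() {
    pp <- cfg$preprocess
    keep <- sample_qc(env$counts, pp$min_assigned_reads)
    env$counts <- env$counts[, keep, drop = FALSE]
    env$metadata <- env$metadata[env$metadata$sample %in% keep, ,
                                 drop = FALSE]
    env$filtered <- filter_low_expressed(env$counts, pp$min_count,
                                         pp$min_samples)
    env$factors <- tmm_norm_factors(env$filtered)
    env$logcpm <- cpm_log(env$filtered, env$factors, pp$prior_count)
    vd_factors <- intersect(c("muscle", "individual", "batch"),
                            colnames(env$metadata))
    env$vd <- variance_decomposition(env$logcpm, env$metadata, vd_factors)
    emit(.write_tsv(cbind(gene = rownames(env$vd), env$vd),
                    file.path(cfg$output_dir, "variance_decomposition.tsv")))
    emit(write_matrix_tsv(env$logcpm$values,
                          file.path(cfg$output_dir, "logcpm.tsv"),
                          id_col = "gene"))
  })

  stage("celltype", cfg$stages$celltype, function() {
    env$eigen <- celltype_eigenvectors(env$logcpm, env$markers)
    env$ct_assoc <- celltype_association(env$eigen, env$metadata)
    cl <- cluster_muscles(env$eigen, env$metadata)
    emit(write_matrix_tsv(env$eigen$scores,
                          file.path(cfg$output_dir, "celltype_scores.tsv"),
                          id_col = "sample"))
    emit(.write_tsv(env$ct_assoc$table,
                    file.path(cfg$output_dir, "celltype_association.tsv")))
    emit(write_matrix_tsv(cl$means,
                          file.path(cfg$output_dir, "celltype_muscle_means.tsv"),
                          id_col = "muscle"))
  })

  stage("de", cfg$stages$de, function() {
    vw <- voom_weights(env$filtered, env$factors, env$metadata$muscle)
    env$voom <- vw
    deg <- per_gene_mixed_de(vw$expr, vw$weights, env$metadata)
    if (!is.null(env$eigen))
      deg <- flag_celltype_driven(deg, vw$expr, env$eigen)
    env$deg <- deg
    emit(.write_tsv(deg$table, file.path(cfg$output_dir, "deg_table.tsv")))
    emit(write_matrix_tsv(pairwise_deg_fraction(deg, exclude_flagged = FALSE),
                          file.path(cfg$output_dir, "pairwise_deg_pct_all.tsv"),
                          id_col = "muscle"))
    emit(write_matrix_tsv(pairwise_deg_fraction(deg, exclude_flagged = TRUE),
                          file.path(cfg$output_dir,
                                    "pairwise_deg_pct_intrinsic.tsv"),
                          id_col = "muscle"))
  })

  stage("network", cfg$stages$network, function() {
    nw <- cfg$network
    par <- network_params(nw$power, nw$min_module_size, nw$deep_split,
                          nw$merge_cut_height, nw$calibration_quantile,
                          nw$consensus_quantile)
    expr <- if (!is.null(env$voom)) env$voom$expr else env$logcpm$values
    toms <- per_individual_toms(expr, env$metadata, power = par$power,
                                min_samples = nw$min_samples)
    cons <- consensus_tom(toms, par$calibration_quantile,
                          par$consensus_quantile)
    assign0 <- cut_modules(1 - cons, par)
    if (any(assign0 != "unassigned")) {
      merged <- merge_modules(expr, assign0, par$merge_cut_height)
      env$modules <- merged$assignment
      env$me <- merged$me
      assoc <- module_muscle_association(env$me, env$metadata)
      conn <- intramodular_connectivity(cons, env$modules, nw$hub_fraction)
      ef <- if (!is.null(env$pathways))
        enrichment_factor(env$modules, env$pathways) else NULL
      ctmod <- if (!is.null(env$markers))
        flag_celltype_modules(env$modules, env$markers) else NULL
      top <- if (!is.null(env$deg))
        select_top_modules(setNames(env$deg$table$F, env$deg$table$gene),
                           env$modules) else NULL
      emit(.write_tsv(data.frame(gene = names(env$modules),
                                 module = unname(env$modules)),
                      file.path(cfg$output_dir, "module_assignment.tsv")))
      emit(write_matrix_tsv(env$me$scores,
                            file.path(cfg$output_dir, "module_eigengenes.tsv"),
                            id_col = "sample"))
      emit(.write_tsv(assoc$table,
                      file.path(cfg$output_dir, "module_muscle_association.tsv")))
      emit(.write_tsv(conn, file.path(cfg$output_dir, "connectivity.tsv")))
      if (!is.null(ef))
        jsonlite::write_json(ef,
          emit(file.path(cfg$output_dir, "enrichment_factor.json")),
          auto_unbox = TRUE, digits = NA)
      if (!is.null(ctmod))
        emit(.write_tsv(ctmod,
                        file.path(cfg$output_dir, "celltype_modules.tsv")))
      if (!is.null(top))
        emit(.write_tsv(top, file.path(cfg$output_dir, "top_modules.tsv")))
    } else {
      logf("network: no modules detected")
    }
  })

  stage("histology", cfg$stages$histology, function() {
    hp <- cfg$histology
    fp <- fiber_typing_params(bandwidth = hp$bandwidth,
                              min_cluster_fraction = hp$min_cluster_fraction,
                              min_fibers_per_sample =
                                hp$min_fibers_per_sample)
    myo <- simulate_myofiber_objects(
      n_samples = hp$n_samples,
      n_fibers_per_sample = hp$n_fibers_per_sample,
      contamination_rate = hp$contamination_rate,
      seed = stage_seed(cfg$seed, 3))
    filt <- filter_myofibers(myo$objects, fp)
    sel <- select_section(filt$objects, fp)
    ft <- fiber_type_clustering(sel$objects, fp)
    emit(write_matrix_tsv(ft$proportions,
                          file.path(cfg$output_dir, "fiber_type_proportions.tsv"),
                          id_col = "sample"))
    ves <- simulate_vessel_objects(
      n_sections = hp$vessel_sections,
      objects_per_section = hp$vessel_objects,
      tissue_area_um2 = hp$tissue_area_um2,
      capillary_fraction = hp$capillary_fraction,
      seed = stage_seed(cfg$seed, 4))
    cap <- capillary_metrics(ves$objects, ves$tissue_area_um2)
    emit(.write_tsv(cap, file.path(cfg$output_dir, "capillary_metrics.tsv")))
    foc <- simulate_foci_objects(
      n_fibers = hp$foci_fibers,
      foci_per_fiber_mean = hp$foci_per_fiber_mean,
      false_positive_rate = hp$foci_false_positive_rate,
      seed = stage_seed(cfg$seed, 5))
    fm <- foci_metrics(foc$objects, foc$n_fibers)
    emit(.write_tsv(fm, file.path(cfg$output_dir, "foci_metrics.tsv")))
  })

  checksums <- tools::md5sum(outputs)
  manifest <- list(package = "myoatlas",
                   version = as.character(utils::packageVersion("myoatlas")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   outputs = lapply(seq_along(outputs), function(i)
                     list(path = outputs[i], md5 = unname(checksums[i]))))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("pipeline complete: ", length(outputs), " outputs")
  invisible(manifest)
}

#' Summary report from a pipeline manifest
#'
#' Renders convenience figures from the written outputs: muscle-by-cell-type
#' mean-score heatmap, pairwise DEG percentage heatmap, fiber-type
#' proportion and capillary-density plots. Side-effect free on the data
#' files; requires the pheatmap and ggplot2 packages.
#'
#' @param manifest manifest list returned by [run_pipeline()] or path to
#'   `manifest.json`.
#' @param report_dir output directory for figures (default
#'   `<output_dir>/report`).
#' @return character vector of figure paths.
#' @export
report <- function(manifest, report_dir = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  if (is.null(manifest$outputs) || !length(manifest$outputs))
    stop("empty manifest")
  out_dir <- manifest$config$output_dir
  report_dir <- report_dir %||% file.path(out_dir, "report")
  dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(manifest$outputs, function(o) o$path, character(1))
  figs <- character(0)

  plot_heatmap <- function(tsv, png) {
    if (!file.exists(tsv) || !requireNamespace("pheatmap", quietly = TRUE))
      return(NULL)
    m <- read_matrix_tsv(tsv)
    grDevices::png(png, width = 900, height = 700)
    pheatmap::pheatmap(m, cluster_rows = nrow(m) > 2,
                       cluster_cols = ncol(m) > 2)
    grDevices::dev.off()
    figs <<- c(figs, png)
  }
  plot_heatmap(file.path(out_dir, "celltype_muscle_means.tsv"),
               file.path(report_dir, "celltype_muscle_means.png"))
  plot_heatmap(file.path(out_dir, "pairwise_deg_pct_all.tsv"),
               file.path(report_dir, "pairwise_deg_pct.png"))

  prop_tsv <- file.path(out_dir, "fiber_type_proportions.tsv")
  if (file.exists(prop_tsv)) {
    m <- read_matrix_tsv(prop_tsv)
    grDevices::png(file.path(report_dir, "fiber_type_proportions.png"),
                   width = 900, height = 600)
    graphics::boxplot(m, ylab = "proportion of myofibers",
                      main = "Fiber-type cluster proportions")
    grDevices::dev.off()
    figs <- c(figs, file.path(report_dir, "fiber_type_proportions.png"))
  }
  cap_tsv <- file.path(out_dir, "capillary_metrics.tsv")
  if (file.exists(cap_tsv)) {
    df <- read.delim(cap_tsv)
    grDevices::png(file.path(report_dir, "capillary_density.png"),
                   width = 700, height = 600)
    graphics::boxplot(df$capillary_density,
                      ylab = "capillaries per um^2",
                      main = "Capillary density")
    grDevices::dev.off()
    figs <- c(figs, file.path(report_dir, "capillary_density.png"))
  }
  figs
}
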