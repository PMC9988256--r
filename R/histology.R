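#' Fiber-typing parameters
#'
#' @param bandwidth mean-shift bandwidth in log-scaled MFI space
#'   (default 0.02).
#' @param min_cluster_fraction clusters holding less than this fraction of
#'   all fibers are discarded (default 0.01).
#' @param min_fibers_per_sample minimum retained fibers for a sample to enter
#'   the typing (default 100).
#' @param boundary_pct,interior_pct percentile thresholds on segmentation
#'   certainty (defaults 5 and 95, pooled across muscles).
#' @param csa_pct lower/upper cross-sectional-area percentiles, computed per
#'   muscle (default c(10, 99)).
#' @param circularity_pct circularity percentile (default 1).
#' @param strict_to_text if TRUE, apply the circularity rule exactly as the
#'   source protocol words it (exclude above the 1st percentile); the default
#'   FALSE excludes below it, the interpretation that retains myofibers.
#' @param kernel mean-shift kernel: "gaussian" (default, truncated at three
#'   bandwidths) or "flat" (top-hat over the bandwidth ball).
#' @return object of class `fiber_typing_params`.
#' @export
fiber_typing_params <- function(bandwidth = 0.02,
                                min_cluster_fraction = 0.01,
                                min_fibers_per_sample = 100,
                                boundary_pct = 5, interior_pct = 95,
                                csa_pct = c(10, 99), circularity_pct = 1,
                                strict_to_text = FALSE,
                                kernel = c("gaussian", "flat")) {
  stopifnot(bandwidth > 0, min_cluster_fraction > 0,
            min_cluster_fraction < 1)
  structure(list(bandwidth = bandwidth,
                 min_cluster_fraction = min_cluster_fraction,
                 min_fibers_per_sample = min_fibers_per_sample,
                 boundary_pct = boundary_pct, interior_pct = interior_pct,
                 csa_pct = csa_pct, circularity_pct = circularity_pct,
                 strict_to_text = strict_to_text,
                 kernel = match.arg(kernel)),
            class = "fiber_typing_params")
}

#' Filter non-myofiber objects by percentile rules
#'
#' Excludes objects whose boundary segmentation certainty is below the 5th
#' percentile, interior certainty above the 95th percentile, cross-sectional
#' area outside the 10th-99th percentile of its muscle, or circularity below
#' the 1st percentile. All criteria except CSA pool samples across muscles;
#' CSA percentiles are per muscle because CSA distributions differ between
#' muscles. All comparisons are strict, so objects exactly at a threshold
#' are retained, and constant features exclude nothing.
#'
#' @param objects myofiber object table (columns `area_um2`, `circularity`,
#'   `boundary_certainty`, `interior_certainty`, `sample_id`, `section_id`,
#'   and `muscle` for per-muscle CSA; without a muscle column CSA is pooled
#'   with a warning).
#' @param params a [fiber_typing_params()].
#' @return list with `objects` (retained rows) and `ledger` (data.frame of
#'   excluded object ids and which rule(s) fired).
#' @export
filter_myofibers <- function(objects, params = fiber_typing_params()) {
  if (nrow(objects) == 0) stop("empty object table")
  req <- c("object_id", "sample_id", "area_um2", "circularity",
           "boundary_certainty", "interior_certainty")
  miss <- setdiff(req, colnames(objects))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  pct <- function(x, p) quantile(x, p / 100, names = FALSE, type = 7)
  bad_boundary <- objects$boundary_certainty <
    pct(objects$boundary_certainty, params$boundary_pct)
  bad_interior <- objects$interior_certainty >
    pct(objects$interior_certainty, params$interior_pct)
  circ_thr <- pct(objects$circularity, params$circularity_pct)
  bad_circ <- if (params$strict_to_text)
    objects$circularity > circ_thr else objects$circularity < circ_thr

  if ("muscle" %in% colnames(objects)) {
    bad_csa <- logical(nrow(objects))
    for (m in unique(objects$muscle)) {
      i <- objects$muscle == m
      lo <- pct(objects$area_um2[i], params$csa_pct[1])
      hi <- pct(objects$area_um2[i], params$csa_pct[2])
      bad_csa[i] <- objects$area_um2[i] < lo | objects$area_um2[i] > hi
    }
  } else {
    warning("no muscle column; CSA percentiles computed on the pooled table")
    lo <- pct(objects$area_um2, params$csa_pct[1])
    hi <- pct(objects$area_um2, params$csa_pct[2])
    bad_csa <- objects$area_um2 < lo | objects$area_um2 > hi
  }

  excluded <- bad_boundary | bad_interior | bad_csa | bad_circ
  ledger <- data.frame(object_id = objects$object_id[excluded],
                       boundary = bad_boundary[excluded],
                       interior = bad_interior[excluded],
                       csa = bad_csa[excluded],
                       circularity = bad_circ[excluded],
                       stringsAsFactors = FALSE)
  list(objects = objects[!excluded, , drop = FALSE], ledger = ledger)
}

#' Select the best section per sample
#'
#' Keeps, for every sample, the section with the most retained fibers (ties
#' broken by section identifier order) and includes the sample only when
#' that section holds at least `min_fibers_per_sample` fibers.
#'
#' @param objects retained myofiber object table.
#' @param params a [fiber_typing_params()].
#' @return list with `objects` (fibers of chosen sections of included
#'   samples) and `sections` (per-sample chosen section, fiber count,
#'   inclusion flag).
#' @export
select_section <- function(objects, params = fiber_typing_params()) {
  tab <- lapply(split(objects, objects$sample_id), function(df) {
    counts <- table(df$section_id)
    counts <- counts[order(-as.numeric(counts), names(counts))]
    data.frame(sample_id = df$sample_id[1], section_id = names(counts)[1],
               n_fibers = as.integer(counts[1]),
               included = as.integer(counts[1]) >=
                 params$min_fibers_per_sample,
               stringsAsFactors = FALSE)
  })
  sections <- do.call(rbind, c(tab, list(make.row.names = FALSE)))
  keep_key <- paste(sections$sample_id[sections$included],
                    sections$section_id[sections$included])
  kept <- objects[paste(objects$sample_id, objects$section_id) %in%
                    keep_key, , drop = FALSE]
  list(objects = kept, sections = sections)
}

#' Myofiber typing by mean-shift clustering of MFI values
#'
#' Per sample and channel, mean fluorescence intensities are scaled without
#' centering (division by the per-sample root-mean-square), natural-log
#' transformed, pooled across samples and clustered by mean-shift (Gaussian
#' kernel by default) with bandwidth `h`, expressed as a fraction of the
#' per-channel range of the pooled log-scaled values (modes merged within
#' `h / 2`). Clusters
#' holding less than `min_cluster_fraction` of all fibers are discarded and
#' per-sample proportions are reported over the surviving clusters, with the
#' total fiber count of the sample as the denominator.
#'
#' @param objects myofiber object table (retained fibers of included
#'   samples) with three `mfi_*` columns.
#' @param params a [fiber_typing_params()].
#' @param mfi_channels names of the three MFI columns (default auto-detect).
#' @return object of class `fiber_type_result`: `labels` (per-object cluster
#'   or NA for discarded small clusters), `proportions` (sample x cluster),
#'   `centers` (cluster centroids in log-scaled space), `cluster_sizes`.
#' @export
fiber_type_clustering <- function(objects, params = fiber_typing_params(),
                                  mfi_channels = NULL) {
  if (is.null(mfi_channels))
    mfi_channels <- grep("^mfi_", colnames(objects), value = TRUE)
  stopifnot(length(mfi_channels) == 3)
  mfi <- as.matrix(objects[, mfi_channels])
  if (any(mfi <= 0)) {
    mfi[mfi <= 0] <- .Machine$double.eps
    message("non-positive MFI values shifted by machine epsilon")
  }
  ## per-sample, per-channel RMS scaling (no centering), then natural log
  scaled <- mfi
  for (s in unique(objects$sample_id)) {
    i <- objects$sample_id == s
    rms <- sqrt(colMeans(mfi[i, , drop = FALSE]^2))
    scaled[i, ] <- sweep(mfi[i, , drop = FALSE], 2, rms, `/`)
  }
  pts <- log(scaled)

  ## the bandwidth is a fraction of the per-channel data range: mean-shift
  ## runs on min-max range-scaled coordinates (centers are back-transformed)
  rng <- apply(pts, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  pts_s <- sweep(sweep(pts, 2, rng[1, ]), 2, span, `/`)
  ms <- mean_shift_cpp(pts_s, params$bandwidth, params$bandwidth / 2,
                       gaussian = identical(params$kernel, "gaussian"))
  ms$centers <- sweep(sweep(ms$centers, 2, span, `*`), 2, rng[1, ], `+`)
  labels <- ms$labels
  sizes <- table(labels)
  keep_cl <- as.integer(names(sizes)[sizes >= params$min_cluster_fraction *
                                       length(labels)])
  ## relabel surviving clusters by decreasing size
  keep_cl <- keep_cl[order(-sizes[as.character(keep_cl)])]
  relabel <- setNames(seq_along(keep_cl), keep_cl)
  final <- ifelse(labels %in% keep_cl,
                  relabel[as.character(labels)], NA_integer_)

  samples <- unique(objects$sample_id)
  prop <- matrix(0, length(samples), length(keep_cl),
                 dimnames = list(samples,
                                 paste0("cluster_", seq_along(keep_cl))))
  for (s in samples) {
    i <- objects$sample_id == s
    for (k in seq_along(keep_cl))
      prop[s, k] <- sum(final[i] == k, na.rm = TRUE) / sum(i)
  }
  centers <- ms$centers
  structure(list(labels = final, proportions = prop,
                 centers = centers, cluster_sizes = as.integer(sizes),
                 n_raw_clusters = nrow(centers)),
            class = "fiber_type_result")
}

#' Capillary metrics from a vessel object table
#'
#' An object is a capillary when it is positive for both CD31 and ENG, its
#' area is strictly between 3 and 51 um^2, and its circularity strictly
#' exceeds 0.5. Reports, per sample, the CD31-positive area as a percentage
#' of tissue area and the capillary density (capillaries per um^2).
#'
#' @param vessels object table with `cd31_pos`, `eng_pos`, `area_um2`,
#'   `circularity`, `sample_id`, `section_id`.
#' @param tissue_area_um2 named per-section tissue areas (or a single
#'   number).
#' @param area_range capillary size gate (default c(3, 51), strict).
#' @param min_circularity circularity gate (default 0.5, strict).
#' @param samples sample identifiers to report (default: those present in
#'   the table; pass explicitly to score samples with no objects as zero).
#' @return data.frame per sample: cd31_area_pct, n_capillaries,
#'   capillary_density.
#' @export
capillary_metrics <- function(vessels, tissue_area_um2,
                              area_range = c(3, 51),
                              min_circularity = 0.5,
                              samples = unique(vessels$sample_id)) {
  req <- c("cd31_pos", "eng_pos", "area_um2", "circularity", "sample_id",
           "section_id")
  miss <- setdiff(req, colnames(vessels))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(tissue_area_um2 <= 0)) stop("tissue area must be positive")

  out <- lapply(samples, function(s) {
    df <- vessels[vessels$sample_id == s, , drop = FALSE]
    secs <- unique(df$section_id)
    area <- if (length(tissue_area_um2) == 1 && is.null(names(tissue_area_um2)))
      tissue_area_um2 * max(1, length(secs)) else if (length(secs))
        sum(tissue_area_um2[secs]) else sum(tissue_area_um2)
    is_cap <- df$cd31_pos & df$eng_pos &
      df$area_um2 > area_range[1] & df$area_um2 < area_range[2] &
      df$circularity > min_circularity
    data.frame(sample_id = s,
               cd31_area_pct = 100 * sum(df$area_um2[df$cd31_pos]) / area,
               n_capillaries = sum(is_cap),
               capillary_density = sum(is_cap) / area,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(sample_id = character(0), cd31_area_pct = numeric(0),
                      n_capillaries = integer(0),
                      capillary_density = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Average RNA foci per myofiber
#'
#' A speckle is a focus when its area is strictly below 3.5 um^2 and its
#' circularity strictly above 0.98; when a negative-control table is
#' supplied, foci must additionally exceed the intensity threshold at which
#' approximately all control foci are classified negative (by default the
#' control maximum; configurable percentile).
#'
#' @param foci object table with `area_um2`, `circularity`, `sample_id` and
#'   optionally `intensity`.
#' @param fibers_per_sample named per-sample myofiber counts (> 0).
#' @param negative_control optional object table from a negative-control
#'   probe; its geometric foci define the intensity threshold.
#' @param max_area,min_circularity geometric gates (defaults 3.5, 0.98,
#'   strict).
#' @param control_percentile quantile of control focus intensities used as
#'   threshold (default 1 = maximum).
#' @return data.frame per sample: n_foci, n_fibers, avg_foci_per_fiber.
#' @export
foci_metrics <- function(foci, fibers_per_sample, negative_control = NULL,
                         max_area = 3.5, min_circularity = 0.98,
                         control_percentile = 1) {
  if (any(fibers_per_sample <= 0)) stop("fiber counts must be positive")
  is_focus <- foci$area_um2 < max_area & foci$circularity > min_circularity
  if (!is.null(negative_control)) {
    ctrl_foci <- negative_control$area_um2 < max_area &
      negative_control$circularity > min_circularity
    thr <- if (any(ctrl_foci))
      quantile(negative_control$intensity[ctrl_foci], control_percentile,
               names = FALSE, type = 7) else -Inf
    is_focus <- is_focus & foci$intensity > thr
  }
  samples <- names(fibers_per_sample)
  out <- lapply(samples, function(s) {
    n <- sum(is_focus & foci$sample_id == s)
    data.frame(sample_id = s, n_foci = n,
               n_fibers = unname(fibers_per_sample[s]),
               avg_foci_per_fiber = n / unname(fibers_per_sample[s]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Compare a per-sample histology metric between muscles
#'
#' Fits the atlas mixed model `metric ~ muscle + (1 | individual)` to any
#' per-sample quantitative readout (fiber-type proportion, capillary
#' density, foci average).
#'
#' @param metric named or ordered numeric vector, one value per row of
#'   `metadata`.
#' @param metadata data.frame with `muscle` and `individual`.
#' @return a `muscle_lmm` object (see [fit_muscle_lmm()]).
#' @export
compare_group_metric <- function(metric, metadata) {
  fit_muscle_lmm(metric, metadata)
}
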