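#' Consensus network parameters
#'
#' @param power soft-thresholding power (beta >= 1).
#' @param min_module_size smallest allowed module (default 20).
#' @param deep_split split sensitivity of the tree cut, 0 (conservative) to
#'   4 (aggressive); the atlas default is 0.
#' @param merge_cut_height eigengene-dissimilarity threshold below which
#'   modules are merged (default 0.2).
#' @param calibration_quantile quantile used to put per-individual TOMs on a
#'   common scale (default 0.95).
#' @param consensus_quantile elementwise quantile defining the consensus
#'   (default 0.40).
#' @return object of class `network_params`.
#' @export
network_params <- function(power = 8, min_module_size = 20, deep_split = 0,
                           merge_cut_height = 0.2,
                           calibration_quantile = 0.95,
                           consensus_quantile = 0.40) {
  stopifnot(power >= 1, min_module_size >= 2,
            merge_cut_height > 0, merge_cut_height < 1,
            calibration_quantile > 0, calibration_quantile < 1,
            consensus_quantile > 0, consensus_quantile < 1)
  structure(list(power = power, min_module_size = min_module_size,
                 deep_split = deep_split,
                 merge_cut_height = merge_cut_height,
                 calibration_quantile = calibration_quantile,
                 consensus_quantile = consensus_quantile),
            class = "network_params")
}

#' Biweight midcorrelation
#'
#' Robust correlation based on the median and the median absolute deviation:
#' observations are weighted by `(1 - u^2)^2` with `u = (x - med) / (9 mad)`
#' and weights zero beyond 9 MADs, which down-weights gross outliers.
#' Columns with zero MAD fall back to Pearson normalization for the affected
#' pairs (recorded in the `pearson_fallback` attribute); constant columns
#' get zero correlation with everything.
#'
#' @param x sample x gene numeric matrix (>= 4 rows).
#' @return gene x gene correlation matrix in `[-1, 1]` with unit diagonal.
#' @export
bicor <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("bicor requires >= 4 observations")
  med <- apply(x, 2, median)
  xc <- sweep(x, 2, med)
  madv <- apply(abs(xc), 2, median)
  fallback <- madv == 0
  z <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  if (any(!fallback)) {
    u <- sweep(xc[, !fallback, drop = FALSE], 2,
               9 * madv[!fallback], `/`)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a <- xc[, !fallback, drop = FALSE] * w
    nrm <- sqrt(colSums(a^2))
    nrm[nrm == 0] <- 1
    z[, !fallback] <- sweep(a, 2, nrm, `/`)
  }
  if (any(fallback)) {
    xf <- x[, fallback, drop = FALSE]
    xf <- sweep(xf, 2, colMeans(xf))
    nrm <- sqrt(colSums(xf^2))
    keep <- nrm > 0
    nrm[!keep] <- 1
    z[, fallback] <- sweep(xf, 2, nrm, `/`) *
      rep(as.numeric(keep), each = nrow(x))
  }
  r <- crossprod(z)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  attr(r, "pearson_fallback") <- colnames(x)[fallback]
  r
}

#' Signed-hybrid adjacency
#'
#' `a_ij = cor_ij ^ beta` for positive correlations, 0 otherwise, so only
#' positively co-regulated gene pairs are connected. The diagonal is set to
#' 1 (it is excluded from connectivity sums and handled explicitly by the
#' TOM formula).
#'
#' @param cor_matrix gene x gene correlation matrix.
#' @param beta soft-thresholding power.
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency_signed_hybrid <- function(cor_matrix, beta) {
  stopifnot(beta >= 1)
  a <- ifelse(cor_matrix > 0, cor_matrix^beta, 0)
  diag(a) <- 1
  dimnames(a) <- dimnames(cor_matrix)
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i` the connectivity of node i (diagonal excluded); the diagonal of the
#' result is 1. Combines direct adjacency with shared-neighbourhood overlap.
#'
#' @param adjacency symmetric adjacency matrix in `[0, 1]`.
#' @return symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Per-individual topological overlap matrices
#'
#' Computes a biweight-midcorrelation, signed-hybrid, soft-thresholded TOM
#' from each individual's samples separately. Individuals with fewer than
#' `min_samples` samples are skipped with a message; correlations on so few
#' observations are noisy by design — the consensus quantile is what
#' stabilizes the result.
#'
#' @param expr log-expression matrix (genes x samples).
#' @param metadata sample metadata with an `individual` column.
#' @param power soft-thresholding power.
#' @param min_samples minimum samples per individual (default 4).
#' @return named list of TOM matrices.
#' @export
per_individual_toms <- function(expr, metadata, power = 8, min_samples = 4) {
  stopifnot(ncol(expr) == nrow(metadata))
  idx <- split(seq_len(ncol(expr)), metadata$individual)
  small <- names(idx)[lengths(idx) < min_samples]
  if (length(small))
    message("skipping individuals with < ", min_samples, " samples: ",
            paste(small, collapse = ", "))
  idx <- idx[lengths(idx) >= min_samples]
  lapply(idx, function(i) {
    r <- bicor(t(expr[, i, drop = FALSE]))
    tom_similarity(adjacency_signed_hybrid(r, power))
  })
}

#' Consensus TOM across individuals
#'
#' Each TOM is put on a common scale by quantile matching: it is multiplied
#' by `reference / own`, where `own` is its `calibration_quantile` of
#' off-diagonal entries and `reference` is the median of those quantiles
#' across individuals. The consensus entry is the elementwise
#' `consensus_quantile` of the calibrated TOMs, retaining only edges
#' supported across individuals; values are clipped to `[0, 1]` and the
#' diagonal is 1.
#'
#' @param toms list of >= 2 TOM matrices over identical gene sets.
#' @param calibration_quantile scale-matching quantile (default 0.95).
#' @param consensus_quantile elementwise consensus quantile (default 0.40).
#' @return consensus TOM matrix.
#' @export
consensus_tom <- function(toms, calibration_quantile = 0.95,
                          consensus_quantile = 0.40) {
  stopifnot(length(toms) >= 2)
  dims <- vapply(toms, nrow, integer(1))
  if (length(unique(dims)) != 1 ||
      any(vapply(toms, ncol, integer(1)) != dims[1]))
    stop("all TOMs must share the same gene set")
  ut <- upper.tri(toms[[1]])
  qs <- vapply(toms, function(t) quantile(t[ut], calibration_quantile,
                                          names = FALSE, type = 7),
               numeric(1))
  if (any(qs == 0)) stop("zero calibration quantile in at least one TOM")
  ref <- median(qs)
  stacked <- vapply(seq_along(toms),
                    function(i) toms[[i]][ut] * (ref / qs[i]),
                    numeric(sum(ut)))
  cons_ut <- row_quantile_cpp(stacked, consensus_quantile)
  cons_ut <- pmin(pmax(cons_ut, 0), 1)
  cons <- matrix(0, dims[1], dims[1], dimnames = dimnames(toms[[1]]))
  cons[ut] <- cons_ut
  cons <- cons + t(cons)
  diag(cons) <- 1
  cons
}

## dynamic-hybrid-style tree cut on an average-linkage dendrogram.
## A branch is accepted as a module when it is large enough, its core (the
## lowest ~sqrt(size) internal merges) is tight, it joins the rest of the
## tree well above its own top merge (large local gap; in featureless noise
## trees the merge heights form a continuum and every local gap is tiny),
## and its top merge is not itself an outlier over the branch interior
## (which indicates two distinct modules joined just below the cut and
## triggers a split). Rejected branches are split and their children
## assessed recursively, which also trims chained stragglers off real
## modules. deep_split in {0..4} relaxes the thresholds.
.tree_cut_hybrid <- function(hc, min_size, deep_split = 0,
                             cut_height = NULL) {
  n <- length(hc$order)
  labels <- rep("unassigned", n)
  if (n < min_size || n < 3) return(setNames(labels, hc$labels))
  h <- hc$height
  q5 <- quantile(h, 0.05, names = FALSE, type = 7)
  if (is.null(cut_height)) cut_height <- q5 + 0.99 * (max(h) - q5)
  scale <- max(cut_height - q5, 1e-12)
  ds <- max(0, min(4, deep_split))
  max_core_scatter <- 0.64 + 0.065 * ds
  min_gap <- (1 - max_core_scatter) * 0.28

  m <- hc$merge
  nm <- nrow(m)
  members <- vector("list", nm)
  subh <- vector("list", nm)
  parent <- rep(NA_integer_, nm)
  for (i in seq_len(nm)) {
    mem <- integer(0); hh <- h[i]
    for (child in m[i, ]) {
      if (child < 0) mem <- c(mem, -child)
      else {
        mem <- c(mem, members[[child]])
        hh <- c(hh, subh[[child]])
        parent[child] <- i
      }
    }
    members[[i]] <- mem; subh[[i]] <- hh
  }

  modules <- list()
  assess <- function(node, attach) {
    mem <- members[[node]]
    if (length(mem) < min_size) return(invisible(NULL))
    hi <- sort(subh[[node]])
    core <- mean(hi[seq_len(ceiling(sqrt(length(hi))))])
    core_n <- (core - q5) / scale
    gap_n <- (attach - h[node]) / scale
    self_gap_n <- if (length(hi) > 1)
      (h[node] - hi[length(hi) - 1]) / scale else 0
    if (core_n <= max_core_scatter && gap_n >= min_gap &&
        self_gap_n < min_gap) {
      modules[[length(modules) + 1]] <<- mem
      return(invisible(NULL))
    }
    for (child in m[node, ])
      if (child > 0) assess(child, h[node])
    invisible(NULL)
  }

  ## maximal branches below the cut height
  tops <- which(h <= cut_height &
                  (is.na(parent) | h[ifelse(is.na(parent), 1, parent)] >
                     cut_height))
  for (node in tops) assess(node, cut_height)

  if (length(modules)) {
    ord <- order(lengths(modules), decreasing = TRUE)
    for (j in seq_along(ord))
      labels[modules[[ord[j]]]] <- paste0("M", j)
  }
  setNames(labels, hc$labels)
}

#' Detect modules by dynamic tree cut of the TOM dissimilarity
#'
#' Clusters `1 - TOM` by average-linkage agglomeration and cuts the
#' dendrogram with a dynamic hybrid criterion: branches must reach
#' `min_module_size`, be internally tight and separate clearly from the rest
#' of the tree, with `deep_split` mapping to progressively laxer thresholds.
#' Genes in no accepted branch get the reserved label `"unassigned"`
#' (the conventional grey module).
#'
#' @param diss_tom dissimilarity matrix `1 - TOM`.
#' @param params a [network_params()].
#' @return named character vector of module labels (`M1`, `M2`, ... by
#'   decreasing size, or `"unassigned"`).
#' @export
cut_modules <- function(diss_tom, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  n <- nrow(diss_tom)
  genes <- rownames(diss_tom) %||% paste0("g", seq_len(n))
  if (n < params$min_module_size)
    return(setNames(rep("unassigned", n), genes))
  hc <- hclust(as.dist(diss_tom), method = "average")
  hc$labels <- genes
  .tree_cut_hybrid(hc, params$min_module_size, params$deep_split)
}

#' Module eigengenes
#'
#' The summary expression profile of each module: the first principal
#' component score of the standardized member-gene matrix across all
#' samples, sign-oriented to correlate positively with the module's mean
#' standardized expression.
#'
#' @param expr log-expression matrix (genes x samples).
#' @param assignment named module label vector (from [cut_modules()]).
#' @return object of class `me_matrix`: `scores` (sample x module) and
#'   `var_explained`.
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  if (!length(mods)) stop("no assigned modules")
  sets <- lapply(setNames(mods, mods),
                 function(mo) names(assignment)[assignment == mo])
  et <- celltype_eigenvectors(expr, sets)
  structure(list(scores = et$scores, var_explained = et$var_explained),
            class = "me_matrix")
}

#' Merge modules with similar eigengenes
#'
#' Hierarchically clusters module eigengenes on dissimilarity `1 - cor` and
#' merges branches below `merge_cut_height`, recomputing eigengenes and
#' iterating until stable. Anticorrelated modules are never merged.
#'
#' @param expr log-expression matrix (genes x samples).
#' @param assignment named module label vector.
#' @param merge_cut_height merge threshold (default 0.2).
#' @param max_iter safety cap on merge rounds.
#' @return list with updated `assignment` and `me`.
#' @export
merge_modules <- function(expr, assignment, merge_cut_height = 0.2,
                          max_iter = 10) {
  me <- module_eigengenes(expr, assignment)
  for (it in seq_len(max_iter)) {
    mods <- colnames(me$scores)
    if (length(mods) < 2) break
    d <- as.dist(1 - cor(me$scores))
    hc <- hclust(d, method = "average")
    grp <- cutree(hc, h = merge_cut_height)
    if (max(table(grp)) == 1) break
    sizes <- table(assignment)[mods]
    for (g in unique(grp)) {
      gm <- mods[grp == g]
      if (length(gm) < 2) next
      target <- gm[which.max(sizes[gm])]
      assignment[assignment %in% gm] <- target
    }
    me <- module_eigengenes(expr, assignment)
  }
  list(assignment = assignment, me = me)
}

#' Intramodular connectivity and hub genes
#'
#' `k_within` of a gene is its total adjacency to same-module genes
#' (diagonal excluded); hubs are the top `hub_fraction` by `k_within` within
#' each module. Unassigned genes are absent from the result.
#'
#' @param adjacency gene x gene adjacency matrix.
#' @param assignment named module label vector.
#' @param hub_fraction fraction of each module flagged as hubs
#'   (default 0.10).
#' @return data.frame with gene, module, k_within, hub.
#' @export
intramodular_connectivity <- function(adjacency, assignment,
                                      hub_fraction = 0.10) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  out <- list()
  for (mo in sort(setdiff(unique(assignment), "unassigned"))) {
    g <- names(assignment)[assignment == mo]
    sub <- a[g, g, drop = FALSE]
    kw <- rowSums(sub)
    thr <- quantile(kw, 1 - hub_fraction, names = FALSE, type = 7)
    out[[mo]] <- data.frame(gene = g, module = mo, k_within = kw,
                            hub = kw >= thr, stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Enrichment factor of a module assignment against pathway knowledge
#'
#' Every unordered pair of genes (restricted to genes with a module
#' assignment and at least one pathway annotation) is classified: group 1
#' same module and same pathway, group 2 same module only, group 3 same
#' pathway only, group 4 neither; two genes share a pathway when they share
#' at least one annotation. `EF = (n1 n4) / (n2 n3)` measures concordance of
#' the modules with the knowledge network; `n2 n3 = 0` is reported as an
#' infinite-EF flag.
#'
#' @param assignment named module label vector.
#' @param pathways named list of pathway gene sets.
#' @return list with counts `n1`-`n4`, `EF`, `infinite`, `n_genes`.
#' @export
enrichment_factor <- function(assignment, pathways) {
  annotated <- unique(unlist(pathways))
  genes <- names(assignment)[assignment != "unassigned"]
  genes <- intersect(genes, annotated)
  G <- length(genes)
  if (G < 2)
    return(list(n1 = 0, n2 = 0, n3 = 0, n4 = 0, EF = NA_real_,
                infinite = FALSE, n_genes = G))
  mod <- assignment[genes]
  same_mod <- outer(mod, mod, `==`)
  memb <- vapply(pathways, function(p) genes %in% p, logical(G))
  same_path <- tcrossprod(memb * 1) > 0
  ut <- upper.tri(same_mod)
  n1 <- sum(same_mod[ut] & same_path[ut])
  n2 <- sum(same_mod[ut] & !same_path[ut])
  n3 <- sum(!same_mod[ut] & same_path[ut])
  n4 <- sum(!same_mod[ut] & !same_path[ut])
  denom <- as.numeric(n2) * as.numeric(n3)
  if (denom == 0)
    return(list(n1 = n1, n2 = n2, n3 = n3, n4 = n4, EF = Inf,
                infinite = TRUE, n_genes = G))
  list(n1 = n1, n2 = n2, n3 = n3, n4 = n4,
       EF = as.numeric(n1) * as.numeric(n4) / denom,
       infinite = FALSE, n_genes = G)
}

#' Knowledge-calibrated parameter sweep
#'
#' Runs the full per-individual / calibrated / consensus / tree-cut / merge
#' pipeline for every grid point and scores each module assignment by its
#' enrichment factor against the pathway knowledge network. Returns the
#' ranked results and the argmax parameters (ties broken by smaller power,
#' then smaller min module size, deep split and cut height).
#'
#' @param expr log-expression matrix (genes x samples).
#' @param metadata sample metadata with `individual`.
#' @param pathways named list of pathway gene sets.
#' @param powers,min_sizes,deep_splits,cut_heights grid axes; defaults are
#'   the full atlas sweep (powers 6-22, min sizes 15/20/30, deep split
#'   0/2/4, cut heights 0.1-0.3).
#' @param calibration_quantile,consensus_quantile consensus settings.
#' @param min_samples minimum samples per individual network.
#' @return list with `results` (data.frame, one row per grid point),
#'   `best` (a [network_params()]), `best_assignment`, `best_me`.
#' @export
parameter_sweep <- function(expr, metadata, pathways,
                            powers = c(6, 8, 10, 12, 14, 18, 22),
                            min_sizes = c(15, 20, 30),
                            deep_splits = c(0, 2, 4),
                            cut_heights = c(0.1, 0.15, 0.2, 0.25, 0.3),
                            calibration_quantile = 0.95,
                            consensus_quantile = 0.40,
                            min_samples = 4) {
  rows <- list()
  assignments <- list()
  for (pw in powers) {
    toms <- per_individual_toms(expr, metadata, power = pw,
                                min_samples = min_samples)
    cons <- consensus_tom(toms, calibration_quantile, consensus_quantile)
    diss <- 1 - cons
    for (ms in min_sizes) for (ds in deep_splits) {
      base_par <- network_params(power = pw, min_module_size = ms,
                                 deep_split = ds)
      assign0 <- cut_modules(diss, base_par)
      for (ch in cut_heights) {
        key <- paste(pw, ms, ds, ch, sep = "_")
        if (all(assign0 == "unassigned")) {
          merged_assign <- assign0
          ef <- list(n1 = 0, n2 = 0, n3 = 0, n4 = 0, EF = NA_real_,
                     infinite = FALSE)
          n_mod <- 0L
        } else {
          merged <- merge_modules(expr, assign0, merge_cut_height = ch)
          merged_assign <- merged$assignment
          ef <- enrichment_factor(merged_assign, pathways)
          n_mod <- length(setdiff(unique(merged_assign), "unassigned"))
        }
        assignments[[key]] <- merged_assign
        rows[[key]] <- data.frame(
          power = pw, min_module_size = ms, deep_split = ds,
          merge_cut_height = ch, n_modules = n_mod,
          n1 = ef$n1, n2 = ef$n2, n3 = ef$n3, n4 = ef$n4,
          EF = ef$EF, infinite_EF = isTRUE(ef$infinite))
      }
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ord <- order(-ifelse(is.na(res$EF), -Inf, res$EF), res$power,
               res$min_module_size, res$deep_split, res$merge_cut_height)
  res <- res[ord, ]
  best_row <- res[1, ]
  best <- network_params(power = best_row$power,
                         min_module_size = best_row$min_module_size,
                         deep_split = best_row$deep_split,
                         merge_cut_height = best_row$merge_cut_height,
                         calibration_quantile = calibration_quantile,
                         consensus_quantile = consensus_quantile)
  best_key <- paste(best_row$power, best_row$min_module_size,
                    best_row$deep_split, best_row$merge_cut_height,
                    sep = "_")
  best_assignment <- assignments[[best_key]]
  best_me <- if (any(best_assignment != "unassigned"))
    module_eigengenes(expr, best_assignment) else NULL
  list(results = res, best = best, best_assignment = best_assignment,
       best_me = best_me)
}

#' Module-muscle association
#'
#' Fits the atlas mixed model to every module eigengene, applies BH-FDR over
#' modules, tests the individual random effect by likelihood-ratio test, and
#' labels modules significant for the muscle term as muscle-related.
#'
#' @param me an `me_matrix`.
#' @param metadata sample metadata aligned to the score rows.
#' @param alpha FDR threshold (default 0.05).
#' @return list with `table` (module, F, p, q, ranova_p, muscle_related),
#'   `contrasts` for muscle-related modules, `fits`.
#' @export
module_muscle_association <- function(me, metadata, alpha = 0.05) {
  stopifnot(inherits(me, "me_matrix"),
            nrow(me$scores) == nrow(metadata))
  fits <- lapply(colnames(me$scores), function(mo)
    fit_muscle_lmm(me$scores[, mo], metadata, ranova = TRUE))
  names(fits) <- colnames(me$scores)
  tab <- data.frame(module = colnames(me$scores),
                    F = vapply(fits, `[[`, numeric(1), "F"),
                    p = vapply(fits, `[[`, numeric(1), "p"),
                    ranova_p = vapply(fits, `[[`, numeric(1), "ranova_p"),
                    stringsAsFactors = FALSE)
  tab$q <- p.adjust(tab$p, method = "BH")
  tab$muscle_related <- tab$q < alpha
  sig <- tab$module[tab$muscle_related]
  list(table = tab[, c("module", "F", "p", "q", "ranova_p",
                       "muscle_related")],
       contrasts = lapply(setNames(sig, sig),
                          function(mo) fits[[mo]]$contrasts),
       fits = fits)
}

#' Flag modules driven by cell-type composition
#'
#' A module is flagged when it contains at least `min_markers` marker genes
#' of any single cell type.
#'
#' @param assignment named module label vector.
#' @param markers named list of marker gene sets.
#' @param min_markers threshold (default 5).
#' @return data.frame with module, celltype_flagged, celltype, n_markers.
#' @export
flag_celltype_modules <- function(assignment, markers, min_markers = 5) {
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  out <- lapply(mods, function(mo) {
    g <- names(assignment)[assignment == mo]
    counts <- vapply(markers, function(set) sum(g %in% set), integer(1))
    best <- if (length(counts)) which.max(counts) else integer(0)
    n_best <- if (length(best)) counts[best] else 0L
    data.frame(module = mo,
               celltype_flagged = n_best >= min_markers,
               celltype = if (length(best) && n_best >= min_markers)
                 names(counts)[best] else NA_character_,
               n_markers = as.integer(n_best), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Select top modules by member-gene F statistics
#'
#' A module is selected when the third quartile of its member genes'
#' differential-expression F values strictly exceeds `f_threshold` (5.5) and,
#' when per-module enrichment q-values are supplied, the annotation q is
#' below `q_threshold` (0.01). Without annotation q-values that criterion is
#' skipped with a warning.
#'
#' @param f_values named per-gene F statistics from the DEA.
#' @param assignment named module label vector.
#' @param annotation_q optional named per-module enrichment q-values.
#' @param f_threshold F third-quartile threshold (default 5.5, strict).
#' @param q_threshold annotation threshold (default 0.01).
#' @return data.frame with module, q3_f, annotation_q, selected.
#' @export
select_top_modules <- function(f_values, assignment, annotation_q = NULL,
                               f_threshold = 5.5, q_threshold = 0.01) {
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  if (is.null(annotation_q))
    warning("no annotation q-values supplied; enrichment criterion skipped")
  out <- lapply(mods, function(mo) {
    g <- intersect(names(assignment)[assignment == mo], names(f_values))
    q3 <- if (length(g)) quantile(f_values[g], 0.75, names = FALSE,
                                  type = 7) else NA_real_
    aq <- if (!is.null(annotation_q)) annotation_q[mo] else NA_real_
    sel <- !is.na(q3) && q3 > f_threshold &&
      (is.null(annotation_q) || (!is.na(aq) && aq < q_threshold))
    data.frame(module = mo, q3_f = q3, annotation_q = unname(aq),
               selected = sel, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
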