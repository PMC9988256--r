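#' Precision weights from the mean-variance trend
#'
#' Computes log2-CPM (prior count 0.5) and per-observation precision weights
#' from the fitted mean-variance trend of the count data (`limma::voom`),
#' using a muscle-indicator fixed-effects design for trend estimation. The
#' weights are the inverse fourth power of the predicted square-root
#' residual standard deviation, interpolated at each observation's fitted
#' log-count and clamped at the trend endpoints.
#'
#' @param counts filtered gene x sample count matrix.
#' @param factors per-sample TMM normalization factors.
#' @param design_labels per-sample grouping labels (muscle) for the trend
#'   design.
#' @return list with `expr` (log2-CPM matrix) and `weights` (same shape,
#'   strictly positive).
#' @export
voom_weights <- function(counts, factors = NULL, design_labels) {
  if (nrow(counts) < 10)
    stop("fewer than 10 genes: mean-variance trend unreliable")
  stopifnot(length(design_labels) == ncol(counts))
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  design <- model.matrix(~ factor(design_labels,
                                  levels = unique(design_labels)))
  v <- limma::voom(as.matrix(counts), design = design,
                   lib.size = colSums(counts) * factors)
  list(expr = v$E, weights = structure(v$weights, dimnames = dimnames(v$E)))
}

#' Per-gene weighted mixed-model differential expression
#'
#' Fits `expression ~ muscle + (1 | individual)` with precision weights for
#' every gene, tests the muscle term (Satterthwaite F), applies BH-FDR
#' across genes, and reports Tukey-adjusted pairwise muscle contrasts.
#' Constant genes are excluded from testing with a degenerate flag;
#' singular fits are flagged, not dropped.
#'
#' @param expr log-expression matrix (genes x samples).
#' @param weights positive weight matrix aligned to `expr` (or NULL).
#' @param metadata data.frame with `muscle` and `individual`, aligned to the
#'   columns of `expr`.
#' @param contrasts compute pairwise contrasts per gene (default TRUE).
#' @return object of class `deg_table`: `table` (gene, F, p, q, flags),
#'   `contrast_estimates`/`contrast_p` (gene x pair matrices), `pairs`,
#'   `muscles`.
#' @export
per_gene_mixed_de <- function(expr, weights = NULL, metadata,
                              contrasts = TRUE) {
  stopifnot(ncol(expr) == nrow(metadata))
  if (!is.null(weights) && !all(dim(weights) == dim(expr)))
    stop("weights dimensions must match expr")
  genes <- rownames(expr) %||% paste0("g", seq_len(nrow(expr)))
  lev <- unique(metadata$muscle)
  pairs <- utils::combn(lev, 2)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = "-")

  Fv <- pv <- rep(NA_real_, nrow(expr))
  singular <- degenerate <- logical(nrow(expr))
  cest <- cp <- if (contrasts)
    matrix(NA_real_, nrow(expr), ncol(pairs),
           dimnames = list(genes, pair_names))
  for (g in seq_len(nrow(expr))) {
    y <- expr[g, ]
    if (var(y) == 0) { degenerate[g] <- TRUE; next }
    w <- if (is.null(weights)) NULL else weights[g, ]
    fit <- fit_muscle_lmm(y, metadata, weights = w, contrasts = contrasts)
    Fv[g] <- fit$F; pv[g] <- fit$p
    singular[g] <- fit$singular
    if (contrasts) {
      cest[g, ] <- fit$contrasts$estimate
      cp[g, ] <- fit$contrasts$p_adj
    }
  }
  q <- rep(NA_real_, length(pv))
  q[!degenerate] <- p.adjust(pv[!degenerate], method = "BH")
  tab <- data.frame(gene = genes, F = Fv, p = pv, q = q,
                    singular = singular, degenerate = degenerate,
                    celltype_driven = NA, celltype = NA_character_,
                    celltype_r = NA_real_, stringsAsFactors = FALSE)
  structure(list(table = tab, contrast_estimates = cest, contrast_p = cp,
                 pairs = pair_names, muscles = lev),
            class = "deg_table")
}

#' Flag differentially expressed genes driven by cell-type composition
#'
#' For every significant DEG and every cell type, computes the Pearson
#' correlation between the gene's expression and the cell-type eigenvector
#' score across samples, applies BH-FDR over the whole (gene, cell type)
#' grid, and flags a gene as cell-type related when r > `r_threshold` with
#' correlation FDR < `alpha` for at least one cell type. Unflagged DEGs form
#' the set of muscle-intrinsic genes.
#'
#' @param deg a `deg_table` from [per_gene_mixed_de()].
#' @param expr the log-expression matrix the DEA was run on.
#' @param eigen an `eigen_table` covering the same samples.
#' @param alpha FDR threshold (default 0.05), applied both to select DEGs
#'   and to the correlation family.
#' @param r_threshold correlation threshold (default 0.5).
#' @return the `deg_table` with `celltype_driven`, `celltype` (strongest
#'   offending cell type) and `celltype_r` filled for significant DEGs.
#' @export
flag_celltype_driven <- function(deg, expr, eigen, alpha = 0.05,
                                 r_threshold = 0.5) {
  stopifnot(inherits(deg, "deg_table"), inherits(eigen, "eigen_table"))
  if (!all(colnames(expr) %in% rownames(eigen$scores)))
    stop("eigen scores must cover all samples in expr")
  sc <- eigen$scores[colnames(expr), , drop = FALSE]
  tab <- deg$table
  sig <- which(!is.na(tab$q) & tab$q < alpha)
  if (!length(sig)) return(deg)
  cts <- colnames(sc)
  r <- p <- matrix(NA_real_, length(sig), length(cts),
                   dimnames = list(tab$gene[sig], cts))
  for (i in seq_along(sig)) {
    y <- expr[tab$gene[sig[i]], ]
    for (j in seq_along(cts)) {
      ct <- cor.test(y, sc[, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  qmat <- matrix(p.adjust(p, method = "BH"), nrow(p), dimnames = dimnames(p))
  flagged <- r > r_threshold & qmat < alpha
  tab$celltype_driven[sig] <- rowSums(flagged, na.rm = TRUE) > 0
  for (i in seq_along(sig)) {
    hit <- which(flagged[i, ])
    if (length(hit)) {
      best <- hit[which.max(r[i, hit])]
      tab$celltype[sig[i]] <- cts[best]
      tab$celltype_r[sig[i]] <- r[i, best]
    }
  }
  deg$table <- tab
  deg
}

#' Percentage of DEGs per muscle pair
#'
#' Cell (i, j) is 100 times the number of genes significant for that muscle
#' pair (within-gene Tukey-adjusted contrast p, then BH across genes per
#' pair) divided by the number of genes considered. Optionally excludes
#' cell-type-driven genes.
#'
#' @param deg a `deg_table` with contrasts.
#' @param exclude_flagged drop cell-type-driven genes first (default FALSE).
#' @param alpha significance threshold on the per-pair BH q (default 0.05).
#' @return symmetric muscle x muscle percent matrix with zero diagonal.
#' @export
pairwise_deg_fraction <- function(deg, exclude_flagged = FALSE,
                                  alpha = 0.05) {
  stopifnot(inherits(deg, "deg_table"), !is.null(deg$contrast_p))
  keep <- !deg$table$degenerate
  if (exclude_flagged)
    keep <- keep & !(deg$table$celltype_driven %in% TRUE)
  cp <- deg$contrast_p[keep, , drop = FALSE]
  muscles <- deg$muscles
  m <- matrix(0, length(muscles), length(muscles),
              dimnames = list(muscles, muscles))
  if (nrow(cp) > 0) {
    pairs <- strsplit(deg$pairs, "-", fixed = TRUE)
    for (j in seq_along(pairs)) {
      qj <- p.adjust(cp[, j], method = "BH")
      pct <- 100 * sum(qj < alpha, na.rm = TRUE) / nrow(cp)
      a <- pairs[[j]][1]; b <- pairs[[j]][2]
      m[a, b] <- m[b, a] <- pct
    }
  }
  m
}

#' Transcript-level differential expression
#'
#' Runs the identical precision-weighted mixed-model machinery on transcript
#' rows, restricted to transcripts of genes present in the filtered gene
#' dataset, and marks transcripts of cell-type-driven genes so they can be
#' excluded from the muscle-intrinsic set.
#'
#' @param transcript_counts transcript x sample count matrix.
#' @param transcript_to_gene data.frame with columns `transcript`, `gene`.
#' @param factors per-sample normalization factors for the transcript data.
#' @param metadata sample metadata (muscle, individual).
#' @param flagged_genes character vector of cell-type-driven gene ids.
#' @param gene_universe optional character vector restricting parent genes.
#' @return a `deg_table` whose `table` gains `transcript` and `parent_gene`
#'   columns and a `celltype_driven` flag inherited from the parent gene.
#' @export
transcript_level_de <- function(transcript_counts, transcript_to_gene,
                                factors = NULL, metadata,
                                flagged_genes = character(0),
                                gene_universe = NULL) {
  stopifnot(all(c("transcript", "gene") %in% colnames(transcript_to_gene)))
  map <- setNames(transcript_to_gene$gene, transcript_to_gene$transcript)
  tx <- rownames(transcript_counts)
  keep <- tx %in% names(map)
  if (!is.null(gene_universe)) keep <- keep & map[tx] %in% gene_universe
  counts <- transcript_counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) stop("no transcripts left after gene restriction")
  vw <- voom_weights(counts, factors, metadata$muscle)
  det <- per_gene_mixed_de(vw$expr, vw$weights, metadata)
  det$table$transcript <- det$table$gene
  det$table$parent_gene <- unname(map[det$table$transcript])
  det$table$celltype_driven <- det$table$parent_gene %in% flagged_genes &
    !is.na(det$table$q) & det$table$q < 0.05
  det
}
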