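#' Exclude shallowly sequenced samples
#'
#' Keeps samples whose total assigned read count strictly exceeds the
#' threshold (samples with 5 M or fewer assigned reads are excluded from all
#' downstream analyses).
#'
#' @param counts gene x sample integer matrix.
#' @param min_assigned_reads threshold (default 5e6).
#' @return character vector of retained sample identifiers, order preserved.
#' @export
sample_qc <- function(counts, min_assigned_reads = 5e6) {
  if (is.null(dim(counts)) || ncol(counts) == 0 || nrow(counts) == 0)
    stop("empty count matrix")
  stopifnot(min_assigned_reads >= 0)
  colnames(counts)[colSums(counts) > min_assigned_reads]
}

#' Filter lowly expressed genes
#'
#' A gene is retained iff it has `min_count` or more reads in at least
#' `min_samples` samples (defaults 10 reads / 16 samples, the size of the
#' smallest muscle group).
#'
#' @param counts gene x sample integer matrix.
#' @param min_count minimum read count (default 10).
#' @param min_samples minimum number of samples reaching it (default 16).
#' @return filtered count matrix, sample set unchanged.
#' @export
filter_low_expressed <- function(counts, min_count = 10, min_samples = 16) {
  if (min_samples > ncol(counts))
    stop("min_samples exceeds the number of samples")
  keep <- rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization (30% log-ratio trim,
#' 5% absolute-intensity trim, precision weights), computed with
#' `edgeR::calcNormFactors`. The reference sample is the column whose
#' upper-quartile expression is closest to the mean upper-quartile. Factors
#' are scaled to have geometric mean 1.
#'
#' @param counts gene x sample matrix.
#' @param logratio_trim two-sided log-ratio trim fraction (default 0.30).
#' @param abs_trim absolute-intensity trim fraction (default 0.05).
#' @return named numeric vector of per-sample factors.
#' @export
tmm_norm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  if (any(colSums(counts) == 0)) stop("sample with zero total count")
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  setNames(f, colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (effective library size in millions))`, where the
#' effective library size is the column sum times its normalization factor.
#'
#' @param counts gene x sample matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior_count pseudo-count (default 0.5).
#' @return list with `values` (log2-CPM matrix) and `norm_factors`.
#' @export
cpm_log <- function(counts, factors = NULL, prior_count = 0.5) {
  stopifnot(prior_count > 0)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- colSums(counts) * factors / 1e6
  values <- log2(sweep(counts + prior_count, 2, eff, `/`))
  dimnames(values) <- dimnames(counts)
  list(values = values, norm_factors = setNames(factors, colnames(counts)))
}

#' Per-gene variance decomposition across known factors
#'
#' Fits a fixed-effects linear model per gene over the supplied factors and
#' reports each factor's share of the total sum of squares (Type II partial
#' SS via `car::Anova`), in percent, with a residual column completing to
#' 100. Constant or aliased factors are dropped with a warning.
#'
#' @param expr log-expression matrix (genes x samples) or the list returned
#'   by [cpm_log()].
#' @param metadata data.frame with one row per sample (same order as the
#'   columns of `expr`).
#' @param factor_names columns of `metadata` to include.
#' @return data.frame, genes x (factors + residual), percentages.
#' @export
variance_decomposition <- function(expr, metadata,
                                   factor_names = c("muscle", "individual",
                                                    "batch")) {
  if (is.list(expr) && !is.null(expr$values)) expr <- expr$values
  stopifnot(ncol(expr) == nrow(metadata))
  missing <- setdiff(factor_names, colnames(metadata))
  if (length(missing))
    stop("factors absent from metadata: ", paste(missing, collapse = ", "))
  keep <- vapply(factor_names, function(f) {
    v <- metadata[[f]]
    length(unique(v)) > 1
  }, logical(1))
  if (any(!keep))
    warning("dropping constant factor(s): ",
            paste(factor_names[!keep], collapse = ", "))
  factor_names <- factor_names[keep]
  if (!length(factor_names)) stop("no usable factors")
  df <- metadata[, factor_names, drop = FALSE]
  for (f in factor_names)
    if (is.character(df[[f]])) df[[f]] <- factor(df[[f]])
  form <- as.formula(paste("y ~", paste(factor_names, collapse = " + ")))

  res <- matrix(NA_real_, nrow(expr), length(factor_names) + 1,
                dimnames = list(rownames(expr),
                                c(factor_names, "residual")))
  for (g in seq_len(nrow(expr))) {
    df$y <- expr[g, ]
    fit <- lm(form, data = df)
    a <- tryCatch(car::Anova(fit, type = 2, singular.ok = TRUE),
                  error = function(e) NULL)
    if (is.null(a)) {
      ## perfect fits (zero residual) break the F computation; fall back
      ## to explicit Type-II drop-term sums of squares
      rss_full <- sum(resid(fit)^2)
      ss <- vapply(factor_names, function(f) {
        red <- lm(as.formula(paste("y ~",
                                   paste(setdiff(factor_names, f),
                                         collapse = " + "),
                                   if (length(factor_names) == 1) "1")),
                  data = df)
        sum(resid(red)^2) - rss_full
      }, numeric(1))
      ss <- c(ss, Residuals = rss_full)
    } else {
      ss <- a[["Sum Sq"]]
      names(ss) <- rownames(a)
    }
    tot <- sum(ss, na.rm = TRUE)
    if (tot <= 0) {
      res[g, ] <- c(rep(0, length(factor_names)), 100)
      next
    }
    shares <- 100 * ss[factor_names] / tot
    shares[is.na(shares)] <- 0
    res[g, ] <- c(shares, 100 - sum(shares))
  }
  as.data.frame(res)
}

#' Principal-component QC of log-expression values
#'
#' Convenience wrapper around `prcomp` on centered, scaled log-CPM, for
#' unsupervised inspection of sample structure.
#'
#' @param expr log-expression matrix (genes x samples) or [cpm_log()] output.
#' @param n_pcs number of components to return.
#' @return data.frame of per-sample scores plus percent variance attribute.
#' @export
pca_qc <- function(expr, n_pcs = 5) {
  if (is.list(expr) && !is.null(expr$values)) expr <- expr$values
  keep <- apply(expr, 1, sd) > 0
  p <- prcomp(t(expr[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  n_pcs <- min(n_pcs, ncol(p$x))
  out <- as.data.frame(p$x[, seq_len(n_pcs), drop = FALSE])
  attr(out, "percent_var") <- 100 * p$sdev^2 / sum(p$sdev^2)
  out
}
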