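#' Summarize marker-gene sets by their first principal component
#'
#' For each cell type, marker rows of the log-expression matrix are
#' standardized (zero mean, unit variance across samples) and summarized by
#' the first right-singular vector of the marker x sample matrix; the
#' per-sample scores act as a relative-abundance proxy for that cell type.
#' Scores are sign-oriented to correlate positively with the set's mean
#' standardized expression, so higher score = higher marker expression.
#'
#' @param expr log-expression matrix (genes x samples) or [cpm_log()] output.
#' @param markers named list of marker gene identifier vectors.
#' @return object of class `eigen_table`: `scores` (sample x cell type),
#'   `var_explained`, and the identifiers dropped per set.
#' @export
celltype_eigenvectors <- function(expr, markers) {
  if (is.list(expr) && !is.null(expr$values)) expr <- expr$values
  stopifnot(is.list(markers), length(markers) > 0, !is.null(names(markers)))
  scores <- matrix(NA_real_, ncol(expr), length(markers),
                   dimnames = list(colnames(expr), names(markers)))
  ve <- setNames(numeric(length(markers)), names(markers))
  dropped <- list()
  for (ct in names(markers)) {
    ids <- markers[[ct]]
    found <- intersect(ids, rownames(expr))
    lost <- setdiff(ids, found)
    X <- expr[found, , drop = FALSE]
    sds <- apply(X, 1, sd)
    if (any(sds == 0)) {
      lost <- c(lost, rownames(X)[sds == 0])
      X <- X[sds != 0, , drop = FALSE]
    }
    if (length(lost)) dropped[[ct]] <- lost
    if (nrow(X) == 0)
      stop("no resolvable, non-constant markers for cell type '", ct, "'")
    X <- t(scale(t(X)))
    sv <- svd(X)
    ## PC1 score scaled by 1/sqrt(m): a set of identical standardized
    ## genes returns exactly that standardized profile
    sc <- sv$d[1] * sv$v[, 1] / sqrt(nrow(X))
    s <- sign(cor(sc, colMeans(X)))
    if (is.na(s) || s == 0) s <- 1
    scores[, ct] <- s * sc
    ve[ct] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (length(dropped))
    warning("markers dropped (unresolvable or constant): ",
            paste(names(dropped), collapse = ", "))
  structure(list(scores = scores, var_explained = ve, dropped = dropped),
            class = "eigen_table")
}

#' Fit the atlas mixed model `y ~ muscle + (1 | individual)`
#'
#' Restricted-maximum-likelihood fit with muscle as a fixed effect and
#' individual as a random intercept, optionally with per-observation
#' precision weights. The muscle term is tested with an F test using the
#' Satterthwaite denominator degrees of freedom; all pairwise muscle
#' contrasts are reported with Tukey family-wise adjustment (studentized
#' range on the muscle-term denominator df; `df_method` records this
#' approximation). Degenerate responses (zero variance) return F = 0, p = 1;
#' designs with fewer than two individuals fall back to a fixed-effects
#' model with a warning.
#'
#' @param y numeric response, one value per row of `metadata`.
#' @param metadata data.frame with `muscle` and `individual` columns.
#' @param weights optional positive per-observation weights.
#' @param contrasts compute pairwise muscle contrasts (default TRUE).
#' @param ranova also test the random effect by likelihood-ratio test.
#' @return object of class `muscle_lmm`: `F`, `p`, `num_df`, `den_df`,
#'   `contrasts` (data.frame), `varcomp`, `singular`, `degenerate`,
#'   `ranova_p` (if requested).
#' @export
fit_muscle_lmm <- function(y, metadata, weights = NULL, contrasts = TRUE,
                           ranova = FALSE) {
  stopifnot(length(y) == nrow(metadata),
            all(c("muscle", "individual") %in% colnames(metadata)))
  if (!is.null(weights) && any(weights <= 0))
    stop("weights must be positive")
  md <- data.frame(y = as.numeric(y),
                   muscle = factor(metadata$muscle,
                                   levels = unique(metadata$muscle)),
                   individual = factor(metadata$individual))
  lev <- levels(md$muscle)
  k <- length(lev)
  if (k < 2) stop("at least two muscles required")
  if (any(table(md$muscle) < 2)) stop("each muscle needs >= 2 observations")

  empty_contrasts <- function(est = 0, p = 1) {
    pairs <- utils::combn(lev, 2)
    data.frame(muscle1 = pairs[1, ], muscle2 = pairs[2, ],
               estimate = est, SE = NA_real_, t = NA_real_, p_adj = p,
               stringsAsFactors = FALSE)
  }
  if (var(md$y) == 0) {
    return(structure(list(F = 0, p = 1, num_df = k - 1, den_df = NA_real_,
                          contrasts = if (contrasts) empty_contrasts(),
                          varcomp = c(individual = 0, residual = 0),
                          singular = TRUE, degenerate = TRUE,
                          df_method = "degenerate", ranova_p = NA_real_),
                     class = "muscle_lmm"))
  }

  use_lmm <- length(unique(md$individual)) >= 2
  if (!use_lmm) {
    warning("fewer than 2 individuals; falling back to fixed-effects model")
    fit <- lm(y ~ muscle, data = md, weights = weights)
    a <- anova(fit)
    Fv <- a["muscle", "F value"]; pv <- a["muscle", "Pr(>F)"]
    den_df <- a["Residuals", "Df"]
    beta <- coef(fit); V <- vcov(fit)
    singular <- FALSE
    vc <- c(individual = NA_real_, residual = summary(fit)$sigma^2)
    ran_p <- NA_real_
    df_method <- "residual"
  } else {
    md$.w <- if (is.null(weights)) rep(1, nrow(md)) else weights
    fit <- suppressMessages(lmerTest::lmer(
      y ~ muscle + (1 | individual), data = md, weights = .w, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    a <- tryCatch(suppressMessages(anova(fit, ddf = "Satterthwaite")),
                  error = function(e) NULL)
    if (is.null(a) || !is.finite(a[["F value"]][1])) {
      a <- anova(fit, ddf = "Kenward-Roger")
    }
    Fv <- a[["F value"]][1]; pv <- a[["Pr(>F)"]][1]
    den_df <- a[["DenDF"]][1]
    beta <- lme4::fixef(fit); V <- as.matrix(vcov(fit))
    singular <- lme4::isSingular(fit)
    vcv <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(individual = vcv$vcov[vcv$grp == "individual"],
            residual = vcv$vcov[vcv$grp == "Residual"])
    ran_p <- if (ranova) {
      r <- lmerTest::ranova(fit)
      r[["Pr(>Chisq)"]][2]
    } else NA_real_
    df_method <- "satterthwaite"
  }

  ctab <- NULL
  if (contrasts) {
    ## estimated marginal means: intercept + treatment dummy per muscle
    emm <- c(0, beta[paste0("muscle", lev[-1])])
    names(emm) <- lev
    Xl <- cbind(0, rbind(0, diag(k - 1)))  # rows: muscles; cols: coef
    Xl[, 1] <- 1
    pairs <- utils::combn(seq_len(k), 2)
    est <- se <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      l <- Xl[pairs[1, j], ] - Xl[pairs[2, j], ]
      est[j] <- sum(l * beta)
      se[j] <- sqrt(drop(t(l) %*% V %*% l))
    }
    tval <- est / se
    dfc <- if (is.finite(den_df)) den_df else nrow(md) - k
    p_adj <- ptukey(abs(tval) * sqrt(2), nmeans = k, df = dfc,
                    lower.tail = FALSE)
    ctab <- data.frame(muscle1 = lev[pairs[1, ]], muscle2 = lev[pairs[2, ]],
                       estimate = est, SE = se, t = tval, p_adj = p_adj,
                       stringsAsFactors = FALSE)
  }

  structure(list(F = Fv, p = pv, num_df = k - 1, den_df = den_df,
                 contrasts = ctab, varcomp = vc, singular = singular,
                 degenerate = FALSE, df_method = df_method,
                 ranova_p = ran_p),
            class = "muscle_lmm")
}

#' Test cell-type scores for muscle differences
#'
#' Fits the atlas mixed model to each cell-type eigenvector score and applies
#' Benjamini-Hochberg FDR across the cell-type family. Pairwise muscle
#' contrasts are reported for cell types significant at `alpha`.
#'
#' @param eigen an `eigen_table` from [celltype_eigenvectors()].
#' @param metadata data.frame aligned to the score rows.
#' @param alpha FDR threshold for reporting contrasts (default 0.05).
#' @return list with `table` (cell_type, F, p, q, singular) and `contrasts`
#'   (named list for significant cell types) and `fits`.
#' @export
celltype_association <- function(eigen, metadata, alpha = 0.05) {
  stopifnot(inherits(eigen, "eigen_table"))
  sc <- eigen$scores
  stopifnot(nrow(sc) == nrow(metadata))
  fits <- lapply(colnames(sc), function(ct)
    fit_muscle_lmm(sc[, ct], metadata))
  names(fits) <- colnames(sc)
  tab <- data.frame(cell_type = colnames(sc),
                    F = vapply(fits, `[[`, numeric(1), "F"),
                    p = vapply(fits, `[[`, numeric(1), "p"),
                    singular = vapply(fits, `[[`, logical(1), "singular"),
                    stringsAsFactors = FALSE)
  tab$q <- p.adjust(tab$p, method = "BH")
  sig <- tab$cell_type[tab$q < alpha]
  list(table = tab[, c("cell_type", "F", "p", "q", "singular")],
       contrasts = lapply(setNames(sig, sig),
                          function(ct) fits[[ct]]$contrasts),
       fits = fits)
}

#' Cluster muscles by mean cell-type scores
#'
#' Averages the per-sample eigenvector scores within each muscle and
#' clusters muscles hierarchically (correlation distance, average linkage).
#'
#' @param eigen an `eigen_table`.
#' @param metadata data.frame aligned to the score rows, with a `muscle`
#'   column.
#' @return list with `means` (muscle x cell type matrix) and `dendrogram`
#'   (an `hclust`).
#' @export
cluster_muscles <- function(eigen, metadata) {
  stopifnot(inherits(eigen, "eigen_table"),
            nrow(eigen$scores) == nrow(metadata))
  sc <- eigen$scores
  muscles <- unique(metadata$muscle)
  means <- t(vapply(muscles, function(m)
    colMeans(sc[metadata$muscle == m, , drop = FALSE]),
    numeric(ncol(sc))))
  rownames(means) <- muscles
  C <- suppressWarnings(cor(t(means)))
  if (anyNA(C)) {
    ## rows with zero variance: identical rows get distance 0, others 1
    for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C)))
      if (is.na(C[i, j]))
        C[i, j] <- if (isTRUE(all.equal(means[i, ], means[j, ]))) 1 else 0
  }
  d <- as.dist(1 - C)
  list(means = means, dendrogram = hclust(d, method = "average"))
}
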