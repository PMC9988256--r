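test_that("eigenvector summaries behave like sign-oriented PC1 scores", {
  set.seed(20)
  n <- 40
  expr <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
  ## singleton set: scores equal the standardized gene itself
  et <- celltype_eigenvectors(expr, list(ct = "g1"))
  expect_equal(unname(et$scores[, "ct"]),
               unname(scale(expr["g1", ])[, 1]), tolerance = 1e-10)
  ## two perfectly correlated markers: variance explained 1
  expr2 <- rbind(a = expr["g1", ], b = 2 * expr["g1", ] + 3)
  et2 <- celltype_eigenvectors(expr2, list(ct = c("a", "b")))
  expect_equal(unname(et2$var_explained["ct"]), 1, tolerance = 1e-12)
  ## invariance to marker order and to sample order
  et3 <- celltype_eigenvectors(expr2, list(ct = c("b", "a")))
  expect_equal(et2$scores, et3$scores, tolerance = 1e-10)
  perm <- sample(n)
  et4 <- celltype_eigenvectors(expr2[, perm], list(ct = c("a", "b")))
  expect_equal(et4$scores[colnames(expr2), ], et2$scores[, 1],
               tolerance = 1e-10, ignore_attr = TRUE)
  ## sign rule: higher score means higher marker expression
  expect_gt(cor(et2$scores[, 1], rowMeans(scale(t(expr2)))), 0)
  expect_error(celltype_eigenvectors(expr, list(ct = "missing")), "marker")
})

test_that("eigen-scores track a planted fraction gradient closely", {
  set.seed(21)
  n <- 60
  frac <- runif(n)
  expr <- t(vapply(1:8, function(i) 2 * frac + rnorm(n, sd = 0.2),
                   numeric(n)))
  rownames(expr) <- paste0("m", 1:8)
  colnames(expr) <- paste0("s", 1:n)
  et <- celltype_eigenvectors(expr, list(ct = rownames(expr)))
  expect_gt(abs(cor(et$scores[, "ct"], frac)), 0.9)
})

test_that("the atlas mixed model handles degenerate and exact cases", {
  md <- expand.grid(individual = paste0("i", 1:6),
                    muscle = c("A", "B"), stringsAsFactors = FALSE)
  ## constant response
  fit0 <- fit_muscle_lmm(rep(1, nrow(md)), md)
  expect_equal(fit0$F, 0)
  expect_equal(fit0$p, 1)
  expect_true(all(fit0$contrasts$estimate == 0))
  expect_true(fit0$degenerate)
  ## complete pairing, no noise, delta = 1: exact recovery
  y <- as.numeric(factor(md$individual)) / 10 + (md$muscle == "B")
  fit1 <- suppressWarnings(suppressMessages(fit_muscle_lmm(y, md)))
  expect_equal(abs(fit1$contrasts$estimate), 1, tolerance = 1e-6)
  ## fewer than two individuals falls back to fixed effects with warning
  md1 <- data.frame(individual = "i1", muscle = rep(c("A", "B"), each = 4))
  expect_warning(fit2 <- fit_muscle_lmm(rnorm(8), md1), "individuals")
  expect_equal(fit2$df_method, "residual")
  expect_error(fit_muscle_lmm(rnorm(3), data.frame(
    individual = "i1", muscle = c("A", "B", "B"))), "observations")
})

test_that("two-muscle mixed-model p-values match the paired t-test", {
  md <- expand.grid(individual = paste0("i", 1:20),
                    muscle = c("A", "B"), stringsAsFactors = FALSE)
  set.seed(22)
  rel_err <- replicate(30, {
    u <- rnorm(20)
    y <- u[as.integer(factor(md$individual))] + 0.4 * (md$muscle == "B") +
      rnorm(40, sd = 0.8)
    fit <- fit_muscle_lmm(y, md, contrasts = FALSE)
    tt <- t.test(y[md$muscle == "B"] - y[md$muscle == "A"])$p.value
    abs(fit$p - tt) / tt
  })
  expect_lt(max(rel_err), 0.1)
})

test_that("manual Tukey contrasts agree with emmeans", {
  skip_if_not_installed("emmeans")
  fx <- fx_small()
  md <- fx$sim$metadata
  set.seed(23)
  y <- rnorm(nrow(md)) + 0.8 * (md$group == "G2")
  w <- runif(nrow(md), 0.5, 2)
  fit <- fit_muscle_lmm(y, md, weights = w)
  df <- data.frame(y = y, muscle = factor(md$muscle,
                                          levels = unique(md$muscle)),
                   individual = factor(md$individual), .w = w)
  ref <- lmerTest::lmer(y ~ muscle + (1 | individual), data = df,
                        weights = .w, REML = TRUE)
  em <- summary(emmeans::emmeans(ref, pairwise ~ muscle,
                                 lmer.df = "satterthwaite")$contrasts,
                adjust = "tukey")
  expect_equal(abs(fit$contrasts$estimate), abs(em$estimate),
               tolerance = 1e-6)
  expect_equal(fit$contrasts$SE, em$SE, tolerance = 1e-6)
  expect_equal(fit$contrasts$p_adj, em$p.value, tolerance = 0.02)
})

test_that("cell-type association is calibrated and permutation-sensitive", {
  ## null replicates: fraction of significant cell types stays near nominal
  prior <- matrix(20, 3, 4, dimnames = list(c("G1", "G2", "G3"), NULL))
  colnames(prior) <- paste0("ct", 1:4)
  hits <- 0; total <- 0
  for (s in 1:5) {
    params <- generative_params(n_genes = 120, n_celltypes = 4,
                                markers_per_celltype = 8,
                                celltype_fraction_prior = prior,
                                muscle_effect_sd = 0,
                                planted_modules = list(), n_de_genes = 0,
                                seed = 100 + s)
    sim <- simulate_bulk_counts(study_design(n_individuals = 10), params)
    lc <- cpm_log(sim$counts)
    et <- celltype_eigenvectors(lc, simulate_marker_sets(params))
    tab <- celltype_association(et, sim$metadata)$table
    hits <- hits + sum(tab$q < 0.05)
    total <- total + nrow(tab)
  }
  expect_lte(hits / total, 0.1)

  ## planted endothelial shift ranks that cell type highly; permuting
  ## muscle labels destroys significance
  fx <- fx_small()
  et <- celltype_eigenvectors(fx$logcpm, fx$markers)
  tab <- celltype_association(et, fx$sim$metadata)$table
  expect_lt(tab$q[tab$cell_type == "endothelial"], 0.05)
  set.seed(24)
  md_perm <- fx$sim$metadata
  md_perm$muscle <- sample(md_perm$muscle)
  tab_perm <- celltype_association(et, md_perm)$table
  expect_gt(median(tab_perm$q), 0.2)
})

test_that("muscle clustering recovers the three latent groups", {
  fx <- fx_default()
  et <- celltype_eigenvectors(cpm_log(fx$filt, fx$factors), fx$markers)
  cl <- cluster_muscles(et, fx$sim$metadata)
  expect_equal(dim(cl$means),
               c(length(fx$design$muscles), length(fx$markers)))
  k3 <- cutree(cl$dendrogram, k = 3)
  groups <- fx$design$group_map[names(k3)]
  ## the cut partitions muscles exactly as the latent groups
  expect_equal(length(unique(paste(k3, groups))), 3)
  ## identical muscles give a zero-height tree
  et0 <- et
  et0$scores <- matrix(rep(rnorm(ncol(et$scores)),
                           each = nrow(et$scores)),
                       nrow(et$scores),
                       dimnames = dimnames(et$scores))
  cl0 <- cluster_muscles(et0, fx$sim$metadata)
  expect_equal(max(abs(cl0$dendrogram$height)), 0, tolerance = 1e-12)
})
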