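test_that("biweight midcorrelation is exact on linear data and robust", {
  set.seed(40)
  x <- rnorm(20)
  m <- cbind(x = x, y = 2 * x + 3, z = -x)
  r <- bicor(m)
  expect_equal(r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(r["x", "z"], -1, tolerance = 1e-12)
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  ## one gross outlier: bicor stays closer to the clean Pearson value
  set.seed(41)
  a <- rnorm(20); b <- a + rnorm(20, sd = 0.3)
  clean <- cor(a, b)
  a_out <- a; a_out[1] <- 15
  contaminated <- cor(a_out, b)
  robust <- bicor(cbind(a = a_out, b = b))["a", "b"]
  expect_lt(abs(robust - clean), abs(contaminated - clean))
  expect_error(bicor(matrix(1:6, 3, 2)), "4 observations")
  ## zero-MAD column falls back to Pearson and is recorded
  mm <- cbind(const_mad = c(rep(0, 12), 1:8), v = rnorm(20))
  r2 <- bicor(mm)
  expect_true("const_mad" %in% attr(r2, "pearson_fallback"))
  expect_true(all(abs(r2) <= 1))
})

test_that("signed-hybrid adjacency zeroes negative correlations", {
  cm <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0.2, -0.3, 0.2, 1), 3)
  a <- adjacency_signed_hybrid(cm, 8)
  expect_equal(a[1, 2], 0.5^8, tolerance = 1e-15)
  expect_equal(a[1, 3], 0)
  a1 <- adjacency_signed_hybrid(cm, 1)
  expect_equal(a1[2, 3], 0.2)
  expect_equal(a1[1, 3], 0)
})

test_that("topological overlap matches hand computation and the oracle", {
  ## three nodes, one unit edge
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1; diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1)
  expect_equal(tom[1, 3], 0)
  expect_equal(tom[2, 3], 0)
  ## complete graph: all off-diagonal overlap 1
  full <- matrix(1, 4, 4)
  expect_true(all(tom_similarity(full) == 1))
  ## random instances match the brute-force double loop
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    a <- random_adjacency(n)
    expect_equal(tom_similarity(a), oracle_tom(a), tolerance = 1e-12)
  }
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("consensus calibration is an identity on identical inputs", {
  set.seed(43)
  a <- random_adjacency(12)
  tom <- tom_similarity(a)
  cons <- consensus_tom(list(tom, tom, tom))
  expect_equal(cons, tom, tolerance = 1e-12)
  ## order invariance
  b <- tom_similarity(random_adjacency(12))
  c3 <- tom_similarity(random_adjacency(12))
  expect_equal(consensus_tom(list(tom, b, c3)),
               consensus_tom(list(c3, tom, b)), tolerance = 1e-12)
  expect_error(consensus_tom(list(tom)), "2")
  zero <- tom; zero[upper.tri(zero)] <- 0; zero[lower.tri(zero)] <- 0
  expect_error(consensus_tom(list(zero, zero)), "quantile")
})

test_that("tree cut finds planted blocks and rejects featureless noise", {
  set.seed(44)
  ## planted blocks across replicates
  for (r in 1:3) {
    n <- 40
    z1 <- rnorm(n); z2 <- rnorm(n)
    blk <- function(z) vapply(1:50, function(i)
      sqrt(0.8) * z + sqrt(0.2) * rnorm(n), numeric(n))
    x <- cbind(blk(z1), blk(z2), matrix(rnorm(n * 60), n))
    colnames(x) <- paste0("g", seq_len(ncol(x)))
    truth <- rep(c("A", "B", "none"), c(50, 50, 60))
    tom <- tom_similarity(adjacency_signed_hybrid(bicor(x), 8))
    asg <- cut_modules(1 - tom, network_params())
    skip_if_not_installed("mclust")
    expect_gt(mclust::adjustedRandIndex(asg, truth), 0.9)
    ## relabeling genes permutes assignments identically
    perm <- sample(ncol(x))
    asg_p <- cut_modules((1 - tom)[perm, perm], network_params())
    expect_equal(unname(asg_p[names(asg)] == "unassigned"),
                 unname(asg == "unassigned"))
  }
  ## pure noise: at least 80% unassigned
  unass <- replicate(5, {
    x <- matrix(rnorm(100 * 40), 40, 100,
                dimnames = list(NULL, paste0("g", 1:100)))
    tom <- tom_similarity(adjacency_signed_hybrid(bicor(x), 8))
    mean(cut_modules(1 - tom, network_params()) == "unassigned")
  })
  expect_true(all(unass >= 0.8))
  ## fewer genes than the minimum module size: everything unassigned
  tiny <- tom_similarity(random_adjacency(5))
  expect_true(all(cut_modules(1 - tiny, network_params()) == "unassigned"))
})

test_that("module eigengenes summarize members and track planted factors", {
  set.seed(45)
  n <- 30
  prof <- rnorm(n)
  expr <- rbind(matrix(rep(prof, 5), 5, byrow = TRUE),
                matrix(rnorm(3 * n), 3))
  rownames(expr) <- paste0("g", 1:8)
  colnames(expr) <- paste0("s", 1:n)
  asg <- setNames(c(rep("M1", 5), rep("unassigned", 3)), rownames(expr))
  me <- module_eigengenes(expr, asg)
  expect_equal(unname(me$var_explained["M1"]), 1, tolerance = 1e-12)
  expect_equal(unname(me$scores[, "M1"]), unname(scale(prof)[, 1]),
               tolerance = 1e-9)
  ## member order invariance
  me2 <- module_eigengenes(expr[sample(8), ], asg)
  expect_equal(me2$scores, me$scores, tolerance = 1e-9)
  ## detected modules on the default atlas track the planted latent factors
  fx <- fx_default()
  mod <- fx_default_modules()
  truth_lab <- fx$sim$truth$module_labels
  factors <- fx$sim$truth$module_factors
  for (mo in colnames(mod$me$scores)) {
    genes <- names(mod$assignment)[mod$assignment == mo]
    planted <- names(which.max(table(truth_lab[genes])))
    z <- factors[planted, rownames(mod$me$scores)]
    expect_gt(abs(cor(mod$me$scores[, mo], z)), 0.9)
  }
})

test_that("eigengene merging respects the dissimilarity threshold", {
  set.seed(46)
  n <- 40
  z <- rnorm(n)
  near <- function(r) sqrt(r) * z + sqrt(1 - r) * rnorm(n)
  expr <- rbind(
    t(vapply(1:25, function(i) z + rnorm(n, sd = 0.2), numeric(n))),
    t(vapply(1:25, function(i) near(0.95) + rnorm(n, sd = 0.2),
             numeric(n))),
    t(vapply(1:25, function(i) -z + rnorm(n, sd = 0.2), numeric(n))))
  rownames(expr) <- paste0("g", 1:75)
  colnames(expr) <- paste0("s", 1:n)
  asg <- setNames(rep(c("M1", "M2", "M3"), each = 25), rownames(expr))
  merged <- merge_modules(expr, asg, merge_cut_height = 0.2)
  ## highly correlated M1/M2 merged; anticorrelated M3 kept separate
  expect_equal(merged$assignment[paste0("g", 1)],
               merged$assignment[paste0("g", 26)], ignore_attr = TRUE)
  expect_false(merged$assignment[[1]] == merged$assignment[[51]])
  expect_equal(length(unique(merged$assignment)), 2)
  ## idempotent
  again <- merge_modules(expr, merged$assignment, 0.2)
  expect_identical(again$assignment, merged$assignment)
})

test_that("intramodular connectivity identifies hubs and conserves mass", {
  ## star topology: the center has maximal within-module connectivity
  n <- 6
  a <- matrix(0, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  a[1, 2:n] <- a[2:n, 1] <- 0.9
  diag(a) <- 1
  asg <- setNames(c(rep("M1", n)), rownames(a))
  ct <- intramodular_connectivity(a, asg, hub_fraction = 0.2)
  expect_equal(ct$gene[which.max(ct$k_within)], "g1")
  expect_true(ct$hub[ct$gene == "g1"])
  ## unassigned genes are absent
  asg2 <- asg; asg2["g6"] <- "unassigned"
  ct2 <- intramodular_connectivity(a, asg2)
  expect_false("g6" %in% ct2$gene)
  ## sum of kWithin equals twice the within-module adjacency mass
  set.seed(47)
  b <- random_adjacency(10)
  dimnames(b) <- list(paste0("g", 1:10), paste0("g", 1:10))
  asg3 <- setNames(rep(c("M1", "M2"), each = 5), rownames(b))
  ct3 <- intramodular_connectivity(b, asg3)
  for (mo in c("M1", "M2")) {
    g <- names(asg3)[asg3 == mo]
    sub <- b[g, g]; diag(sub) <- 0
    expect_equal(sum(ct3$k_within[ct3$module == mo]), sum(sub),
                 tolerance = 1e-12)
  }
})

test_that("enrichment factor classifies gene pairs exactly", {
  ## six-gene worked configuration
  asg <- setNames(c("A", "A", "A", "B", "B", "B"), paste0("g", 1:6))
  pw <- list(P1 = paste0("g", c(1, 2, 4)), P2 = paste0("g", c(3, 5, 6)))
  ef <- enrichment_factor(asg, pw)
  counts <- oracle_ef(asg, pw)
  expect_equal(c(ef$n1, ef$n2, ef$n3, ef$n4), unname(counts))
  expect_equal(ef$EF, 0.625)
  expect_equal(ef$n1 + ef$n2 + ef$n3 + ef$n4, choose(6, 2))
  ## pathways identical to modules: infinite enrichment flag
  pw_id <- list(P1 = paste0("g", 1:3), P2 = paste0("g", 4:6))
  ef_id <- enrichment_factor(asg, pw_id)
  expect_true(ef_id$infinite)
  expect_equal(ef_id$EF, Inf)
  ## random pathway assignment: mean EF near 1
  set.seed(48)
  genes <- paste0("g", 1:60)
  asg2 <- setNames(rep(c("A", "B", "C"), each = 20), genes)
  efs <- replicate(50, {
    lab <- sample(rep(c("P1", "P2", "P3"), each = 20))
    enrichment_factor(asg2, split(genes, lab))$EF
  })
  expect_equal(mean(efs), 1, tolerance = 0.25)
})

test_that("parameter sweep returns a full grid and honours single points", {
  fx <- fx_small()
  pw <- simulate_knowledge_network(fx$sim$truth, 0)
  expr <- fx_small_de()$voom$expr
  sw <- parameter_sweep(expr[1:300, ], fx$sim$metadata, pw,
                        powers = 8, min_sizes = 20, deep_splits = 0,
                        cut_heights = 0.2)
  expect_equal(nrow(sw$results), 1)
  expect_equal(sw$best$power, 8)
  expect_equal(sw$best$merge_cut_height, 0.2)
})

test_that("module-muscle association flags planted group factors", {
  fx <- fx_default()
  mod <- fx_default_modules()
  assoc <- module_muscle_association(mod$me, fx$sim$metadata)
  truth_lab <- fx$sim$truth$module_labels
  ## the two group-shifted planted factors must be muscle-related
  shifted <- c("planted_1", "planted_2")
  for (mo in assoc$table$module) {
    genes <- names(mod$assignment)[mod$assignment == mo]
    planted <- names(which.max(table(truth_lab[genes])))
    if (planted %in% shifted)
      expect_true(assoc$table$muscle_related[assoc$table$module == mo])
  }
  expect_true(all(c("ranova_p", "q") %in% colnames(assoc$table)))
  ## a constant eigengene is never muscle-related
  me0 <- mod$me
  me0$scores <- cbind(me0$scores, flat = 0)
  assoc0 <- module_muscle_association(me0, fx$sim$metadata)
  expect_false(assoc0$table$muscle_related[assoc0$table$module == "flat"])
})

test_that("cell-type module flag needs five markers of a single type", {
  markers <- list(endo = paste0("e", 1:10), immune = paste0("i", 1:10))
  asg <- setNames(c(rep("M1", 10), rep("M2", 10)),
                  c(paste0("e", 1:5), paste0("x", 1:5),
                    paste0("e", 6:9), paste0("i", 1:4), paste0("y", 1:2)))
  out <- flag_celltype_modules(asg, markers, min_markers = 5)
  expect_true(out$celltype_flagged[out$module == "M1"])
  expect_equal(out$celltype[out$module == "M1"], "endo")
  ## 4 + 4 markers of two different types do not flag
  expect_false(out$celltype_flagged[out$module == "M2"])
  out2 <- flag_celltype_modules(asg, list())
  expect_true(all(!out2$celltype_flagged))
})

test_that("top-module selection applies the strict F-quartile rule", {
  f <- setNames(c(rep(10, 8), rep(5.5, 8), c(1, 2, 3, 10, 10, 10, 10, 10)),
                paste0("g", 1:24))
  asg <- setNames(rep(c("M1", "M2", "M3"), each = 8), paste0("g", 1:24))
  expect_warning(out <- select_top_modules(f, asg), "skipped")
  expect_true(out$selected[out$module == "M1"])
  ## third quartile exactly at the threshold is not selected
  expect_false(out$selected[out$module == "M2"])
  expect_equal(out$q3_f[out$module == "M3"],
               quantile(f[17:24], 0.75, names = FALSE))
  ## annotation q gate when provided
  out2 <- select_top_modules(f, asg,
                             annotation_q = c(M1 = 0.5, M2 = 0.001,
                                              M3 = 0.001))
  expect_false(out2$selected[out2$module == "M1"])
  expect_true(out2$selected[out2$module == "M3"])
})
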