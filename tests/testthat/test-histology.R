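test_that("myofiber percentile filters fire at the documented rates", {
  set.seed(50)
  n <- 4000
  obj <- data.frame(object_id = sprintf("o%05d", 1:n),
                    sample_id = rep(paste0("s", 1:4), each = n / 4),
                    section_id = "sec_1",
                    muscle = rep(c("GR", "VL"), each = n / 2),
                    area_um2 = rlnorm(n, 8, 0.4),
                    circularity = runif(n, 0.3, 1),
                    mfi_myhc1 = 1, mfi_myhc2a = 1, mfi_myhc2x = 1,
                    boundary_certainty = runif(n),
                    interior_certainty = runif(n))
  res <- filter_myofibers(obj)
  led <- res$ledger
  expect_equal(nrow(res$objects) + nrow(led), n)
  expect_equal(sum(led$boundary) / n, 0.05, tolerance = 0.01)
  expect_equal(sum(led$interior) / n, 0.05, tolerance = 0.01)
  expect_equal(sum(led$csa) / n, 0.11, tolerance = 0.015)
  expect_equal(sum(led$circularity) / n, 0.01, tolerance = 0.006)
})

test_that("filter boundaries are strict and degenerate features inert", {
  ## evenly spaced boundary certainties 0..100: the 5th percentile value is
  ## attained exactly and must be retained (strict less-than)
  obj <- make_objects(101)
  obj$boundary_certainty <- 0:100
  obj$interior_certainty <- 0.5
  obj$circularity <- 0.9
  obj$area_um2 <- 1000
  res <- filter_myofibers(obj)
  expect_false(obj$object_id[obj$boundary_certainty == 5] %in%
                 res$ledger$object_id)
  expect_true(all(obj$object_id[obj$boundary_certainty < 5] %in%
                    res$ledger$object_id))
  ## all-identical objects: nothing excluded
  same <- make_objects(50)
  same$area_um2 <- 1000; same$circularity <- 0.9
  same$boundary_certainty <- 0.8; same$interior_certainty <- 0.2
  expect_equal(nrow(filter_myofibers(same)$ledger), 0)
  expect_error(filter_myofibers(make_objects(5)[0, ]), "empty")
})

test_that("section selection keeps the largest section and a 100-fiber floor", {
  a <- make_objects(120, sample_id = "s1", section_id = "sec_1")
  b <- make_objects(80, sample_id = "s1", section_id = "sec_2")
  b$object_id <- paste0("b", b$object_id)
  sel <- select_section(rbind(a, b))
  expect_equal(sel$sections$section_id, "sec_1")
  expect_true(sel$sections$included)
  ## 99 fibers in the best section excludes the sample
  sel99 <- select_section(make_objects(99))
  expect_false(sel99$sections$included)
  ## exactly 100 fibers is included
  sel100 <- select_section(make_objects(100))
  expect_true(sel100$sections$included)
  ## ties broken by section identifier order
  t1 <- make_objects(120, section_id = "sec_2")
  t2 <- make_objects(120, section_id = "sec_1")
  t2$object_id <- paste0("t", t2$object_id)
  expect_equal(select_section(rbind(t1, t2))$sections$section_id, "sec_1")
})

test_that("mean-shift typing recovers planted clusters and proportions", {
  myo <- simulate_myofiber_objects(n_samples = 10,
                                   n_fibers_per_sample = 300, seed = 51)
  filt <- filter_myofibers(myo$objects)
  sel <- select_section(filt$objects)
  ft <- fiber_type_clustering(sel$objects)
  expect_equal(ncol(ft$proportions), 3)
  truth <- myo$truth[match(sel$objects$object_id, myo$objects$object_id)]
  for (s in rownames(ft$proportions)) {
    i <- sel$objects$sample_id == s
    tp <- sort(vapply(1:3, function(k) sum(truth[i] == k) / sum(i),
                      numeric(1)), decreasing = TRUE)
    dp <- sort(ft$proportions[s, ], decreasing = TRUE)
    expect_lt(max(abs(dp - tp)), 0.02)
  }
  ## labels invariant to a per-sample intensity rescaling
  obj2 <- sel$objects
  i <- obj2$sample_id == obj2$sample_id[1]
  mfi_cols <- grep("^mfi_", colnames(obj2))
  obj2[i, mfi_cols] <- obj2[i, mfi_cols] * 2
  ft2 <- fiber_type_clustering(obj2)
  expect_identical(ft$labels, ft2$labels)
  ## labels invariant to object order
  perm <- sample(nrow(sel$objects))
  ft3 <- fiber_type_clustering(sel$objects[perm, ])
  expect_identical(ft3$labels, ft$labels[perm])
})

test_that("single-cluster data yields one cluster with proportion 1", {
  myo <- simulate_myofiber_objects(
    n_samples = 4, n_fibers_per_sample = 200,
    cluster_centers = matrix(c(5000, 5000, 5000), 1),
    cluster_weights = 1, contamination_rate = 0, seed = 52)
  ## a wide bandwidth relative to the single blob: one mode survives
  ft <- fiber_type_clustering(myo$objects,
                              fiber_typing_params(bandwidth = 0.3))
  expect_equal(ncol(ft$proportions), 1)
  expect_true(all(abs(ft$proportions - 1) < 1e-12))
})

test_that("capillary scoring applies the three rules strictly", {
  toy <- data.frame(object_id = paste0("v", 1:5), sample_id = "s1",
                    section_id = "sec",
                    area_um2 = c(10, 2, 60, 20, 10),
                    circularity = c(0.8, 0.9, 0.9, 0.3, 0.8),
                    cd31_pos = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                    eng_pos = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- capillary_metrics(toy, c(sec = 1e5))
  expect_equal(out$n_capillaries, 1)
  expect_equal(out$capillary_density, 1e-5)
  ## CD31-positive area fraction counts every CD31+ object
  expect_equal(out$cd31_area_pct, 100 * sum(toy$area_um2) / 1e5)
  ## area exactly 3 is not a capillary (strict larger-than)
  edge <- toy[1, ]; edge$area_um2 <- 3
  expect_equal(capillary_metrics(edge, 1e5)$n_capillaries, 0)
  ## empty table with explicit samples scores zero
  empty <- toy[0, ]
  out0 <- capillary_metrics(empty, 1e5, samples = "s1")
  expect_equal(out0$capillary_density, 0)
  expect_equal(out0$cd31_area_pct, 0)
  ## row-by-row oracle on random tables
  set.seed(53)
  for (r in 1:5) {
    n <- sample(5:20, 1)
    tab <- data.frame(object_id = paste0("v", 1:n), sample_id = "s1",
                      section_id = "sec",
                      area_um2 = runif(n, 0, 80),
                      circularity = runif(n),
                      cd31_pos = runif(n) < 0.7,
                      eng_pos = runif(n) < 0.7)
    want <- sum(mapply(function(a, c, p1, p2)
      p1 && p2 && a > 3 && a < 51 && c > 0.5,
      tab$area_um2, tab$circularity, tab$cd31_pos, tab$eng_pos))
    expect_equal(capillary_metrics(tab, 1e6)$n_capillaries, want)
  }
})

test_that("foci scoring applies the geometric and control rules strictly", {
  toy <- data.frame(object_id = paste0("f", 1:3), sample_id = "s1",
                    fiber_id = c(1, 1, 2),
                    area_um2 = c(1.0, 3.4, 3.6),
                    circularity = c(0.99, 0.97, 0.99),
                    intensity = c(100, 100, 100))
  out <- foci_metrics(toy, c(s1 = 2))
  expect_equal(out$avg_foci_per_fiber, 0.5)
  ## circularity exactly 0.98 is rejected (strict above)
  edge <- toy[1, ]; edge$circularity <- 0.98
  expect_equal(foci_metrics(edge, c(s1 = 2))$n_foci, 0)
  ## a negative control containing the brightest test foci silences all
  ctrl <- toy; ctrl$intensity <- 200
  out_ctrl <- foci_metrics(toy, c(s1 = 2), negative_control = ctrl)
  expect_equal(out_ctrl$avg_foci_per_fiber, 0)
  expect_error(foci_metrics(toy, c(s1 = 0)), "positive")
  ## row-by-row oracle
  set.seed(54)
  for (r in 1:5) {
    n <- sample(5:20, 1)
    tab <- data.frame(object_id = paste0("f", 1:n), sample_id = "s1",
                      fiber_id = sample(5, n, TRUE),
                      area_um2 = runif(n, 0, 6),
                      circularity = runif(n, 0.9, 1),
                      intensity = rlnorm(n, 4, 1))
    want <- sum(tab$area_um2 < 3.5 & tab$circularity > 0.98)
    expect_equal(foci_metrics(tab, c(s1 = 10))$n_foci, want)
  }
})

test_that("group comparison of histology metrics detects planted effects", {
  md <- expand.grid(individual = paste0("i", 1:19),
                    muscle = c("VL", "GL"), stringsAsFactors = FALSE)
  ## identical values: p = 1
  same <- compare_group_metric(rep(0.3, nrow(md)), md)
  expect_equal(same$p, 1)
  ## planted two-fold density difference, paired design
  set.seed(55)
  hits <- replicate(10, {
    base <- rlnorm(19, log(4e-4), 0.25)
    y <- c(base, 2 * base) * rlnorm(38, 0, 0.15)
    compare_group_metric(y, md)$p < 0.01
  })
  expect_gte(mean(hits), 0.9)
  ## contrasts are antisymmetric under pair swap (reversed level order)
  y <- rnorm(nrow(md)) + (md$muscle == "GL")
  f1 <- compare_group_metric(y, md)
  rev_idx <- rev(seq_len(nrow(md)))
  f2 <- compare_group_metric(y[rev_idx], md[rev_idx, ])
  expect_equal(f2$contrasts$estimate, -f1$contrasts$estimate,
               tolerance = 1e-8)
})
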