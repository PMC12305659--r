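test_that("the default plate map honours the screening layout", {
  pm <- synth_plate_map()
  expect_equal(nrow(pm), 384)
  expect_identical(validate_plate_map(pm), pm)
  row_of <- substr(pm$well, 1, 1)
  col_of <- as.integer(substring(pm$well, 2))
  # edge rows/columns are vehicle
  edge <- row_of %in% c("A", "B", "O", "P") | col_of %in% c(1, 24)
  expect_true(all(pm$kind[edge] == "vehicle"))
  expect_true(all(is.na(pm$concentration[pm$kind == "vehicle"])))
  # positive-control columns: 12-point 2-fold series per compound
  for (pc in c("brefeldin_a", "etoposide")) {
    conc <- pm$concentration[!is.na(pm$treatment_id) & pm$treatment_id == pc]
    expect_length(conc, 12)
    expect_equal(conc[1] / conc[12], 2^11)
    expect_equal(unique(round(conc[-12] / conc[-1], 10)), 2)
  }
  # each sample treatment: 4-point 2-fold dilution
  for (t in unique(na.omit(pm$treatment_id[pm$kind == "sample"]))) {
    conc <- sort(pm$concentration[pm$kind == "sample" &
                                    pm$treatment_id == t], decreasing = TRUE)
    expect_length(conc, 4)
    expect_equal(conc, conc[1] / c(1, 2, 4, 8))
  }
})

test_that("plate-map validation names the offending well", {
  pm <- synth_plate_map()
  bad <- pm
  bad$well[5] <- "Q9"
  expect_error(validate_plate_map(bad), "Q9")
  dup <- pm
  dup$well[2] <- pm$well[1]
  expect_error(validate_plate_map(dup), pm$well[1])
  expect_error(synth_cell_tables(pm, synth_ground_truth(4, "T01", "T01",
                                                        n_classes = 1),
                                 n_features = 4, wells = "Z1"), "Z1")
})

test_that("generators are deterministic and well-subset independent", {
  pm <- synth_plate_map(treatments = c("T01", "T02"))
  gt <- synth_ground_truth(6, c("T01", "T02"), active = "T01",
                           n_classes = 1, n_affected = 3, seed = 2)
  wells <- c("A3", "A4", pm$well[pm$kind == "sample"][1:4])
  a <- synth_cell_tables(pm, gt, n_features = 6, n_cells = 50, seed = 9,
                         wells = wells)
  b <- synth_cell_tables(pm, gt, n_features = 6, n_cells = 50, seed = 9,
                         wells = wells)
  expect_identical(a, b)
  # a well's content does not depend on which other wells are generated
  solo <- synth_cell_tables(pm, gt, n_features = 6, n_cells = 50, seed = 9,
                            wells = wells[3])
  expect_identical(solo$cells[[wells[3]]], a$cells[[wells[3]]])
  # different seed changes the draw
  c2 <- synth_cell_tables(pm, gt, n_features = 6, n_cells = 50, seed = 10,
                          wells = wells)
  expect_false(identical(a$cells, c2$cells))

  ms1 <- synth_ms_features(paste0("S", 1:6), 20,
                           list(m = c("S1", "S2")), seed = 3)
  ms2 <- synth_ms_features(paste0("S", 1:6), 20,
                           list(m = c("S1", "S2")), seed = 3)
  expect_identical(ms1, ms2)
  lib1 <- synth_reference_library(12, 3, seed = 4)
  expect_identical(lib1, synth_reference_library(12, 3, seed = 4))
})

test_that("null-effect treatments are indistinguishable from vehicle (KS)", {
  pm <- synth_plate_map(treatments = "T01")
  gt <- synth_ground_truth(6, "T01", active = character(0), n_classes = 1,
                           seed = 42)
  t_wells <- pm$well[pm$kind == "sample"][1:2]
  ct <- synth_cell_tables(pm, gt, n_features = 6, n_cells = 500, seed = 42,
                          wells = c("A3", "A4", "A5", t_wells))
  veh <- do.call(rbind, ct$cells[c("A3", "A4", "A5")])
  trt <- do.call(rbind, ct$cells[t_wells])
  for (j in 1:6) {
    p <- suppressWarnings(ks.test(trt[, j], veh[, j]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("a +3 SD planted effect surfaces in HistDiff exactly on its features", {
  # oracle: expected |score| for a 3 SD Gaussian shift is
  # 2 * (1 - overlap), overlap = integral of min(N(0,1), N(3,1)) = 2*pnorm(-1.5)
  oracle <- 2 * (1 - 2 * pnorm(-1.5))
  pm <- synth_plate_map(treatments = "T01")
  veh_wells <- c("A3", "A4", "A5", "A6")
  med <- sapply(1:20, function(r) {
    gt <- synth_ground_truth(20, "T01", active = "T01", n_classes = 1,
                             n_affected = 20, effect_size = 3,
                             potency_range = c(1, 1), ec50 = 1e-9, seed = r)
    # force the effect onto features 1..10 only
    e <- numeric(20); e[1:10] <- 3
    gt$effects[["T01"]] <- e
    w <- pm$well[pm$kind == "sample"][1] # top concentration well
    ct <- synth_cell_tables(pm, gt, n_features = 20, n_cells = 300,
                            seed = r, wells = c(veh_wells, w),
                            heavy_tails = FALSE)
    histdiff_normalize(ct$cells[[w]],
                       do.call(rbind, ct$cells[veh_wells]))
  })
  med <- apply(abs(med), 1, median)
  expect_setequal(which(med > 0.5), 1:10)
  expect_equal(unname(median(med[1:10])), oracle, tolerance = 0.35)
})

test_that("synthetic MS features reproduce the planted incidence", {
  samples <- paste0("S", 1:8)
  act <- list(m1 = c("S1", "S2", "S3"), m2 = c("S4", "S5"))
  ms <- synth_ms_features(samples, 15, act, background_cardinality = 3,
                          background_rate = 0, seed = 6)
  tab <- ms$table
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$rt >= 0 & tab$rt <= 11))
  expect_true(all(tab$mz >= 50 & tab$mz <= 1500))
  expect_false(anyDuplicated(tab$feature_id) > 0)
  # with zero background rate the detection matrix equals the ground truth
  mat <- as.matrix(tab[, samples]) > 0
  rownames(mat) <- tab$feature_id
  expect_identical(unname(mat), unname(ms$incidence))
  expect_identical(colnames(mat)[mat[ms$active_ids[["m1"]], ]],
                   c("S1", "S2", "S3"))
  # background rows have the stated cardinality
  bg <- setdiff(tab$feature_id, ms$active_ids)
  expect_true(all(rowSums(mat[bg, ]) == 3))
  # false-presence rate adds, never removes
  ms2 <- synth_ms_features(samples, 15, act, background_cardinality = 3,
                           background_rate = 0.5, seed = 6)
  expect_true(all(ms2$incidence[ms$incidence]))
  expect_gt(sum(ms2$incidence), sum(ms$incidence))

  expect_error(synth_ms_features(samples, 1, act), "smaller")
  expect_error(synth_ms_features(samples, 15, list(m1 = "S1")), ">= 2")
  expect_error(synth_ms_features(samples, 15, list(m1 = c("S1", "ZZ"))),
               "unknown samples")
})

test_that("reference-library fingerprints respect their class structure", {
  # one class: all pairwise Pearson correlations share a common positive mean
  lib1 <- synth_reference_library(10, 1, n_features = 40, seed = 3)
  rho <- cor(t(lib1$fingerprints))
  expect_gt(mean(rho[upper.tri(rho)]), 0.5)
  # zero within-class noise: identical fingerprints per class
  lib0 <- synth_reference_library(9, 3, noise = 0, seed = 3)
  for (k in unique(lib0$labels)) {
    fp <- lib0$fingerprints[names(lib0$labels)[lib0$labels == k], ,
                            drop = FALSE]
    expect_equal(max(apply(fp, 2, function(col) diff(range(col)))), 0)
  }
  expect_error(synth_reference_library(2, 5), "n_moa_classes")
})

test_that("cell tables and plate maps round-trip through CSV", {
  pm <- synth_plate_map()
  p1 <- file.path(tempdir(), "pm.csv")
  write_plate_map(pm, p1)
  expect_equal(read_plate_map(p1), pm)
  gt <- synth_ground_truth(3, "T01", "T01", n_classes = 1, seed = 1)
  ct <- synth_cell_tables(pm, gt, n_features = 3, n_cells = 20, seed = 1,
                          wells = c("A3", "C3"))
  p2 <- file.path(tempdir(), "cells.csv")
  write_cell_tables(ct$cells, p2)
  back <- read_cell_tables(p2)
  expect_setequal(names(back), names(ct$cells))
  for (w in names(back))
    expect_equal(unname(back[[w]]), unname(ct$cells[[w]]), tolerance = 1e-12)
})
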