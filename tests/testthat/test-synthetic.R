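test_that("identical params and seed give bit-identical output", {
  p <- synthetic_params(n_genes = 800, n_groups = 3, units_per_group = 50,
                        markers_per_group = 20, seed = 5)
  a <- generate_st(p)
  b <- generate_st(p)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$positions, b$positions)
  sa <- generate_sc(p)
  sb <- generate_sc(p)
  expect_identical(as.matrix(sa$counts$counts), as.matrix(sb$counts$counts))
  expect_identical(sa$truth$phase, sb$truth$phase)
})

test_that("low-quality construction is exact for spots", {
  p <- synthetic_params(n_genes = 800, n_groups = 2, units_per_group = 50,
                        markers_per_group = 20, frac_low_quality = 0.1, seed = 3)
  st <- generate_st(p)
  det <- detected_genes(st$counts)
  expect_identical(sum(det < 200), 10L)                 # exactly 10% of 100
  expect_identical(unname(det < 200), unname(st$truth$low_quality))
  expect_true(all(det[!st$truth$low_quality] >= 200))
})

test_that("low-quality cells split half mito, half low-gene, exactly", {
  p <- synthetic_params(n_genes = 800, n_groups = 5, units_per_group = 100,
                        markers_per_group = 20, frac_low_quality = 0.2, seed = 3)
  sc <- generate_sc(p)
  expect_identical(sum(sc$truth$low_quality), 100L)
  expect_identical(sum(sc$truth$failure_mode == "mito"), 50L)
  expect_identical(sum(sc$truth$failure_mode == "low_genes"), 50L)
  mf <- mito_fraction(sc$counts)
  det <- detected_genes(sc$counts)
  expect_true(all(mf[sc$truth$failure_mode == "mito"] > 0.2))
  expect_true(all(det[sc$truth$failure_mode == "low_genes"] < 200))
  healthy <- sc$truth$failure_mode == "none"
  expect_true(all(det[healthy] >= 200))
  expect_true(all(mf[healthy] <= 0.2))
})

test_that("planted markers carry roughly the stated fold change in their region", {
  p <- synthetic_params(seed = 17)                      # defaults: fold 4, 200/group
  st <- generate_st(p)
  counts <- as.matrix(st$counts$counts)
  grp <- st$truth$group
  ratios <- unlist(lapply(1:2, function(g) {
    markers <- st$truth$marker_sets[[g]]$genes[1:10]
    vapply(markers, function(m) {
      mean(counts[m, grp == g]) / mean(counts[m, grp != g])
    }, numeric(1))
  }))
  expect_true(all(abs(ratios / p$marker_fold_change - 1) < 0.25))
})

test_that("marker means exceed outside means for modest folds (property)", {
  frac_ok <- unlist(lapply(1:5, function(s) {
    p <- synthetic_params(n_genes = 800, n_groups = 3, units_per_group = 100,
                          markers_per_group = 20, marker_fold_change = 2,
                          frac_low_quality = 0, seed = s)
    st <- generate_st(p)
    counts <- as.matrix(st$counts$counts)
    grp <- st$truth$group
    unlist(lapply(1:3, function(g) {
      m <- st$truth$marker_sets[[g]]$genes
      rowMeans(counts[m, grp == g]) > rowMeans(counts[m, grp != g])
    }))
  }))
  expect_gte(mean(frac_ok), 0.99)
})

test_that("marker sets are disjoint and every unit has one group label", {
  p <- quick_params(seed = 2)
  st <- generate_st(p)
  all_markers <- unlist(lapply(st$truth$marker_sets, `[[`, "genes"))
  expect_identical(anyDuplicated(all_markers), 0L)
  expect_identical(length(st$truth$group), ncol(st$counts$counts))
  expect_false(any(is.na(st$truth$group)))
})

test_that("a G1-only phase mix plants no elevated cycle expression", {
  p <- synthetic_params(seed = 4, phase_frac = c(G1 = 1, S = 0, G2M = 0),
                        n_groups = 3, units_per_group = 80,
                        frac_low_quality = 0)
  sc <- generate_sc(p)
  expect_true(all(sc$truth$phase == "G1"))
  nm <- normalize_counts(sc$counts)
  sets <- default_cell_cycle_sets()
  sc_scores <- cc_scores(nm, sets$G1S, sets$G2M)
  expect_true(all(sc_scores$s_g1s < 2))
  expect_true(all(sc_scores$s_g2m < 2))
})

test_that("G1 cells score below the classification threshold on both sets", {
  p <- synthetic_params(seed = 9)
  sc <- generate_sc(p)
  nm <- normalize_counts(apply_qc(sc$counts))
  sets <- default_cell_cycle_sets()
  calls <- cc_scores(nm, sets$G1S, sets$G2M)
  g1 <- sc$truth$phase[calls$unit_id] == "G1"
  below <- calls$s_g1s[g1] < 2 & calls$s_g2m[g1] < 2
  expect_gte(mean(below), 0.95)
})

test_that("generator output round-trips through the file formats", {
  p <- quick_params(seed = 6, units_per_group = 20)
  st <- generate_st(p)
  dir <- withr::local_tempdir()
  paths <- write_counts(st$counts, dir)
  back <- read_counts(paths[["matrix"]], paths[["genes"]], paths[["barcodes"]],
                      unit_kind = "spot")
  expect_identical(as.matrix(back$counts), as.matrix(st$counts$counts))

  posf <- file.path(dir, "positions.csv")
  utils::write.table(st$positions, posf, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pos <- read_spot_positions(posf)
  expect_identical(pos$barcode, st$positions$barcode)
  expect_identical(pos$array_row, st$positions$array_row)
})

test_that("stage series plants monotone rate drifts in the stated direction", {
  p <- quick_params(seed = 8, n_groups = 3, units_per_group = 50)
  ser <- generate_stage_series(p)
  counts <- as.matrix(ser$counts$counts)
  stage <- ser$truth$stage
  stage_mean <- function(g) vapply(levels(stage), function(s)
    mean(counts[g, stage == s]), numeric(1))
  up_ok <- vapply(ser$truth$up_genes, function(g) all(diff(stage_mean(g)) > 0),
                  logical(1))
  down_ok <- vapply(ser$truth$down_genes, function(g) all(diff(stage_mean(g)) < 0),
                    logical(1))
  expect_gte(mean(c(up_ok, down_ok)), 0.9)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(synthetic_params(n_genes = 100, n_groups = 5,
                                markers_per_group = 50), "exceeds n_genes")
  expect_error(synthetic_params(marker_fold_change = 1), "fold_change")
  expect_error(synthetic_params(phase_frac = c(G1 = 0.5, S = 0.5, G2M = 0.5)),
               "sum to 1")
  expect_error(synthetic_params(n_genes = 150, n_groups = 1,
                                markers_per_group = 10, frac_low_quality = 0.1),
               "min_detected")
  p <- synthetic_params(n_genes = 600, n_groups = 4, units_per_group = 50,
                        markers_per_group = 20, frac_low_quality = 0,
                        grid_ncol = 8, grid_nrow = 10)
  expect_error(generate_st(p), "too small")
})
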