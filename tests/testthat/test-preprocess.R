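test_that("spot filter applies the strict fewer-than boundary", {
  cm <- make_cm_detected(c(199, 200, 350), n_genes = 400)
  out <- filter_spots(cm)
  expect_identical(out$unit_ids, c("u002", "u003"))
  expect_identical(out$gene_ids, cm$gene_ids)           # gene axis untouched
  expect_identical(filter_spots(out)$unit_ids, out$unit_ids)  # idempotent
  all_good <- make_cm_detected(c(250, 300), n_genes = 400)
  expect_identical(filter_spots(all_good)$unit_ids, all_good$unit_ids)
  too_low <- make_cm_detected(c(10, 20), n_genes = 400)
  expect_error(filter_spots(too_low), "removed every")
})

test_that("cell filter combines gene and mitochondrial criteria with OR", {
  n_genes <- 400
  gene_ids <- c(sprintf("MT-g%02d", 1:4), sprintf("g%04d", 5:n_genes))
  build_cell <- function(n_detected, mito_frac) {
    v <- integer(n_genes)
    v[5:(4 + n_detected)] <- 1L
    v[1] <- as.integer(round(mito_frac / (1 - mito_frac) * n_detected))
    v
  }
  cells <- cbind(build_cell(300, 0.25),   # mito too high -> removed
                 build_cell(300, 0.20),   # exactly 20% -> retained
                 build_cell(150, 0.05),   # too few genes -> removed
                 build_cell(300, 0.05))   # healthy
  cm <- count_matrix(cells, gene_ids, sprintf("c%d", 1:4), "cell")
  out <- filter_cells(cm)
  expect_identical(out$unit_ids, c("c2", "c4"))
  mf <- mito_fraction(cm)
  expect_equal(unname(mf[2]), 0.20, tolerance = 1e-9)
})

test_that("cell filter warns and skips the mito criterion without MT- genes", {
  cm <- make_cm_detected(c(300, 150), n_genes = 400, unit_kind = "cell")
  expect_warning(out <- filter_cells(cm), "MT-")
  expect_identical(out$unit_ids, "u001")
})

test_that("gene filter applies the in-at-least-three-cells boundary", {
  counts <- rbind(c(1L, 1L, 1L, 0L),   # 3 cells -> kept
                  c(1L, 1L, 0L, 0L),   # 2 cells -> removed
                  c(0L, 0L, 0L, 0L),   # all zero -> removed
                  c(2L, 3L, 4L, 5L))   # 4 cells -> kept
  cm <- count_matrix(counts, c("a", "b", "c", "d"), sprintf("u%d", 1:4), "cell")
  out <- filter_genes(cm)
  expect_identical(out$gene_ids, c("a", "d"))
  expect_identical(filter_genes(out)$gene_ids, out$gene_ids)
})

test_that("unit and gene filters commute on clean synthetic data", {
  p <- synthetic_params(n_genes = 800, n_groups = 3, units_per_group = 60,
                        markers_per_group = 20, frac_low_quality = 0.1, seed = 12)
  st <- generate_st(p)
  a <- filter_genes(filter_spots(st$counts))
  b <- filter_spots(filter_genes(st$counts))
  expect_identical(a$gene_ids, b$gene_ids)
  expect_identical(a$unit_ids, b$unit_ids)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
})

test_that("normalization follows the median-scaling log2 definition", {
  one <- count_matrix(matrix(c(3L, 0L, 1L)), c("a", "b", "c"), "u1", "spot")
  nm1 <- normalize_counts(one)
  expect_equal(nm1$values[, 1], log2(1 + c(a = 3, b = 0, c = 1)))
  expect_identical(nm1$scale_target, 4)

  two <- count_matrix(cbind(c(60L, 40L, 0L), c(100L, 100L, 100L)),
                      c("a", "b", "c"), c("u1", "u2"), "spot")
  nm2 <- normalize_counts(two)                          # totals 100, 300; median 200
  expect_equal(nm2$values["a", "u1"], log2(1 + 60 * 2))
  expect_equal(nm2$values["a", "u2"], log2(1 + 100 * 2 / 3))
  expect_equal(nm2$values["c", "u1"], 0)

  zero_unit <- count_matrix(cbind(c(1L, 0L), c(0L, 0L)), c("a", "b"),
                            c("u1", "u2"), "spot")
  expect_error(normalize_counts(zero_unit), "zero total")
})

test_that("rescaled linear totals reproduce the recorded median (invariant)", {
  p <- quick_params(seed = 3, units_per_group = 40)
  st <- generate_st(p)
  nm <- normalize_counts(st$counts)
  totals <- colSums(2^nm$values - 1)
  expect_true(all(abs(totals / nm$scale_target - 1) < 1e-6))
})

test_that("variable-gene selection ranks by dispersion with stated tie-breaks", {
  vals <- rbind(const = rep(1.5, 6),
                noisy = c(0, 3, 0, 3, 0, 3),
                mild = c(1, 1.2, 1, 1.2, 1, 1.2))
  nm <- make_nm(vals)
  top1 <- select_variable_genes(nm, 1)
  expect_identical(top1$genes, "noisy")
  expect_false("const" %in% select_variable_genes(nm, 2)$genes)
  expect_setequal(select_variable_genes(nm, 3)$genes, rownames(vals))
  expect_identical(select_variable_genes(nm, 2, exclude = "noisy")$genes,
                   c("mild", "const"))
  expect_error(select_variable_genes(nm, 4), "exceeds")
})

test_that("planted markers are enriched among the top variable genes", {
  p <- synthetic_params(seed = 21)
  st <- generate_st(p)
  nm <- normalize_counts(apply_qc(st$counts))
  top <- select_variable_genes(nm, round(0.1 * length(nm$gene_ids)))
  markers <- unlist(lapply(st$truth$marker_sets, `[[`, "genes"))
  markers <- intersect(markers, nm$gene_ids)
  frac_in_top <- mean(markers %in% top$genes)
  expect_gt(frac_in_top, 0.3)                           # >> the 10% base rate
})

test_that("hierarchical clustering honours k and renumbers by size", {
  set.seed(42)
  vals <- cbind(matrix(rnorm(40, 0), 4), matrix(rnorm(24, 5), 4))
  nm <- make_nm(vals)
  expect_identical(unname(cluster_hierarchical(nm, k = 1)$labels),
                   rep(0L, 16))
  singles <- cluster_hierarchical(nm, k = 16)
  expect_identical(sort(unique(unname(singles$labels))), 0:15)
  two <- cluster_hierarchical(nm, k = 2)
  expect_identical(unname(two$labels),
                   c(rep(0L, 10), rep(1L, 6)))          # larger cluster gets 0
  expect_error(cluster_hierarchical(nm, k = 17), "between 1")
})

test_that("clustering recovers planted regions (recovery experiment)", {
  skip_if_not_installed("mclust")
  ari <- vapply(1:3, function(s) {
    p <- synthetic_params(seed = s)
    st <- generate_st(p)
    nm <- normalize_counts(apply_qc(st$counts))
    ca <- cluster_hierarchical(nm, select_variable_genes(nm, 500), k = 5)
    mclust::adjustedRandIndex(ca$labels, st$truth$group[nm$unit_ids])
  }, numeric(1))
  expect_true(all(ari >= 0.9))
})

test_that("clustering is permutation-equivariant", {
  set.seed(7)
  vals <- matrix(rnorm(300), nrow = 10) +
    rep(c(0, 4, 8), each = 10)[col(matrix(0, 10, 30))]
  colnames(vals) <- sprintf("u%03d", 1:30)
  nm <- make_nm(vals)
  ca <- cluster_hierarchical(nm, k = 3)
  perm <- sample(ncol(vals))
  nm_p <- make_nm(vals[, perm])
  ca_p <- cluster_hierarchical(nm_p, k = 3)
  # same partition: every permuted cluster coincides with an original one
  crosstab <- table(ca$labels, ca_p$labels[nm$unit_ids])
  expect_identical(sum(crosstab > 0), 3L)
})

test_that("balanced subsampling is exact, deterministic and order-stable", {
  labels <- stats::setNames(rep(0:2, times = c(5, 8, 5)), sprintf("u%02d", 1:18))
  ca <- cluster_assignment(labels)
  ids <- balanced_subsample(ca, 5, seed = 1)
  expect_length(ids, 15L)
  expect_identical(ids[1:5], sprintf("u%02d", 1:5))     # whole group, stable order
  expect_identical(balanced_subsample(ca, 5, seed = 1), ids)
  expect_false(identical(balanced_subsample(ca, 5, seed = 2)[6:10], ids[6:10]))
  expect_error(balanced_subsample(ca, 6, seed = 1), "group '0'")
})
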