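#' Parameters for the synthetic ST / scRNA-seq generator
#'
#' The generator draws UMI counts from a gamma-Poisson (negative binomial)
#' model with lognormal gene baselines and lognormal library sizes — the
#' standard noise model for droplet single-cell and spot-level count data.
#' Group structure (tissue regions for spots, cell types for cells) is
#' planted by multiplying the baseline rate of each group's marker genes by
#' `marker_fold_change` inside the group. Defaults emulate a fetal-tissue
#' Visium-style experiment: ~6,000 UMIs per unit over 2,000 genes (each spot
#' pooling on the order of 5-100 cells' worth of RNA), ~5% mitochondrial
#' genes, and 10% deliberately low-quality units to exercise QC.
#'
#' @param n_genes Total number of genes (includes mitochondrial and
#'   cell-cycle genes).
#' @param n_groups Number of regions (ST) or cell types (SC).
#' @param units_per_group Spots/cells per group.
#' @param markers_per_group Planted marker genes per group (disjoint across
#'   groups).
#' @param marker_fold_change Multiplicative rate increase of a marker inside
#'   its group; must be > 1.
#' @param nb_dispersion Negative-binomial size parameter (> 0); smaller is
#'   noisier.
#' @param libsize_meanlog,libsize_sdlog Log-scale mean and sd of per-unit
#'   library size.
#' @param mito_gene_frac Fraction of genes named with the "MT-" prefix.
#' @param frac_low_quality Fraction of units constructed to fail QC.
#' @param phase_frac Named fractions for `G1`, `S`, `G2M` phase labels
#'   (cells only); must sum to 1.
#' @param cc_fold Rate multiplier applied to the G1/S (resp. G2/M) gene set
#'   in cells labelled S (resp. G2M), chosen so set-average scores separate
#'   phases by construction.
#' @param min_detected Detected-gene count that low-quality units are thinned
#'   below (and that healthy units are guaranteed to reach); matches the QC
#'   default of 200.
#' @param max_mito Mitochondrial fraction that mito-flagged low-quality cells
#'   are pushed above; matches the QC default of 0.20.
#' @param grid_ncol,grid_nrow Optional explicit spot-array dimensions; by
#'   default the grid is derived from `units_per_group`.
#' @param seed Integer seed; identical params (including seed) give
#'   bit-identical output.
#' @return A validated list of class `SyntheticParams`.
#' @export
synthetic_params <- function(n_genes = 2000,
                             n_groups = 5,
                             units_per_group = 200,
                             markers_per_group = 50,
                             marker_fold_change = 4,
                             nb_dispersion = 2,
                             libsize_meanlog = log(6000),
                             libsize_sdlog = 0.3,
                             mito_gene_frac = 0.05,
                             frac_low_quality = 0.1,
                             phase_frac = c(G1 = 0.5, S = 0.25, G2M = 0.25),
                             cc_fold = 6,
                             min_detected = 200,
                             max_mito = 0.20,
                             grid_ncol = NULL,
                             grid_nrow = NULL,
                             seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_groups = as.integer(n_groups),
            units_per_group = as.integer(units_per_group),
            markers_per_group = as.integer(markers_per_group),
            marker_fold_change = marker_fold_change,
            nb_dispersion = nb_dispersion,
            libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
            mito_gene_frac = mito_gene_frac,
            frac_low_quality = frac_low_quality,
            phase_frac = phase_frac, cc_fold = cc_fold,
            min_detected = as.integer(min_detected), max_mito = max_mito,
            grid_ncol = grid_ncol, grid_nrow = grid_nrow,
            seed = as.integer(seed))
  n_cc <- length(default_cc_gene_names()$g1s) + length(default_cc_gene_names()$g2m)
  n_mito <- round(p$mito_gene_frac * p$n_genes)
  if (p$markers_per_group * p$n_groups + n_mito + n_cc > p$n_genes) {
    stop("markers_per_group x n_groups (plus mitochondrial and cell-cycle genes) exceeds n_genes",
         call. = FALSE)
  }
  if (p$marker_fold_change <= 1) stop("marker_fold_change must be > 1", call. = FALSE)
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (p$frac_low_quality < 0 || p$frac_low_quality >= 1) {
    stop("frac_low_quality must be in [0, 1)", call. = FALSE)
  }
  if (p$frac_low_quality > 0 && p$n_genes <= p$min_detected) {
    stop("n_genes must exceed min_detected to plant low-quality units",
         call. = FALSE)
  }
  if (!setequal(names(p$phase_frac), c("G1", "S", "G2M")) ||
      abs(sum(p$phase_frac) - 1) > 1e-9 || any(p$phase_frac < 0)) {
    stop("phase_frac must have names G1, S, G2M and sum to 1", call. = FALSE)
  }
  structure(p, class = "SyntheticParams")
}

# synthetic names of the packaged cell-cycle sets; kept in code so the
# generator and the GMT fixture cannot drift apart
default_cc_gene_names <- function() {
  list(g1s = sprintf("G1S.SYN.%02d", 1:43),
       g2m = sprintf("G2M.SYN.%02d", 1:54))
}

#' Path to the packaged synthetic cell-cycle gene sets (GMT)
#'
#' The package ships a GMT with a 43-gene G1/S set and a 54-gene G2/M set —
#' the sizes of the core cell-cycle sets the scoring procedure expects. The
#' gene names are synthetic placeholders understood by the simulator; for
#' real data substitute any GMT whose names match your annotation.
#'
#' @return File path of the packaged GMT.
#' @export
cell_cycle_gmt <- function() {
  system.file("extdata", "cell_cycle_synthetic.gmt", package = "stmia",
              mustWork = TRUE)
}

#' Load the packaged synthetic cell-cycle gene sets
#'
#' @return List with `GeneSet` elements `G1S` and `G2M`.
#' @export
default_cell_cycle_sets <- function() {
  read_gmt(cell_cycle_gmt())
}

# Shared gene table: ids, baseline rates, marker assignment. Drawn first
# after seeding so ST and SC runs with the same params share gene identities,
# baselines and marker sets (matched regions <-> cell types).
build_gene_table <- function(p) {
  cc <- default_cc_gene_names()
  n_cc <- length(cc$g1s) + length(cc$g2m)
  n_mito <- round(p$mito_gene_frac * p$n_genes)
  n_plain <- p$n_genes - n_mito - n_cc
  ids <- c(sprintf("gene%05d", seq_len(n_plain)),
           sprintf("MT-gene%03d", seq_len(n_mito)),
           cc$g1s, cc$g2m)
  lambda <- stats::rlnorm(p$n_genes, meanlog = 0, sdlog = 1)
  is_cc <- c(rep(FALSE, n_plain + n_mito), rep(TRUE, n_cc))
  # fixed mid-range baseline for cycle genes keeps set-average scores of
  # inactive cells well below the classification threshold
  lambda[is_cc] <- stats::median(lambda[!is_cc])
  markers <- lapply(seq_len(p$n_groups), function(g) {
    ids[((g - 1) * p$markers_per_group + 1):(g * p$markers_per_group)]
  })
  names(markers) <- sprintf("group%d", seq_len(p$n_groups))
  list(ids = ids, lambda = lambda,
       mito = startsWith(ids, "MT-"),
       g1s = ids %in% cc$g1s, g2m = ids %in% cc$g2m,
       markers = markers)
}

# NB count matrix for one dataset given per-unit rate multipliers.
# mult: genes x units matrix of multiplicative adjustments to lambda.
draw_counts <- function(p, gt, mult) {
  n_units <- ncol(mult)
  libsize <- stats::rlnorm(n_units, p$libsize_meanlog, p$libsize_sdlog)
  rate <- gt$lambda * mult
  rate <- sweep(rate, 2, colSums(rate), "/")      # relative expression per unit
  mu <- sweep(rate, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = p$nb_dispersion),
                   nrow = p$n_genes, ncol = n_units)
  counts
}

# binomial downsampling until a unit detects fewer than `target` genes;
# preserves gene rank structure (thinning, not resampling)
thin_unit <- function(v, target) {
  while (sum(v > 0) >= target) {
    v <- stats::rbinom(length(v), v, 0.5)
  }
  v
}

# deterministic guarantee that a healthy unit detects at least `target`
# genes: add single counts to the first zero-count genes as needed
top_up_unit <- function(v, target) {
  short <- target - sum(v > 0)
  if (short > 0) {
    zeros <- which(v == 0)
    v[zeros[seq_len(short)]] <- 1L
  }
  v
}

pick_low_quality <- function(n_units, frac) {
  n_lq <- round(frac * n_units)
  if (n_lq == 0) return(integer())
  sort(sample.int(n_units, n_lq))
}

#' Generate a synthetic spatial transcriptomics dataset
#'
#' Spots are laid out on a rectangular array partitioned into `n_groups`
#' contiguous row-bands (the planted tissue regions; layout is deterministic,
#' randomness only in counts). Counts follow the negative-binomial model of
#' [synthetic_params()]; each region's marker genes have their rate
#' multiplied by `marker_fold_change` inside that region. A
#' `frac_low_quality` subset of spots is binomially downsampled until it
#' detects fewer than `min_detected` genes, while every other spot is
#' guaranteed to detect at least `min_detected`.
#'
#' @param params A [synthetic_params()] object.
#' @return List with elements `counts` (a `CountMatrix` of kind spot),
#'   `positions` (tissue-positions data.frame as read by
#'   [read_spot_positions()]), and `truth` (planted group labels, marker
#'   sets, low-quality flags, region layout).
#' @export
generate_st <- function(params) {
  stopifnot(inherits(params, "SyntheticParams"))
  p <- params
  with_seed(p$seed, {
    gt <- build_gene_table(p)
    n_units <- p$n_groups * p$units_per_group
    group <- rep(seq_len(p$n_groups), each = p$units_per_group)

    w <- if (!is.null(p$grid_ncol)) as.integer(p$grid_ncol) else
      ceiling(sqrt(p$units_per_group))
    h <- ceiling(p$units_per_group / w)  # rows per region band
    if (!is.null(p$grid_nrow) && p$grid_nrow < p$n_groups * h) {
      stop(sprintf("grid of %d rows is too small for %d region blocks of %d rows",
                   p$grid_nrow, p$n_groups, h), call. = FALSE)
    }
    j <- sequence(rep(p$units_per_group, p$n_groups)) - 1L
    array_row <- (group - 1L) * h + j %/% w
    array_col <- j %% w

    mult <- matrix(1, p$n_genes, n_units)
    for (g in seq_len(p$n_groups)) {
      rows <- match(gt$markers[[g]], gt$ids)
      mult[rows, group == g] <- p$marker_fold_change
    }
    counts <- draw_counts(p, gt, mult)

    lq <- pick_low_quality(n_units, p$frac_low_quality)
    for (u in lq) counts[, u] <- thin_unit(counts[, u], p$min_detected)
    for (u in setdiff(seq_len(n_units), lq)) {
      counts[, u] <- top_up_unit(counts[, u], p$min_detected)
    }

    barcodes <- sprintf("SPOT-%04d", seq_len(n_units))
    cm <- count_matrix(counts, gt$ids, barcodes, unit_kind = "spot")
    positions <- data.frame(
      barcode = barcodes, in_tissue = 1L,
      array_row = as.integer(array_row), array_col = as.integer(array_col),
      pixel_row = array_row * 200 + 100, pixel_col = array_col * 200 + 100,
      stringsAsFactors = FALSE
    )
    layout <- data.frame(group = seq_len(p$n_groups),
                         row_start = (seq_len(p$n_groups) - 1L) * h,
                         row_end = seq_len(p$n_groups) * h - 1L)
    truth <- list(
      group = stats::setNames(group, barcodes),
      marker_sets = lapply(names(gt$markers), function(nm)
        gene_set(nm, gt$markers[[nm]], "planted region markers")),
      low_quality = stats::setNames(seq_len(n_units) %in% lq, barcodes),
      region_layout = layout,
      params = p
    )
    names(truth$marker_sets) <- names(gt$markers)
    list(counts = cm, positions = positions, truth = truth)
  })
}

#' Generate a synthetic single-cell RNA-seq dataset
#'
#' As [generate_st()] but without a spatial layout: groups are cell types.
#' Each cell additionally carries a planted cell-cycle phase label; cells in
#' S (resp. G2M) have the packaged G1/S (resp. G2/M) gene set's rates
#' multiplied by `cc_fold`, so set-average scores separate the phases by
#' construction. Low-quality cells are split half/half between a
#' mitochondrial-fraction failure (> `max_mito`) and a low detected-gene
#' failure (< `min_detected`).
#'
#' @param params A [synthetic_params()] object.
#' @return List with elements `counts` (a `CountMatrix` of kind cell) and
#'   `truth` (group labels, marker sets, phase labels, low-quality flags and
#'   failure modes).
#' @export
generate_sc <- function(params) {
  stopifnot(inherits(params, "SyntheticParams"))
  p <- params
  with_seed(p$seed, {
    gt <- build_gene_table(p)
    n_units <- p$n_groups * p$units_per_group
    group <- rep(seq_len(p$n_groups), each = p$units_per_group)

    # deterministic phase counts (largest remainder), randomly placed
    target <- p$phase_frac * n_units
    n_ph <- floor(target)
    rem <- n_units - sum(n_ph)
    if (rem > 0) {
      extra <- order(target - n_ph, decreasing = TRUE)[seq_len(rem)]
      n_ph[extra] <- n_ph[extra] + 1
    }
    phase <- sample(rep(names(n_ph), times = n_ph))

    mult <- matrix(1, p$n_genes, n_units)
    for (g in seq_len(p$n_groups)) {
      rows <- match(gt$markers[[g]], gt$ids)
      mult[rows, group == g] <- p$marker_fold_change
    }
    mult[gt$g1s, phase == "S"] <- mult[gt$g1s, phase == "S"] * p$cc_fold
    mult[gt$g2m, phase == "G2M"] <- mult[gt$g2m, phase == "G2M"] * p$cc_fold
    counts <- draw_counts(p, gt, mult)

    lq <- pick_low_quality(n_units, p$frac_low_quality)
    n_mito_fail <- floor(length(lq) / 2)
    mito_fail <- lq[seq_len(n_mito_fail)]
    gene_fail <- setdiff(lq, mito_fail)
    for (u in gene_fail) counts[, u] <- thin_unit(counts[, u], p$min_detected)
    mito_rows <- which(gt$mito)
    for (u in mito_fail) {
      if (sum(counts[mito_rows, u]) == 0) counts[mito_rows[1], u] <- 1L
      while (sum(counts[mito_rows, u]) <= p$max_mito * sum(counts[, u])) {
        counts[mito_rows, u] <- counts[mito_rows, u] * 2L
      }
    }
    for (u in setdiff(seq_len(n_units), gene_fail)) {
      counts[, u] <- top_up_unit(counts[, u], p$min_detected)
    }
    # healthy cells must pass the mito gate; halve mito counts in the
    # (rare) draw that lands above the threshold
    for (u in setdiff(seq_len(n_units), mito_fail)) {
      while (sum(counts[mito_rows, u]) > p$max_mito * sum(counts[, u])) {
        counts[mito_rows, u] <- counts[mito_rows, u] %/% 2L
      }
    }

    barcodes <- sprintf("CELL-%05d", seq_len(n_units))
    cm <- count_matrix(counts, gt$ids, barcodes, unit_kind = "cell")
    failure <- rep("none", n_units)
    failure[mito_fail] <- "mito"
    failure[gene_fail] <- "low_genes"
    truth <- list(
      group = stats::setNames(group, barcodes),
      marker_sets = lapply(names(gt$markers), function(nm)
        gene_set(nm, gt$markers[[nm]], "planted cell-type markers")),
      phase = stats::setNames(phase, barcodes),
      low_quality = stats::setNames(seq_len(n_units) %in% lq, barcodes),
      failure_mode = stats::setNames(failure, barcodes),
      params = p
    )
    names(truth$marker_sets) <- names(gt$markers)
    list(counts = cm, truth = truth)
  })
}

#' Generate an ordered stage series with planted monotone genes
#'
#' Emulates an ordered differentiation series (e.g. early/mid/late
#' erythroblasts): `n_stages` groups of cells in a stated order. The first
#' `markers_per_group` plain genes drift linearly up in rate from 1x to
#' `marker_fold_change`x across the stages; the next block drifts down
#' symmetrically; all remaining genes are flat. Used to validate monotone
#' trend calling.
#'
#' @param params A [synthetic_params()] object; `n_groups` is the number of
#'   stages and `marker_fold_change` the extreme-stage fold.
#' @return List with `counts` (CountMatrix of kind cell), and `truth` holding
#'   `stage` (factor with levels in stage order), `up_genes`, `down_genes`,
#'   `flat_genes`.
#' @export
generate_stage_series <- function(params) {
  stopifnot(inherits(params, "SyntheticParams"))
  p <- params
  with_seed(p$seed, {
    gt <- build_gene_table(p)
    n_stages <- p$n_groups
    n_units <- n_stages * p$units_per_group
    stage_idx <- rep(seq_len(n_stages), each = p$units_per_group)
    levels <- sprintf("stage%d", seq_len(n_stages))

    m <- p$markers_per_group
    up <- gt$ids[seq_len(m)]
    down <- gt$ids[(m + 1):(2 * m)]
    up_drift <- 1 + (p$marker_fold_change - 1) * (stage_idx - 1) / (n_stages - 1)
    down_drift <- 1 + (p$marker_fold_change - 1) * (n_stages - stage_idx) / (n_stages - 1)
    mult <- matrix(1, p$n_genes, n_units)
    mult[match(up, gt$ids), ] <- rep(up_drift, each = m)
    mult[match(down, gt$ids), ] <- rep(down_drift, each = m)
    counts <- draw_counts(p, gt, mult)
    barcodes <- sprintf("CELL-%05d", seq_len(n_units))
    cm <- count_matrix(counts, gt$ids, barcodes, unit_kind = "cell")
    truth <- list(
      stage = stats::setNames(factor(levels[stage_idx], levels = levels),
                              barcodes),
      up_genes = up, down_genes = down,
      flat_genes = setdiff(gt$ids[!gt$mito & !gt$g1s & !gt$g2m], c(up, down)),
      params = p
    )
    list(counts = cm, truth = truth)
  })
}
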