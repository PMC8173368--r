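#' Subpopulation percentage, reported to two decimals
#'
#' `100 * n_sub / n_total`, rounded half-up to two decimals — the style used
#' for reporting subpopulation shares such as "25.26% (120 cells of 475
#' cells)".
#'
#' @param n_sub Count in the subpopulation (0..n_total).
#' @param n_total Total count (> 0).
#' @return Percentage in \[0, 100\] with two decimals.
#' @export
#' @examples
#' subpopulation_percent(120, 475)  # 25.26
#' subpopulation_percent(29, 184)   # 15.76
subpopulation_percent <- function(n_sub, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_sub < 0 || n_sub > n_total) {
    stop("n_sub must lie in [0, n_total]", call. = FALSE)
  }
  round_half_up(100 * n_sub / n_total, 2)
}

#' QC summary for a filtering step
#'
#' @param cm_before,cm_after `CountMatrix` objects before and after QC
#'   (`cm_after` units must be a subset of `cm_before` units).
#' @return List with units/genes before and after, and the median detected
#'   genes and median UMI total per retained unit.
#' @export
qc_summary <- function(cm_before, cm_after) {
  stopifnot(inherits(cm_before, "CountMatrix"), inherits(cm_after, "CountMatrix"))
  if (!all(cm_after$unit_ids %in% cm_before$unit_ids)) {
    stop("cm_after units are not a subset of cm_before units", call. = FALSE)
  }
  list(unit_kind = cm_before$unit_kind,
       units_before = ncol(cm_before$counts),
       units_after = ncol(cm_after$counts),
       genes_before = nrow(cm_before$counts),
       genes_after = nrow(cm_after$counts),
       median_genes_per_unit = stats::median(detected_genes(cm_after)),
       median_umis_per_unit = stats::median(unit_totals(cm_after)))
}

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], populated
#' for a fully synthetic run. Fields: `seed`; `synthetic` (arguments for
#' [synthetic_params()]); `qc` (arguments for [qc_thresholds()]); `n_top`
#' variable genes; `k_st` / `k_sc` cluster counts; `markers`
#' (`logfc_threshold`, `min_pct`, `alpha`); `mia` (`universe` either
#' `"intersection"` or `"union"`, and `min_score`); `cellcycle`
#' (`gmt` path or `NULL` for the packaged sets, `threshold`); `trends`
#' (`enabled`, `alpha`, `n_per_group`).
#'
#' @param seed Integer seed recorded in every output header.
#' @return A config list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(),
    qc = list(),
    n_top = 500L,
    k_st = 5L,
    k_sc = 5L,
    markers = list(logfc_threshold = 0.1, min_pct = 0.01, alpha = 0.05),
    mia = list(universe = "intersection", min_score = -log10(0.05)),
    cellcycle = list(gmt = NULL, threshold = 2),
    trends = list(enabled = TRUE, alpha = 0.05, n_per_group = 50L)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys missing from the file fall back to [default_pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A config list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("config must be .yaml, .yml or .json", call. = FALSE))
  cfg <- default_pipeline_config()
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      for (sub in names(user[[key]])) cfg[[key]][[sub]] <- user[[key]][[sub]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full ST + scRNA-seq integration pipeline
#'
#' Generates (or loads) the two datasets, applies QC, normalizes, selects
#' variable genes, clusters, detects markers, runs MIA, classifies cell
#' cycle on the single-cell data, optionally calls stage trends on a
#' synthetic stage series, and writes every table to `out_dir` with a
#' provenance header (package version, seed, config hash). Re-running with
#' an identical config reproduces byte-identical tabular outputs.
#'
#' @param cfg A config list ([default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the in-memory stage results (`qc`,
#'   `clusters`, `markers`, `mia`, `assignments`, `cellcycle`,
#'   `phase_fractions`, `trends`, `summary`).
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(cfg)
  header <- c(sprintf("# stmia %s", as.character(utils::packageVersion("stmia"))),
              sprintf("# seed=%d config_hash=%s", cfg$seed, hash))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  params <- stage("simulate", do.call(synthetic_params,
                                      c(cfg$synthetic, list(seed = cfg$seed))))
  st <- stage("simulate", generate_st(params))
  sc <- stage("simulate", generate_sc(params))
  th <- stage("qc", do.call(qc_thresholds, cfg$qc))

  st_f <- stage("qc", apply_qc(st$counts, th))
  sc_f <- stage("qc", apply_qc(sc$counts, th))
  qc <- list(st = qc_summary(st$counts, st_f), sc = qc_summary(sc$counts, sc_f))
  jsonlite::write_json(c(list(seed = cfg$seed, config_hash = hash), qc),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  st_nm <- stage("normalize", normalize_counts(st_f))
  sc_nm <- stage("normalize", normalize_counts(sc_f))

  cc_sets <- stage("cellcycle", if (is.null(cfg$cellcycle$gmt))
    default_cell_cycle_sets() else read_gmt(cfg$cellcycle$gmt))
  st_var <- stage("cluster", select_variable_genes(st_nm, min(cfg$n_top, nrow(st_nm$values))))
  # known cell-cycle genes are excluded from the clustering gene set so
  # cycling phase does not masquerade as cell-type structure
  sc_avail <- length(setdiff(sc_nm$gene_ids,
                             unlist(lapply(cc_sets, as_gene_ids))))
  sc_var <- stage("cluster", select_variable_genes(
    sc_nm, min(cfg$n_top, sc_avail), exclude = cc_sets))
  st_ca <- stage("cluster", cluster_hierarchical(st_nm, st_var, k = cfg$k_st))
  sc_ca <- stage("cluster", cluster_hierarchical(sc_nm, sc_var, k = cfg$k_sc))
  write_tsv_with_header(
    data.frame(unit_id = st_ca$unit_ids, cluster = unname(st_ca$labels)),
    file.path(out_dir, "st_clusters.tsv"), header)
  write_tsv_with_header(
    data.frame(unit_id = sc_ca$unit_ids, cluster = unname(sc_ca$labels)),
    file.path(out_dir, "sc_clusters.tsv"), header)

  mk <- cfg$markers
  st_mt <- stage("markers", find_all_markers(st_nm, st_ca, mk$logfc_threshold, mk$min_pct))
  sc_mt <- stage("markers", find_all_markers(sc_nm, sc_ca, mk$logfc_threshold, mk$min_pct))
  write_tsv_with_header(st_mt, file.path(out_dir, "st_markers.tsv"), header)
  write_tsv_with_header(sc_mt, file.path(out_dir, "sc_markers.tsv"), header)
  st_sets <- stage("markers", marker_sets(st_mt, alpha = mk$alpha))
  sc_sets <- stage("markers", marker_sets(sc_mt, alpha = mk$alpha))
  names(st_sets) <- sub("^cluster", "region", names(st_sets))
  for (i in seq_along(st_sets)) st_sets[[i]]$name <- names(st_sets)[i]
  write_gmt(st_sets, file.path(out_dir, "st_marker_sets.gmt"))
  write_gmt(sc_sets, file.path(out_dir, "sc_marker_sets.gmt"))

  universe <- stage("mia", switch(cfg$mia$universe,
                                  intersection = intersect(st_nm$gene_ids, sc_nm$gene_ids),
                                  union = union(st_nm$gene_ids, sc_nm$gene_ids),
                                  stop("mia$universe must be 'intersection' or 'union'")))
  mia <- stage("mia", mia_map(sc_sets, st_sets, universe))
  write_tsv_with_header(as.data.frame(mia), file.path(out_dir, "mia_map.tsv"), header)
  assignments <- stage("mia", assign_regions(mia, min_score = cfg$mia$min_score))
  write_tsv_with_header(assignments, file.path(out_dir, "mia_assignments.tsv"), header)

  calls <- stage("cellcycle", cc_classify(cc_scores(sc_nm, cc_sets$G1S, cc_sets$G2M),
                                          threshold = cfg$cellcycle$threshold))
  fractions <- stage("cellcycle", phase_fractions(calls, sc_ca))
  write_tsv_with_header(calls, file.path(out_dir, "cellcycle_calls.tsv"), header)
  write_tsv_with_header(fractions, file.path(out_dir, "phase_fractions.tsv"), header)

  trends <- NULL
  if (isTRUE(cfg$trends$enabled)) {
    series <- stage("trends", generate_stage_series(params))
    ser_nm <- stage("trends", normalize_counts(series$counts))
    trends <- stage("trends", gradual_genes(ser_nm, series$truth$stage,
                                            alpha = cfg$trends$alpha))
    write_tsv_with_header(trends, file.path(out_dir, "trends.tsv"), header)
    pca <- stage("trends", balanced_stage_pca(ser_nm, series$truth$stage,
                                              n_per_group = cfg$trends$n_per_group,
                                              seed = cfg$seed))
    write_tsv_with_header(pca, file.path(out_dir, "trend_pca.tsv"), header)
  }

  cluster_pct <- vapply(seq_len(sc_ca$k) - 1L, function(cl)
    subpopulation_percent(sum(sc_ca$labels == cl), length(sc_ca$labels)),
    numeric(1))
  summary <- list(
    seed = cfg$seed, config_hash = hash,
    qc = qc,
    st_cluster_sizes = as.integer(tabulate(st_ca$labels + 1L, st_ca$k)),
    sc_cluster_sizes = as.integer(tabulate(sc_ca$labels + 1L, sc_ca$k)),
    sc_cluster_percent = cluster_pct,
    proliferative_fraction = sum(calls$label != "G1_quiescent") / nrow(calls),
    region_assignments = stats::setNames(assignments$cell_type, assignments$region)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(qc = qc, st_clusters = st_ca, sc_clusters = sc_ca,
                 st_markers = st_mt, sc_markers = sc_mt, mia = mia,
                 assignments = assignments, cellcycle = calls,
                 phase_fractions = fractions, trends = trends,
                 summary = summary, truth = list(st = st$truth, sc = sc$truth)))
}
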