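#' Quality-control thresholds
#'
#' @param min_genes_per_spot Spots detecting fewer genes than this are
#'   removed ("fewer than" is strict: a spot at exactly the threshold is
#'   kept).
#' @param min_genes_per_cell As above, for cells.
#' @param max_mito_frac Cells whose mitochondrial UMI fraction exceeds this
#'   (strictly) are removed.
#' @param min_cells_per_gene Genes detected in fewer units than this are
#'   removed.
#' @return A validated list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes_per_spot = 200L,
                          min_genes_per_cell = 200L,
                          max_mito_frac = 0.20,
                          min_cells_per_gene = 3L) {
  th <- list(min_genes_per_spot = as.integer(min_genes_per_spot),
             min_genes_per_cell = as.integer(min_genes_per_cell),
             max_mito_frac = max_mito_frac,
             min_cells_per_gene = as.integer(min_cells_per_gene))
  if (any(unlist(th[c(1, 2, 4)]) < 0) || th$max_mito_frac < 0 ||
      th$max_mito_frac > 1) {
    stop("QC thresholds must be non-negative and max_mito_frac in [0, 1]",
         call. = FALSE)
  }
  structure(th, class = "QCThresholds")
}

stop_if_empty <- function(cm, what, n_before) {
  if (ncol(cm$counts) == 0L || nrow(cm$counts) == 0L) {
    stop(sprintf("%s removed every record (%d x %d before filtering)",
                 what, n_before[1], n_before[2]), call. = FALSE)
  }
  cm
}

#' Filter low-coverage spots
#'
#' Retains spots detecting at least `min_genes_per_spot` genes. The gene axis
#' and spot order are untouched; detected-gene counts are computed on the
#' matrix as passed in.
#'
#' @param cm A `CountMatrix` of kind spot.
#' @param th A [qc_thresholds()].
#' @return Filtered `CountMatrix`.
#' @export
filter_spots <- function(cm, th = qc_thresholds()) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(th, "QCThresholds"))
  if (cm$unit_kind != "spot") stop("filter_spots expects unit_kind = 'spot'", call. = FALSE)
  keep <- detected_genes(cm) >= th$min_genes_per_spot
  out <- subset_counts(cm, units = cm$unit_ids[keep])
  stop_if_empty(out, "spot filter", dim(cm))
}

#' Filter low-quality cells
#'
#' Removes cells detecting fewer than `min_genes_per_cell` genes OR whose
#' mitochondrial UMI fraction (counts of "MT-"-prefixed genes over total
#' counts) strictly exceeds `max_mito_frac`. A cell at exactly the
#' mitochondrial threshold is kept. If no "MT-" gene is present the
#' mitochondrial criterion is skipped with a warning.
#'
#' @param cm A `CountMatrix` of kind cell.
#' @param th A [qc_thresholds()].
#' @return Filtered `CountMatrix`.
#' @export
filter_cells <- function(cm, th = qc_thresholds()) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(th, "QCThresholds"))
  if (cm$unit_kind != "cell") stop("filter_cells expects unit_kind = 'cell'", call. = FALSE)
  low_genes <- detected_genes(cm) < th$min_genes_per_cell
  if (!any(startsWith(cm$gene_ids, "MT-"))) {
    warning("no 'MT-' genes present; mitochondrial criterion skipped",
            call. = FALSE)
    high_mito <- rep(FALSE, ncol(cm$counts))
  } else {
    high_mito <- mito_fraction(cm) > th$max_mito_frac
  }
  out <- subset_counts(cm, units = cm$unit_ids[!(low_genes | high_mito)])
  stop_if_empty(out, "cell filter", dim(cm))
}

#' Filter rarely detected genes
#'
#' Retains genes detected (count > 0) in at least `min_cells_per_gene`
#' units.
#'
#' @param cm A `CountMatrix`.
#' @param th A [qc_thresholds()].
#' @return Filtered `CountMatrix`.
#' @export
filter_genes <- function(cm, th = qc_thresholds()) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(th, "QCThresholds"))
  n_units <- Matrix::rowSums(cm$counts > 0)
  out <- subset_counts(cm, genes = cm$gene_ids[n_units >= th$min_cells_per_gene])
  stop_if_empty(out, "gene filter", dim(cm))
}

#' Apply the standard QC sequence
#'
#' Unit filter (spots or cells, per `unit_kind`) followed by the gene
#' filter, each applied once on the matrix as it stands. With
#' `iterate = TRUE` the two filters are re-applied until a fixed point is
#' reached (gene removal can drop a unit's detected-gene count below
#' threshold and vice versa).
#'
#' @param cm A `CountMatrix`.
#' @param th A [qc_thresholds()].
#' @param iterate Re-filter to a fixed point (default `FALSE`).
#' @return Filtered `CountMatrix`.
#' @export
apply_qc <- function(cm, th = qc_thresholds(), iterate = FALSE) {
  unit_filter <- if (cm$unit_kind == "spot") filter_spots else filter_cells
  out <- filter_genes(unit_filter(cm, th), th)
  if (iterate) {
    repeat {
      nxt <- filter_genes(unit_filter(out, th), th)
      if (identical(dim(nxt), dim(out))) break
      out <- nxt
    }
  }
  out
}

#' Median-scaling log2 normalization
#'
#' Each unit's counts are divided by the unit's total transcript count,
#' scaled by the median total across units, and log2-transformed with a
#' pseudocount of 1:
#' `value = log2(1 + count * median_total / unit_total)`.
#' The pre-scaling median total is recorded as `scale_target`, so the
#' linear-scale sum `2^value - 1` of every unit equals it.
#'
#' @param cm A `CountMatrix` (run QC first; zero-total units are an error).
#' @return An object of class `NormalizedMatrix`: list with `values` (dense
#'   genes x units matrix of log2 expression), `gene_ids`, `unit_ids`,
#'   `unit_kind`, `scale_target`.
#' @export
normalize_counts <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) {
    stop(sprintf("%d unit(s) have zero total counts; apply QC before normalizing",
                 sum(totals == 0)), call. = FALSE)
  }
  med <- stats::median(totals)
  scaled <- sweep(as.matrix(cm$counts), 2, med / totals, "*")
  values <- log2(1 + scaled)
  dimnames(values) <- list(cm$gene_ids, cm$unit_ids)
  structure(list(values = values, gene_ids = cm$gene_ids,
                 unit_ids = cm$unit_ids, unit_kind = cm$unit_kind,
                 scale_target = med),
            class = "NormalizedMatrix")
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d %ss (log2 scale, median total %.1f)\n",
              nrow(x$values), ncol(x$values), x$unit_kind, x$scale_target))
  invisible(x)
}

#' Select the most variable genes
#'
#' Ranks genes by dispersion (variance / mean) of linear-scale expression
#' `2^value - 1` and returns the top `n_top`. Genes with zero mean have
#' dispersion 0. Ties are broken lexicographically by gene id.
#'
#' @param nm A [normalize_counts()] result.
#' @param n_top Number of genes to select.
#' @param exclude Optional [gene_set()]s or gene id vector removed before
#'   ranking — e.g. known cell-cycle genes, whose strong phase-driven
#'   variance would otherwise dominate clustering.
#' @return A [gene_set()] named `"variable_genes"`.
#' @export
select_variable_genes <- function(nm, n_top, exclude = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  drop <- if (is.null(exclude)) character() else
    unlist(lapply(if (inherits(exclude, "GeneSet")) list(exclude) else exclude,
                  as_gene_ids))
  ids <- setdiff(nm$gene_ids, drop)
  if (n_top > length(ids)) {
    stop("n_top exceeds the number of (non-excluded) genes", call. = FALSE)
  }
  lin <- 2^nm$values[ids, , drop = FALSE] - 1
  mu <- rowMeans(lin)
  v <- rowMeans(lin^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, ids)
  gene_set("variable_genes", ids[ord[seq_len(n_top)]],
           "top variably expressed genes (dispersion ranked)")
}

#' Cluster assignment
#'
#' @param labels Integer labels 0..k-1, named by unit id.
#' @param k Number of clusters; defaults to the number of distinct labels.
#' @return An object of class `ClusterAssignment` with elements `unit_ids`,
#'   `labels` (named integer vector) and `k`.
#' @export
cluster_assignment <- function(labels, k = length(unique(labels))) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(names(labels))) stop("labels must be named by unit id", call. = FALSE)
  if (!setequal(unique(labels), seq_len(k) - 1L)) {
    stop("labels must use every value in 0..k-1", call. = FALSE)
  }
  structure(list(unit_ids = names(labels), labels = labels, k = as.integer(k)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d units in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels + 1L, x$k), collapse = ", ")))
  invisible(x)
}

#' Ward hierarchical clustering of units
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances over
#' the supplied genes, cut to `k` clusters. Labels are renumbered 0..k-1 by
#' decreasing cluster size (ties by first occurrence).
#'
#' @param nm A [normalize_counts()] result.
#' @param genes A [gene_set()] or character vector of gene ids to cluster
#'   on; defaults to all genes.
#' @param k Number of clusters (1..n_units).
#' @return A [cluster_assignment()].
#' @export
cluster_hierarchical <- function(nm, genes = NULL, k) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  n_units <- ncol(nm$values)
  if (k < 1 || k > n_units) stop("k must be between 1 and the number of units", call. = FALSE)
  ids <- if (is.null(genes)) nm$gene_ids else intersect(as_gene_ids(genes), nm$gene_ids)
  if (length(ids) == 0L) stop("none of the requested genes are present", call. = FALSE)
  x <- t(nm$values[ids, , drop = FALSE])
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  sizes <- tabulate(raw, k)
  new_label <- integer(k)
  new_label[order(-sizes, seq_len(k))] <- seq_len(k) - 1L
  cluster_assignment(stats::setNames(new_label[raw], nm$unit_ids), k = k)
}

#' Balanced subsampling of clusters
#'
#' Draws exactly `n_per_group` unit ids from every cluster without
#' replacement, deterministically under `seed`. When a cluster has exactly
#' `n_per_group` members it is returned whole in original order.
#'
#' @param ca A [cluster_assignment()] (or a named factor/character vector of
#'   group labels).
#' @param n_per_group Sample size per group.
#' @param seed Integer seed.
#' @return Character vector of unit ids, groups concatenated in label
#'   order.
#' @export
balanced_subsample <- function(ca, n_per_group, seed) {
  labels <- if (inherits(ca, "ClusterAssignment")) ca$labels else ca
  if (is.null(names(labels))) stop("group labels must be named by unit id", call. = FALSE)
  groups <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  with_seed(seed, {
    unlist(lapply(groups, function(g) {
      ids <- names(labels)[labels == g]
      if (length(ids) < n_per_group) {
        stop(sprintf("group '%s' has %d units, fewer than n_per_group = %d",
                     g, length(ids), n_per_group), call. = FALSE)
      }
      if (length(ids) == n_per_group) ids else sample(ids, n_per_group)
    }), use.names = FALSE)
  })
}
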