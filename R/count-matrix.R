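#' UMI count matrix with unit metadata
#'
#' Container for a raw UMI count matrix, genes in rows and units (ST spots or
#' single cells) in columns. Counts are stored as a sparse
#' [Matrix::dgCMatrix-class]; `unit_kind` records whether columns are spots
#' or cells so downstream QC can pick the right filters.
#'
#' @param counts Matrix-like object of non-negative integer counts,
#'   genes x units. Coerced to a sparse `dgCMatrix`.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param unit_ids Character vector of unique spot/cell barcodes (column
#'   names).
#' @param unit_kind Either `"spot"` or `"cell"`.
#'
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `gene_ids`, `unit_ids`, `unit_kind`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 0L, 0L, 7L), nrow = 3)
#' cm <- count_matrix(m, paste0("g", 1:3), c("bc1", "bc2"), "spot")
#' dim(cm)
count_matrix <- function(counts, gene_ids, unit_ids,
                         unit_kind = c("spot", "cell")) {
  unit_kind <- match.arg(unit_kind)
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(unit_ids)) {
    stop("count matrix dimensions do not match id list lengths", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ids", call. = FALSE)
  }
  if (anyDuplicated(unit_ids)) {
    stop("duplicated unit ids (barcodes)", call. = FALSE)
  }
  v <- counts@x
  if (any(v < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(v != trunc(v))) stop("non-integer counts are not allowed", call. = FALSE)
  dimnames(counts) <- list(gene_ids, unit_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, unit_ids = unit_ids,
         unit_kind = unit_kind),
    class = "CountMatrix"
  )
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d %ss, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), x$unit_kind,
              length(x$counts@x)))
  invisible(x)
}

#' Per-unit number of detected genes
#'
#' A gene counts as detected in a unit when its UMI count is greater than
#' zero.
#'
#' @param cm A [count_matrix()].
#' @return Named integer vector, one entry per unit.
#' @export
detected_genes <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  n <- Matrix::colSums(cm$counts > 0)
  stats::setNames(as.integer(n), cm$unit_ids)
}

#' Per-unit total UMI count
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of column sums.
#' @export
unit_totals <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  stats::setNames(Matrix::colSums(cm$counts), cm$unit_ids)
}

#' Per-unit mitochondrial UMI fraction
#'
#' Mitochondrial genes are identified by name prefix, following the human
#' convention of "MT-"-prefixed mitochondrially encoded genes (MT-CO1 etc.).
#'
#' @param cm A [count_matrix()].
#' @param prefix Gene-name prefix marking mitochondrial genes.
#' @return Named numeric vector in \[0, 1\]; 0 where a unit has no counts.
#' @export
mito_fraction <- function(cm, prefix = "MT-") {
  stopifnot(inherits(cm, "CountMatrix"))
  mito <- startsWith(cm$gene_ids, prefix)
  tot <- Matrix::colSums(cm$counts)
  mt <- if (any(mito)) Matrix::colSums(cm$counts[mito, , drop = FALSE]) else
    numeric(ncol(cm$counts))
  frac <- ifelse(tot > 0, mt / tot, 0)
  stats::setNames(frac, cm$unit_ids)
}

#' Restrict a CountMatrix to a subset of genes and/or units
#'
#' @param cm A [count_matrix()].
#' @param genes,units Character vectors of ids to keep (in the matrix's own
#'   order), or `NULL` to keep all.
#' @return A `CountMatrix`.
#' @export
subset_counts <- function(cm, genes = NULL, units = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  keep_g <- if (is.null(genes)) cm$gene_ids else cm$gene_ids[cm$gene_ids %in% genes]
  keep_u <- if (is.null(units)) cm$unit_ids else cm$unit_ids[cm$unit_ids %in% units]
  count_matrix(cm$counts[keep_g, keep_u, drop = FALSE], keep_g, keep_u,
               cm$unit_kind)
}

#' Gene set
#'
#' A named set of gene identifiers; duplicates are collapsed on
#' construction.
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene ids.
#' @param description Free-text description (second GMT column).
#' @return An object of class `GeneSet` with elements `name`, `description`,
#'   `genes` (unique, original first-occurrence order).
#' @export
gene_set <- function(name, genes, description = "") {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) {
    stop("gene set name must be a non-empty string", call. = FALSE)
  }
  structure(list(name = name, description = as.character(description),
                 genes = unique(as.character(genes))),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

as_gene_ids <- function(x) {
  if (inherits(x, "GeneSet")) x$genes else as.character(x)
}
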