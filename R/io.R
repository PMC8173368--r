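#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads the usual MTX + features + barcodes triplet into a
#' [count_matrix()]. Genes are kept in file order. The features TSV may have
#' one column (id) or more (id, symbol, ...); the first column is the key.
#'
#' @param matrix_path Path to a MatrixMarket coordinate file of integer
#'   counts.
#' @param genes_path Path to a TSV with one gene record per line.
#' @param barcodes_path Path to a TSV with one barcode per line.
#' @param unit_kind `"spot"` or `"cell"`.
#' @return A `CountMatrix`.
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path,
                        unit_kind = c("spot", "cell")) {
  unit_kind <- match.arg(unit_kind)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             colClasses = "character")[[1L]]
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                colClasses = "character")[[1L]]
  if (nrow(m) != length(genes)) {
    stop(sprintf("MTX declares %d rows but genes file has %d records",
                 nrow(m), length(genes)), call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop(sprintf("MTX declares %d columns but barcodes file has %d records",
                 ncol(m), length(barcodes)), call. = FALSE)
  }
  count_matrix(m, genes, barcodes, unit_kind)
}

#' Write a CountMatrix as MTX + features + barcodes
#'
#' The MatrixMarket file uses the coordinate integer format with 1-based
#' indices; the header declares the exact number of stored entries.
#' Round-trips with [read_counts()] bit-exactly on the integer payload.
#'
#' @param cm A [count_matrix()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the three file paths (`matrix`, `genes`, `barcodes`).
#' @export
write_counts <- function(cm, out_dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir),
           call. = FALSE)
    }
  }
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"))
  trip <- Matrix::summary(cm$counts)  # 1-based (i, j, x), column-major order
  ord <- order(trip$j, trip$i)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    sprintf("%d %d %d", nrow(cm$counts), ncol(cm$counts), nrow(trip)),
    sprintf("%d %d %d", trip$i[ord], trip$j[ord], as.integer(trip$x[ord]))
  )
  writeLines(lines, paths[["matrix"]])
  writeLines(cm$gene_ids, paths[["genes"]])
  writeLines(cm$unit_ids, paths[["barcodes"]])
  invisible(paths)
}

#' Read a Visium-dialect tissue-positions table
#'
#' Accepts either a headerless 6-column CSV or the Visium v1 header dialect
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,
#' pxl_col_in_fullres`). Pixel coordinates are carried through untouched.
#'
#' @param csv_path Path to the CSV.
#' @param strict If `TRUE` (default) malformed records raise an error; if
#'   `FALSE` they are dropped with a warning naming the count.
#' @return A data.frame with columns `barcode`, `in_tissue` (0/1 integer),
#'   `array_row`, `array_col` (integers), `pixel_row`, `pixel_col`.
#' @export
read_spot_positions <- function(csv_path, strict = TRUE) {
  empty <- data.frame(barcode = character(), in_tissue = integer(),
                      array_row = integer(), array_col = integer(),
                      pixel_row = numeric(), pixel_col = numeric(),
                      stringsAsFactors = FALSE)
  first <- tryCatch(readLines(csv_path, n = 1L), error = function(e) character())
  if (length(first) == 0L) {
    warning("empty spot-positions file: ", csv_path, call. = FALSE)
    return(empty)
  }
  has_header <- startsWith(first, "barcode")
  raw <- utils::read.csv(csv_path, header = has_header,
                         colClasses = "character")
  if (ncol(raw) != 6L) {
    stop(sprintf("expected 6 columns in spot positions, found %d", ncol(raw)),
         call. = FALSE)
  }
  names(raw) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pixel_row", "pixel_col")
  as_int <- function(v) {
    n <- suppressWarnings(as.numeric(v))
    ifelse(is.na(n) | n != trunc(n), NA_integer_, as.integer(n))
  }
  out <- data.frame(
    barcode = raw$barcode,
    in_tissue = as_int(raw$in_tissue),
    array_row = as_int(raw$array_row),
    array_col = as_int(raw$array_col),
    pixel_row = suppressWarnings(as.numeric(raw$pixel_row)),
    pixel_col = suppressWarnings(as.numeric(raw$pixel_col)),
    stringsAsFactors = FALSE
  )
  bad <- is.na(out$in_tissue) | !(out$in_tissue %in% c(0L, 1L)) |
    is.na(out$array_row) | out$array_row < 0L |
    is.na(out$array_col) | out$array_col < 0L
  if (any(bad)) {
    if (strict) {
      stop(sprintf("%d malformed spot-position record(s) (in_tissue not 0/1 or non-integer array coordinates)",
                   sum(bad)), call. = FALSE)
    }
    warning(sprintf("dropping %d malformed spot-position record(s)", sum(bad)),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (anyDuplicated(out[c("array_row", "array_col")])) {
    stop("duplicated (array_row, array_col) positions", call. = FALSE)
  }
  if (anyDuplicated(out$barcode)) {
    stop("duplicated barcodes in spot positions", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' GMT format: one set per line, `name TAB description TAB gene TAB gene...`.
#' Duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields (no genes)", i),
           call. = FALSE)
    }
    gene_set(f[[1L]], f[-(1:2)], description = f[[2L]])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of [gene_set()] objects (a single `GeneSet` is
#'   accepted).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "GeneSet"))
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
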