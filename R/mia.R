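#' Hypergeometric overlap test for one pair of gene sets
#'
#' Tests whether the overlap `k = |A intersect B|` between two gene sets is
#' larger (enrichment) or smaller (depletion) than expected when drawing
#' `|B|` genes at random from a universe of `N` genes containing `|A|`
#' successes. Both tails include the observed overlap:
#' `p_enr = P(X >= k)` and `p_dep = P(X <= k)` for
#' `X ~ Hypergeometric(N, |A|, |B|)`. Genes outside the universe are dropped
#' from the sets with a logged count.
#'
#' @param set_a,set_b [gene_set()] objects (or character vectors).
#' @param universe Character vector of background gene ids ("all genes as
#'   the background").
#' @return List with `k`, `K` (`|A|` in universe), `n` (`|B|` in universe),
#'   `N`, `p_enr`, `p_dep`.
#' @export
mia_pair <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0L) stop("empty gene universe", call. = FALSE)
  a <- unique(as_gene_ids(set_a))
  b <- unique(as_gene_ids(set_b))
  dropped <- sum(!(a %in% universe)) + sum(!(b %in% universe))
  if (dropped > 0) {
    message(sprintf("mia_pair: dropped %d gene(s) outside the universe", dropped))
  }
  a <- a[a %in% universe]
  b <- b[b %in% universe]
  if (length(a) == 0L || length(b) == 0L) {
    warning("empty gene set after universe restriction", call. = FALSE)
  }
  K <- length(a)
  n <- length(b)
  k <- length(intersect(a, b))
  p_enr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_dep <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  list(k = k, K = K, n = n, N = N, p_enr = p_enr, p_dep = p_dep)
}

#' Multimodal intersection analysis map
#'
#' Applies [mia_pair()] to every (cell type, region) pair of marker gene
#' sets, producing the enrichment/depletion map that places cell types in
#' tissue regions. The display score is a signed log10 p-value:
#' `-log10(p_enr)` when the enrichment tail is the smaller (positive, "red"),
#' `log10(p_dep)` otherwise (negative, "blue"). P-values are reported raw;
#' BH-adjusted values are carried alongside for serialization.
#'
#' @param ct_sets Named list of cell-type marker [gene_set()]s.
#' @param region_sets Named list of region marker [gene_set()]s.
#' @param universe Background gene ids.
#' @return An object of class `MIAResult`: list with `cell_types`,
#'   `regions`, `universe_N`, matrices `overlap_k`, `p_enrichment`,
#'   `p_depletion`, `score` (cell types in rows, regions in columns), and
#'   `set_sizes`.
#' @export
mia_map <- function(ct_sets, region_sets, universe) {
  if (length(ct_sets) < 1 || length(region_sets) < 1) {
    stop("need at least one gene set on each side", call. = FALSE)
  }
  ct_names <- names(ct_sets)
  rg_names <- names(region_sets)
  if (is.null(ct_names) || is.null(rg_names)) {
    stop("set lists must be named", call. = FALSE)
  }
  dims <- list(ct_names, rg_names)
  k <- matrix(NA_integer_, length(ct_sets), length(region_sets), dimnames = dims)
  p_enr <- p_dep <- matrix(NA_real_, length(ct_sets), length(region_sets),
                           dimnames = dims)
  for (i in seq_along(ct_sets)) {
    for (j in seq_along(region_sets)) {
      r <- mia_pair(ct_sets[[i]], region_sets[[j]], universe)
      k[i, j] <- r$k
      p_enr[i, j] <- r$p_enr
      p_dep[i, j] <- r$p_dep
    }
  }
  score <- ifelse(p_enr <= p_dep, -log10(p_enr), log10(p_dep))
  structure(list(
    cell_types = ct_names, regions = rg_names,
    universe_N = length(unique(as.character(universe))),
    overlap_k = k, p_enrichment = p_enr, p_depletion = p_dep,
    score = score,
    set_sizes = list(
      cell_types = stats::setNames(vapply(ct_sets, function(s)
        length(as_gene_ids(s)), 0L), ct_names),
      regions = stats::setNames(vapply(region_sets, function(s)
        length(as_gene_ids(s)), 0L), rg_names))
  ), class = "MIAResult")
}

#' @export
print.MIAResult <- function(x, ...) {
  cat(sprintf("MIAResult: %d cell types x %d regions, universe of %d genes\n",
              length(x$cell_types), length(x$regions), x$universe_N))
  print(round(x$score, 2))
  invisible(x)
}

#' Flatten an MIAResult to a long data.frame
#'
#' One row per (cell type, region) pair with overlap, raw and BH-adjusted
#' tail probabilities, and the signed score.
#'
#' @param x An `MIAResult`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.MIAResult <- function(x, ...) {
  grid <- expand.grid(cell_type = x$cell_types, region = x$regions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(
    grid,
    k = as.vector(x$overlap_k),
    p_enr = as.vector(x$p_enrichment),
    p_dep = as.vector(x$p_depletion),
    p_enr_adj = stats::p.adjust(as.vector(x$p_enrichment), "BH"),
    p_dep_adj = stats::p.adjust(as.vector(x$p_depletion), "BH"),
    score = as.vector(x$score),
    stringsAsFactors = FALSE
  )
  df[order(df$region, df$cell_type), , drop = FALSE]
}

#' Assign each region its best-matching cell type
#'
#' Per region, the cell type with the maximal signed MIA score. Regions
#' whose best score falls below `min_score` are labelled `"unassigned"`.
#' Score ties go to the lexicographically first cell type (logged).
#'
#' @param res An [mia_map()] result.
#' @param min_score Score floor for an assignment; default
#'   `-log10(0.05)` (enrichment p below 0.05).
#' @return data.frame with columns `region`, `cell_type`, `score`.
#' @export
assign_regions <- function(res, min_score = -log10(0.05)) {
  stopifnot(inherits(res, "MIAResult"))
  rows <- lapply(res$regions, function(rg) {
    sc <- res$score[, rg]
    best <- max(sc)
    winners <- sort(res$cell_types[sc == best])
    if (length(winners) > 1) {
      message(sprintf("assign_regions: score tie in region '%s' (%s); taking '%s'",
                      rg, paste(winners, collapse = ", "), winners[1]))
    }
    data.frame(region = rg,
               cell_type = if (best < min_score) "unassigned" else winners[1],
               score = best, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
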