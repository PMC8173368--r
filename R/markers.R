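# Per-group log-likelihood terms of the zero-inflated normal ("bimod")
# model, vectorized over genes. Each row of V is a gene; cols is the unit
# subset forming the group. The model: a value is 0 with probability 1 - pi,
# otherwise Normal(mu, sigma^2). MLEs: pi = fraction positive, mu/sigma the
# (population) moments of the positive values; sigma^2 floored at 1 when a
# group has fewer than 2 positives or zero variance, which prevents
# degenerate likelihoods.
.bimod_ll <- function(V, cols) {
  X <- V[, cols, drop = FALSE]
  n <- length(cols)
  pos <- X > 0
  npos <- rowSums(pos)
  s1 <- rowSums(X)
  s2 <- rowSums(X * X)
  pi_hat <- npos / n
  ll_zero <- ifelse(npos < n, (n - npos) * log1p(-pi_hat), 0)
  mu <- ifelse(npos > 0, s1 / npos, 0)
  v <- pmax(s2 / pmax(npos, 1) - mu^2, 0)
  sig2 <- ifelse(npos < 2 | v < 1e-10, 1, v)
  quad <- s2 - 2 * mu * s1 + npos * mu^2      # = sum (x - mu)^2 over positives
  ll_pos <- ifelse(npos > 0,
                   npos * log(pmax(pi_hat, .Machine$double.xmin)) -
                     npos / 2 * log(2 * pi * sig2) - quad / (2 * sig2),
                   0)
  ll_zero + ll_pos
}

# vectorized LRT over all genes (rows of V): group A columns vs group B
.bimod_lrt_matrix <- function(V, cols_a, cols_b) {
  ll_a <- .bimod_ll(V, cols_a)
  ll_b <- .bimod_ll(V, cols_b)
  ll_ab <- .bimod_ll(V, c(cols_a, cols_b))
  stat <- pmax(2 * (ll_a + ll_b - ll_ab), 0)
  all_zero <- rowSums(V[, c(cols_a, cols_b), drop = FALSE] > 0) == 0
  stat[all_zero] <- 0
  p <- stats::pchisq(stat, df = 3, lower.tail = FALSE)
  p[all_zero] <- 1
  list(stat = stat, p = p)
}

#' Bimodal likelihood-ratio test for differential expression
#'
#' Single-cell expression in each group is modelled as a mixture of a point
#' mass at zero (probability `1 - pi`) and a normal distribution on the
#' positive values. The statistic is twice the gap between the sum of the
#' two groups' maximized log-likelihoods and the pooled fit,
#' `2 * (L(A) + L(B) - L(A U B))`, referred to a chi-square distribution
#' with 3 degrees of freedom (the extra `pi`, `mu`, `sigma`). The MLE of
#' `sigma` is floored at 1 when a group has fewer than two positive values
#' or zero variance. If both groups are entirely zero the statistic is 0 and
#' p is 1.
#'
#' @param x,y Numeric vectors of normalized log-scale expression for the two
#'   groups; zeros are meaningful (undetected).
#' @return List with `stat` (>= 0) and `p` in \[0, 1\].
#' @export
#' @examples
#' bimod_lrt(c(0, 1.2, 1.4, 0, 1.3), c(2.5, 2.6, 2.4, 2.5, 0))
bimod_lrt <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both groups must contain at least one value", call. = FALSE)
  }
  V <- matrix(c(x, y), nrow = 1)
  r <- .bimod_lrt_matrix(V, seq_along(x), length(x) + seq_along(y))
  list(stat = unname(r$stat), p = unname(r$p))
}

#' Natural-log fold change of linear-scale means
#'
#' `ln((mean(2^x - 1) + 1) / (mean(2^y - 1) + 1))`: expression is
#' de-logged, group means taken on the linear scale, and a pseudo-mean of 1
#' keeps the ratio finite at zero means. The natural-log scale matches the
#' conventional marker-gate threshold of 0.1.
#'
#' @param x,y Numeric vectors of normalized log2 expression.
#' @return Scalar natural-log fold change (positive when `x` is higher).
#' @export
log_fold_change <- function(x, y) {
  log((mean(2^x - 1) + 1) / (mean(2^y - 1) + 1))
}

#' One-vs-rest marker detection with the bimodal LRT
#'
#' For each cluster, compares its units against all remaining units. Genes
#' are gated before testing: the detection fraction must reach `min_pct` in
#' at least one of the two groups, and the absolute natural-log fold change
#' must reach `logfc_threshold`. Benjamini-Hochberg adjustment is applied
#' within each cluster's tested set. Records are sorted by adjusted p, then
#' decreasing absolute fold change, then gene id.
#'
#' @param nm A [normalize_counts()] result.
#' @param ca A [cluster_assignment()] with at least 2 clusters.
#' @param logfc_threshold Minimum |log fold change| (natural log), default
#'   0.1.
#' @param min_pct Minimum detection fraction in the better-detected group,
#'   default 0.01.
#' @return A `MarkerTable`: data.frame with columns `gene`, `cluster`,
#'   `log_fc`, `p_value`, `p_adj`, `pct_in`, `pct_out`.
#' @export
find_all_markers <- function(nm, ca, logfc_threshold = 0.1, min_pct = 0.01) {
  stopifnot(inherits(nm, "NormalizedMatrix"), inherits(ca, "ClusterAssignment"))
  if (ca$k < 2) stop("marker detection needs at least 2 clusters", call. = FALSE)
  if (!setequal(ca$unit_ids, nm$unit_ids)) {
    stop("cluster assignment does not cover the matrix units", call. = FALSE)
  }
  V <- nm$values
  labels <- ca$labels[nm$unit_ids]
  lin <- 2^V - 1
  out <- list()
  for (cl in sort(unique(labels))) {
    in_idx <- which(labels == cl)
    out_idx <- which(labels != cl)
    if (length(in_idx) < 2) {
      warning(sprintf("cluster %d has fewer than 2 units; skipped", cl),
              call. = FALSE)
      next
    }
    pct_in <- rowMeans(V[, in_idx, drop = FALSE] > 0)
    pct_out <- rowMeans(V[, out_idx, drop = FALSE] > 0)
    log_fc <- log((rowMeans(lin[, in_idx, drop = FALSE]) + 1) /
                    (rowMeans(lin[, out_idx, drop = FALSE]) + 1))
    keep <- pmax(pct_in, pct_out) >= min_pct & abs(log_fc) >= logfc_threshold
    if (!any(keep)) next
    r <- .bimod_lrt_matrix(V[keep, , drop = FALSE], in_idx, out_idx)
    p_adj <- stats::p.adjust(r$p, method = "BH")
    df <- data.frame(gene = nm$gene_ids[keep], cluster = cl,
                     log_fc = unname(log_fc[keep]), p_value = unname(r$p),
                     p_adj = unname(p_adj),
                     pct_in = unname(pct_in[keep]),
                     pct_out = unname(pct_out[keep]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$p_adj, -abs(df$log_fc), df$gene), , drop = FALSE]
    out[[as.character(cl)]] <- df
  }
  res <- if (length(out) > 0) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(gene = character(), cluster = integer(),
                      log_fc = numeric(), p_value = numeric(),
                      p_adj = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("MarkerTable", "data.frame")
  res
}

#' Extract per-cluster marker gene sets from a MarkerTable
#'
#' Per cluster, the genes with adjusted p below `alpha` and (for
#' `direction = "up"`) positive log fold change — the gene sets consumed by
#' multimodal intersection analysis.
#'
#' @param mt A [find_all_markers()] table.
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @param direction `"up"` (higher in cluster) or `"down"`.
#' @return Named list of [gene_set()] objects, one per cluster present in
#'   the table (empty sets emitted with a warning).
#' @export
marker_sets <- function(mt, alpha = 0.05, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(mt, "data.frame"))
  clusters <- sort(unique(mt$cluster))
  sets <- lapply(clusters, function(cl) {
    rows <- mt$cluster == cl & mt$p_adj < alpha &
      (if (direction == "up") mt$log_fc > 0 else mt$log_fc < 0)
    genes <- mt$gene[rows]
    if (length(genes) == 0L) {
      warning(sprintf("cluster %s has no significant %s-regulated markers",
                      cl, direction), call. = FALSE)
    }
    gene_set(sprintf("cluster%s", cl), genes,
             sprintf("%s-regulated markers, p_adj < %g", direction, alpha))
  })
  stats::setNames(sets, sprintf("cluster%s", clusters))
}

#' Write a MarkerTable as TSV
#'
#' @param mt A [find_all_markers()] table.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return Invisibly, `path`.
#' @export
write_marker_table <- function(mt, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(mt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
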