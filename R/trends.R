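#' Call gradually up- and down-regulated genes across ordered stages
#'
#' A gene is "gradually up-regulated" when its per-stage mean normalized
#' expression increases strictly along the stated stage order (by more than
#' `epsilon` per step) and the first-vs-last-stage bimodal LRT is
#' significant after BH adjustment across all genes; "gradually
#' down-regulated" is symmetric. All other genes are left uncalled.
#'
#' @param nm A [normalize_counts()] result.
#' @param stages Factor of stage labels named by unit id (or a
#'   [cluster_assignment()]); factor level order defines the stage order and
#'   every stage needs at least 2 units.
#' @param alpha BH-adjusted significance cutoff for the extreme-stage test,
#'   default 0.05.
#' @param epsilon Minimum required per-step change in stage means, default 0
#'   (any strict change counts).
#' @return data.frame with one row per called gene: `gene`, `direction`
#'   (`up`/`down`), one `mean_<stage>` column per stage, and
#'   `p_adj_extremes`.
#' @export
gradual_genes <- function(nm, stages, alpha = 0.05, epsilon = 0) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (inherits(stages, "ClusterAssignment")) {
    lab <- stages$labels
    stages <- factor(lab, levels = sort(unique(lab)))
    names(stages) <- names(lab)
  }
  if (!is.factor(stages)) {
    stop("stages must be a factor whose level order is the stage order",
         call. = FALSE)
  }
  if (is.null(names(stages))) stop("stages must be named by unit id", call. = FALSE)
  stages <- stages[nm$unit_ids]
  lv <- levels(stages)
  if (length(lv) < 2) stop("need at least 2 ordered stages", call. = FALSE)
  sizes <- table(stages)
  if (any(sizes < 2)) {
    stop(sprintf("stage(s) with fewer than 2 units: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")), call. = FALSE)
  }
  V <- nm$values
  stage_means <- vapply(lv, function(s)
    rowMeans(V[, which(stages == s), drop = FALSE]), numeric(nrow(V)))
  diffs <- stage_means[, -1, drop = FALSE] - stage_means[, -length(lv), drop = FALSE]
  up <- apply(diffs > epsilon, 1, all)
  down <- apply(diffs < -epsilon, 1, all)
  first <- which(stages == lv[1])
  last <- which(stages == lv[length(lv)])
  lrt <- .bimod_lrt_matrix(V, first, last)
  p_adj <- stats::p.adjust(lrt$p, method = "BH")
  called <- (up | down) & p_adj < alpha
  if (!any(called)) {
    out <- data.frame(gene = character(), direction = character(),
                      stringsAsFactors = FALSE)
    for (s in lv) out[[paste0("mean_", s)]] <- numeric()
    out$p_adj_extremes <- numeric()
    return(out)
  }
  out <- data.frame(gene = nm$gene_ids[called],
                    direction = ifelse(up[called], "up", "down"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lv)) out[[paste0("mean_", lv[i])]] <- stage_means[called, i]
  out$p_adj_extremes <- p_adj[called]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced-subsample PCA across ordered stages
#'
#' Draws `n_per_group` units from every stage ([balanced_subsample()]) and
#' projects the centered, unscaled log2 expression of the sampled units onto
#' the top two principal components. Component signs are canonicalized so
#' the largest-magnitude loading of each component is positive, making
#' outputs comparable across runs.
#'
#' @param nm A [normalize_counts()] result.
#' @param stages Factor of stage labels named by unit id.
#' @param n_per_group Units sampled per stage, default 50.
#' @param seed Integer seed for the subsample.
#' @param genes Optional [gene_set()] or gene id vector to restrict to (e.g.
#'   [select_variable_genes()] output); default all genes.
#' @return data.frame with columns `unit_id`, `stage`, `PC1`, `PC2`;
#'   attribute `"sdev"` carries the component standard deviations.
#' @export
balanced_stage_pca <- function(nm, stages, n_per_group = 50, seed = 1L,
                               genes = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (is.null(names(stages))) stop("stages must be named by unit id", call. = FALSE)
  ids <- balanced_subsample(stages, n_per_group, seed)
  gsel <- if (is.null(genes)) nm$gene_ids else
    intersect(as_gene_ids(genes), nm$gene_ids)
  X <- t(nm$values[gsel, ids, drop = FALSE])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  for (j in 1:2) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  out <- data.frame(unit_id = ids,
                    stage = as.character(stages[ids]),
                    PC1 = unname(pc$x[, 1]), PC2 = unname(pc$x[, 2]),
                    stringsAsFactors = FALSE)
  attr(out, "sdev") <- pc$sdev[1:2]
  out
}
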