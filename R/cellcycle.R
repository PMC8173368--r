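#' Gene-set-average cell-cycle scores
#'
#' The G1/S and G2/M scores of a unit are the arithmetic means of its
#' normalized (log2) expression over the genes of each set that are present
#' in the matrix; missing genes are dropped with a logged count.
#'
#' @param nm A [normalize_counts()] result.
#' @param g1s,g2m [gene_set()]s (or character vectors) for the G1/S and
#'   G2/M programs; the packaged defaults have 43 and 54 genes
#'   ([default_cell_cycle_sets()]).
#' @return data.frame with columns `unit_id`, `s_g1s`, `s_g2m`.
#' @export
cc_scores <- function(nm, g1s = default_cell_cycle_sets()$G1S,
                      g2m = default_cell_cycle_sets()$G2M) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  score_one <- function(set, label) {
    ids <- as_gene_ids(set)
    present <- ids[ids %in% nm$gene_ids]
    missing <- length(ids) - length(present)
    if (length(present) == 0L) {
      stop(sprintf("no %s set genes present in the matrix", label), call. = FALSE)
    }
    if (missing > 0) {
      message(sprintf("cc_scores: %d of %d %s genes absent from the matrix",
                      missing, length(ids), label))
    }
    colMeans(nm$values[present, , drop = FALSE])
  }
  data.frame(unit_id = nm$unit_ids,
             s_g1s = unname(score_one(g1s, "G1/S")),
             s_g2m = unname(score_one(g2m, "G2/M")),
             stringsAsFactors = FALSE)
}

#' Quiescent / proliferative cell-cycle classification
#'
#' A cell with both scores strictly below `threshold` is quiescent
#' (`G1_quiescent`). Otherwise it is proliferative and assigned the phase
#' with the larger score: `G2M` when the G1/S score is below the G2/M
#' score, `G1S` when the G2/M score is below the G1/S score. An exact tie
#' between the two scores of a proliferative cell goes to `G1S` (logged).
#'
#' @param scores A [cc_scores()] data.frame.
#' @param threshold Score threshold for quiescence, on the same log2
#'   normalized scale as the scores; default 2.
#' @return The input data.frame with an added `label` column (factor with
#'   levels `G1_quiescent`, `G1S`, `G2M`).
#' @export
cc_classify <- function(scores, threshold = 2) {
  stopifnot(all(c("unit_id", "s_g1s", "s_g2m") %in% names(scores)))
  quiescent <- scores$s_g1s < threshold & scores$s_g2m < threshold
  label <- ifelse(quiescent, "G1_quiescent",
                  ifelse(scores$s_g1s < scores$s_g2m, "G2M", "G1S"))
  ties <- !quiescent & scores$s_g1s == scores$s_g2m
  if (any(ties)) {
    message(sprintf("cc_classify: %d proliferative score tie(s) assigned G1S",
                    sum(ties)))
  }
  scores$label <- factor(label, levels = c("G1_quiescent", "G1S", "G2M"))
  scores
}

#' Per-cluster cell-cycle phase fractions
#'
#' @param calls A [cc_classify()] data.frame covering all clustered units.
#' @param ca A [cluster_assignment()] (or named vector of group labels).
#' @return data.frame with one row per cluster: fractions `g1`, `g1s`,
#'   `g2m` (summing to 1) and `proliferative` (= g1s + g2m), plus
#'   `n_units`.
#' @export
phase_fractions <- function(calls, ca) {
  labels <- if (inherits(ca, "ClusterAssignment")) ca$labels else ca
  if (!all(names(labels) %in% calls$unit_id)) {
    stop("cell-cycle calls do not cover all clustered units", call. = FALSE)
  }
  call_of <- stats::setNames(as.character(calls$label), calls$unit_id)
  groups <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  rows <- lapply(groups, function(g) {
    ids <- names(labels)[labels == g]
    tab <- table(factor(call_of[ids], levels = c("G1_quiescent", "G1S", "G2M")))
    fr <- as.numeric(tab) / length(ids)
    data.frame(cluster = g, n_units = length(ids),
               g1 = fr[1], g1s = fr[2], g2m = fr[3],
               proliferative = fr[2] + fr[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
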