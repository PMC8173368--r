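# Independent oracles and small fixture builders shared across tests.

# Numerically maximized log-likelihood of the zero-inflated normal model,
# independent of the package's closed-form MLE path. Only valid for groups
# with both zeros and at least two distinct positive values (interior
# optimum).
oracle_zin_ll <- function(v) {
  pos <- v[v > 0]
  n <- length(v)
  k <- length(pos)
  stopifnot(k >= 2, k < n)
  nll <- function(th) {
    p <- 1 / (1 + exp(-th[1]))
    sig <- exp(th[3])
    -((n - k) * log(1 - p) + k * log(p) +
        sum(stats::dnorm(pos, th[2], sig, log = TRUE)))
  }
  best <- Inf
  for (mu0 in c(mean(pos), stats::median(pos))) {
    for (ls0 in c(-3, -1, 0)) {
      r <- stats::optim(c(log(k / (n - k)), mu0, ls0), nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-15))
      best <- min(best, r$value)
    }
  }
  -best
}

oracle_bimod <- function(x, y) {
  stat <- 2 * (oracle_zin_ll(x) + oracle_zin_ll(y) - oracle_zin_ll(c(x, y)))
  list(stat = stat, p = stats::pchisq(stat, df = 3, lower.tail = FALSE))
}

# Hypergeometric tail probabilities by direct combinatorial summation.
oracle_hyper <- function(N, K, n, k) {
  j <- max(0, K + n - N):min(K, n)
  pj <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  list(p_enr = sum(pj[j >= k]), p_dep = sum(pj[j <= k]))
}

# Literal enumeration of every size-n draw from an N-gene universe; only
# feasible for small N.
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)  # treat genes 1..K as set A
  list(p_enr = mean(overlap >= k), p_dep = mean(overlap <= k))
}

# Wrap a dense values matrix as a NormalizedMatrix for direct unit tests.
make_nm <- function(values, unit_kind = "cell", scale_target = NA_real_) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("u%03d", seq_len(ncol(values)))
  }
  structure(list(values = values, gene_ids = rownames(values),
                 unit_ids = colnames(values), unit_kind = unit_kind,
                 scale_target = scale_target),
            class = "NormalizedMatrix")
}

# CountMatrix with a prescribed number of detected genes per unit.
make_cm_detected <- function(detected, n_genes, unit_kind = "spot",
                             gene_ids = sprintf("g%04d", seq_len(n_genes))) {
  counts <- sapply(detected, function(d) c(rep(1L, d), rep(0L, n_genes - d)))
  count_matrix(counts, gene_ids, sprintf("u%03d", seq_along(detected)),
               unit_kind)
}

# Small synthetic params for fast unit tests (no QC failures planted).
quick_params <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 600, n_groups = 3, units_per_group = 60,
                   markers_per_group = 30, frac_low_quality = 0,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_params, args)
}

# Majority-vote mapping of inferred cluster labels to planted group labels.
majority_map <- function(labels, truth) {
  vapply(sort(unique(labels)), function(cl)
    as.integer(names(which.max(table(truth[labels == cl])))), integer(1))
}
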