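#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library code never perturbs user-level
#' randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit polynomial hash of a config list, for provenance
# headers. Not cryptographic; stable across sessions and platforms.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  b <- utf8ToInt(as.character(s))
  h <- 7
  m <- 2147483647
  for (v in b) h <- (h * 31 + v) %% m
  sprintf("%08x", h)
}

# round half-up to `digits` decimals (R's round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}
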