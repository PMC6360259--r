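# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic package code funnels through this so that
# results are reproducible from explicit seeds only.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Number of unordered gene pairs evaluated by the all-pairs correlation
# stage for n genes.
#' Number of distinct gene pairs for an n-gene network
#'
#' The all-pairs correlation stage of the network build evaluates
#' `n * (n - 1) / 2` unordered pairs; this helper is the single source of
#' that stage counter.
#'
#' @param nGenes number of genes (non-negative integer).
#' @return the pair count as a double (may exceed the integer range).
#' @examples
#' pairCount(10)
#' @export
pairCount <- function(nGenes) {
  stopifnot(is.numeric(nGenes), length(nGenes) == 1L, nGenes >= 0)
  n <- as.numeric(nGenes)
  n * (n - 1) / 2
}

# -log10 with the flooring/capping used for heatmap-bound significance
# values: p floored at 1e-300, result floored at 0 and capped at 300.
negLog10 <- function(p, cap = 300) {
  out <- -log10(pmax(p, 1e-300))
  pmin(pmax(out, 0), cap)
}

assertCharacterSet <- function(x, what) {
  if (!is.character(x)) stop(sprintf("'%s' must be a character vector", what))
  unique(x)
}
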