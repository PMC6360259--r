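#' @include AllClasses.R
NULL

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` successes in a draw of `n` from a population of `N`
#' containing `K` successes. For module enrichment the draw is the gene
#' list, the successes are the signature genes and the population is the
#' genes present on the platform. Computed exactly via
#' [stats::phyper()].
#'
#' @param k observed overlap, `0 <= k <= min(n, K)`.
#' @param n draw size (gene-list size).
#' @param K successes in the population (signature size on the platform).
#' @param N population size.
#' @return upper-tail probability in `[0, 1]`.
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
  if (any(k < 0) || any(n > N) || any(K > N) || any(k > pmin(n, K)))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric lower tail, P(X <= k) — depletion significance
#' @inheritParams hypergeomUpperTail
#' @export
hypergeomLowerTail <- function(k, n, K, N) {
  if (any(k < 0) || any(n > N) || any(K > N) || any(k > pmin(n, K)))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K) <= N")
  phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Benjamini--Hochberg step-up FDR
#'
#' Order-preserving wrapper over [stats::p.adjust()] with input
#' validation; output dominates the input element-wise and is capped
#' at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values, same order as input.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric signature enrichment of modules
#'
#' Tests every (module, signature) pair for over-representation (or
#' depletion) of signature genes among the module's genes, against a
#' finite gene population. Signature sizes are computed after
#' intersection with the population; signatures outside
#' `[minSize, maxSize]` are excluded before testing. BH correction is
#' applied across all tested pairs of the call, then rows are filtered
#' to FDR below `fdrThreshold` keeping at most `top` signatures per
#' module (most significant first). The display defaults (FDR < 0.1,
#' sizes 5--1500, top 30) match the module-heatmap filtering rules; pass
#' `fdrThreshold = 1, top = Inf` for the unfiltered table.
#'
#' @param partition a [Partition-class] (or named gene -> module vector).
#' @param signatures a [SignatureSet-class].
#' @param population character vector: the gene universe (must contain
#'   every module gene).
#' @param minSize,maxSize signature size bounds after intersection with
#'   the population (inclusive).
#' @param fdrThreshold keep rows with FDR strictly below this.
#' @param top maximum signatures reported per module.
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower
#'   tail).
#' @return data.frame with columns module, signature, overlap,
#'   module_size, signature_size, population_size, p, fdr, direction,
#'   neg_log10_fdr (floored at 1e-300 before the log).
#' @export
enrichModules <- function(partition, signatures, population,
                          minSize = 5, maxSize = 1500,
                          fdrThreshold = 0.1, top = 30,
                          direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  mem <- if (is(partition, "Partition")) moduleAssignments(partition)
         else partition
  population <- unique(as.character(population))
  if (!length(population)) stop("empty population")
  outside <- setdiff(names(mem), population)
  if (length(outside))
    stop("module gene(s) outside the population: ",
         paste(utils::head(outside, 10), collapse = ", "))
  modules <- split(names(mem), mem)
  if (any(lengths(modules) == 0L)) stop("empty module")
  sets <- lapply(signatureSets(signatures),
                 function(g) intersect(g, population))
  sizes <- lengths(sets)
  keep <- sizes >= minSize & sizes <= maxSize
  sets <- sets[keep]
  if (!length(sets) || !length(modules))
    return(data.frame(module = character(), signature = character(),
                      overlap = integer(), module_size = integer(),
                      signature_size = integer(),
                      population_size = integer(), p = numeric(),
                      fdr = numeric(), direction = character(),
                      neg_log10_fdr = numeric()))
  N <- length(population)
  grid <- expand.grid(module = names(modules), signature = names(sets),
                      stringsAsFactors = FALSE)
  ov <- mapply(function(m, s) length(intersect(modules[[m]], sets[[s]])),
               grid$module, grid$signature)
  n <- lengths(modules)[grid$module]
  K <- lengths(sets)[grid$signature]
  p <- if (direction == "enriched") hypergeomUpperTail(ov, n, K, N)
       else hypergeomLowerTail(ov, n, K, N)
  fdr <- bhFdr(p)
  tab <- data.frame(module = grid$module, signature = grid$signature,
                    overlap = as.integer(ov), module_size = as.integer(n),
                    signature_size = as.integer(K), population_size = N,
                    p = p, fdr = fdr, direction = direction,
                    neg_log10_fdr = negLog10(fdr),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[tab$fdr < fdrThreshold, , drop = FALSE]
  tab <- tab[order(tab$module, tab$p, tab$signature, method = "radix"), ]
  if (is.finite(top)) {
    keepRow <- unlist(lapply(split(seq_len(nrow(tab)), tab$module),
                             utils::head, n = top), use.names = FALSE)
    tab <- tab[sort(keepRow), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
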