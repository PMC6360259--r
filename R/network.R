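#' @include AllClasses.R
NULL

#' All-pairs Spearman correlation matrix
#'
#' Computes Spearman rank correlations (average ranks for ties) between
#' every pair of gene rows across all samples of the experiment,
#' evaluating `n * (n - 1) / 2` distinct pairs. Constant rows, whose
#' rank correlation is undefined, are dropped beforehand with a warning.
#'
#' @param x a [GeneExperiment-class] (or a plain genes-by-samples
#'   numeric matrix) with at least 3 samples.
#' @return symmetric correlation matrix with unit diagonal, one
#'   row/column per retained gene.
#' @export
spearmanAllPairs <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) assay(x, "exprs") else as.matrix(x)
  if (ncol(m) < 3L) stop("need at least 3 samples for rank correlations")
  const <- apply(m, 1L, function(r) diff(range(r)) == 0)
  if (any(const)) {
    warning(sum(const), " constant gene row(s) dropped before correlation: ",
            paste(utils::head(rownames(m)[const], 5), collapse = ", "))
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 non-constant genes")
  cor(t(m), method = "spearman")
}

#' Retain the top-k most correlated partners per gene
#'
#' The parsimony step: for each gene, partners are ranked by descending
#' correlation among the strictly positive entries of its row
#' (see Details for `ranking = "absolute"`), the k best
#' are kept (ties at the k-th rank broken by lexicographically smaller
#' partner id), and the per-gene choices are unioned — i.e. the matrix is
#' symmetrized by setting m_ij = m_ji — giving an undirected weighted
#' graph. A gene with no positive partner stays in the graph as an
#' isolated node. When every node has at least k positive partners the
#' retained undirected edge count lies in `[ceil(k*n/2), k*n]`.
#'
#' @details With `ranking = "absolute"` partners are ordered by |rho| but
#'   an edge is still only retained when rho > 0, keeping modularity
#'   well-defined on non-negative weights.
#'
#' @param rho symmetric correlation matrix with unit diagonal (from
#'   [spearmanAllPairs()]).
#' @param k edges contributed per gene (default 3).
#' @param ranking rank partners by signed rho (default) or |rho|.
#' @return a [CorrelationGraph-class]; its counters record the genes,
#'   the `n*(n-1)/2` pairs evaluated and the edges retained.
#' @export
retainTopKEdges <- function(rho, k = 3, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(rho)
  if (is.null(rownames(rho))) stop("correlation matrix must carry gene names")
  if (!isTRUE(all.equal(rho, t(rho), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  genes <- rownames(rho)
  if (k >= n)
    message("k >= number of genes; all positive edges retained")
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rho[i, ]
    r[i] <- NA_real_
    pos <- which(!is.na(r) & r > 0)
    if (!length(pos)) next
    key <- if (ranking == "signed") r[pos] else abs(r[pos])
    ord <- pos[order(-key, genes[pos], method = "radix")]
    top <- utils::head(ord, k)
    pairs[[i]] <- cbind(pmin(i, top), pmax(i, top))
  }
  ep <- unique(do.call(rbind, pairs))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- genes
  if (!is.null(ep) && nrow(ep)) {
    w <- rho[ep]
    g <- igraph::add_edges(g, t(ep), weight = pmin(w, 1))
  }
  new("CorrelationGraph", graph = g, k = k, nGenes = n,
      nPairsTotal = pairCount(n),
      nEdgesRetained = as.integer(igraph::ecount(g)))
}

#' Build the sparsified co-expression graph from a gene matrix
#'
#' Convenience composition of [spearmanAllPairs()] and
#' [retainTopKEdges()].
#'
#' @inheritParams spearmanAllPairs
#' @inheritParams retainTopKEdges
#' @return a [CorrelationGraph-class].
#' @export
buildNetwork <- function(x, k = 3, ranking = "signed") {
  retainTopKEdges(spearmanAllPairs(x), k = k, ranking = ranking)
}
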