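#' @include AllClasses.R
NULL

#' Accessors for pgcna classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x,object a pgcna object.
#' @name accessors
NULL

#' @describeIn accessors gene sets of a [SignatureSet-class] as a named list.
#' @export
signatureSets <- function(x) {
  stopifnot(is(x, "SignatureSet"))
  x@sets
}

#' @describeIn accessors signature names.
#' @export
signatureNames <- function(x) names(signatureSets(x))

#' @describeIn accessors number of signatures.
#' @export
setMethod("length", "SignatureSet", function(x) length(x@sets))

#' @describeIn accessors extract signatures by name or index.
#' @param i index or name.
#' @export
setMethod("[[", "SignatureSet", function(x, i) x@sets[[i]])

#' @describeIn accessors the underlying [igraph::igraph] of a
#'   [CorrelationGraph-class].
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "CorrelationGraph"))
  x@graph
}

#' @describeIn accessors node (gene) names of a graph.
#' @export
graphNodes <- function(x) igraph::V(asIgraph(x))$name

#' @describeIn accessors stage counters of a graph as a list with elements
#'   `n_genes`, `n_pairs_total`, `n_edges_retained`, `k`.
#' @export
networkStats <- function(x) {
  stopifnot(is(x, "CorrelationGraph"))
  list(n_genes = x@nGenes, n_pairs_total = x@nPairsTotal,
       n_edges_retained = x@nEdgesRetained, k = x@k)
}

#' @describeIn accessors gene -> module label vector of a [Partition-class].
#' @export
moduleAssignments <- function(x) {
  stopifnot(is(x, "Partition"))
  x@membership
}

#' @describeIn accessors modularity Q of a partition.
#' @export
modularityScore <- function(x) {
  stopifnot(is(x, "Partition"))
  x@modularity
}

#' @describeIn accessors module sizes, named by module label, in label order.
#' @export
moduleSizes <- function(x) {
  m <- moduleAssignments(x)
  tab <- table(m)
  lab <- names(tab)
  ord <- order(as.integer(sub("^M", "", lab)))
  out <- as.integer(tab[ord])
  names(out) <- lab[ord]
  out
}

#' @describeIn accessors genes of one module.
#' @param module module label such as `"M1"`.
#' @export
moduleGenes <- function(x, module) {
  m <- moduleAssignments(x)
  names(m)[m == module]
}

#' @describeIn accessors retained partitions of an [EnsembleResult-class].
#' @export
ensemblePartitions <- function(x) {
  stopifnot(is(x, "EnsembleResult"))
  x@partitions
}

#' @describeIn accessors per-run summary table of an ensemble
#'   (`run`, `seed`, `Q`, `nModules`).
#' @export
ensembleSummary <- function(x) {
  stopifnot(is(x, "EnsembleResult"))
  x@summary
}

#' @describeIn accessors -log10 p matrix of an [OverlapMatrix-class].
#' @export
overlapSignificance <- function(x) {
  stopifnot(is(x, "OverlapMatrix"))
  x@neglog10p
}

#' @describeIn accessors raw overlap counts of an [OverlapMatrix-class].
#' @export
overlapCounts <- function(x) {
  stopifnot(is(x, "OverlapMatrix"))
  x@counts
}

#' @describeIn accessors probe-level experiment of a
#'   [SyntheticDataset-class].
#' @export
syntheticExpr <- function(x) { stopifnot(is(x, "SyntheticDataset")); x@expr }

#' @describeIn accessors probe -> gene annotation table.
#' @export
syntheticAnnotation <- function(x) { stopifnot(is(x, "SyntheticDataset")); x@annotation }

#' @describeIn accessors planted gene -> module partition (nulls `"M0"`).
#' @export
truePartition <- function(x) { stopifnot(is(x, "SyntheticDataset")); x@truePartition }

#' @describeIn accessors noiseless gene-by-group expression surface.
#' @export
noiselessProfile <- function(x) { stopifnot(is(x, "SyntheticDataset")); x@noiseless }

#' @describeIn accessors true differential gene sets per condition/timepoint.
#' @export
trueDESets <- function(x) { stopifnot(is(x, "SyntheticDataset")); x@trueDE }

#' @describeIn accessors planted [SignatureSet-class].
#' @export
plantedSignatureSet <- function(x) { stopifnot(is(x, "SyntheticDataset")); x@signatures }

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet with", length(object@sets), "signature(s)\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", min(sz), "-", max(sz), "genes\n")
  }
})

setMethod("show", "CorrelationGraph", function(object) {
  cat("CorrelationGraph:", object@nGenes, "genes,",
      object@nEdgesRetained, "retained edges (k =", object@k, ")\n")
  cat("  pairs evaluated:", format(object@nPairsTotal, big.mark = ","), "\n")
})

setMethod("show", "Partition", function(object) {
  sz <- moduleSizes(object)
  cat("Partition:", length(object@membership), "genes in", length(sz),
      "module(s), Q =", format(object@modularity, digits = 6), "\n")
  cat("  sizes:", paste(utils::head(paste0(names(sz), "=", sz), 10),
                        collapse = " "),
      if (length(sz) > 10) "..." else "", "\n")
})

setMethod("show", "EnsembleResult", function(object) {
  qs <- vapply(object@partitions, modularityScore, numeric(1))
  cat("EnsembleResult:", object@kept, "of", object@nRuns,
      "Louvain runs retained (baseSeed =", object@baseSeed, ")\n")
  if (length(qs))
    cat("  Q range:", format(max(qs), digits = 6), "to",
        format(min(qs), digits = 6), "\n")
})

setMethod("show", "OverlapMatrix", function(object) {
  cat("OverlapMatrix:", nrow(object@counts), "x", ncol(object@counts),
      "set pairs over a population of", object@population, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nrow(object@expr), "probes,",
      nrow(object@noiseless), "genes,", ncol(object@expr), "samples\n")
  sz <- moduleSizes(object@truePartition)
  cat("  planted modules:", sum(names(sz) != "M0"),
      "(plus", if ("M0" %in% names(sz)) sz[["M0"]] else 0, "null genes)\n")
})
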