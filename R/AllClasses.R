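#' @include pgcna-package.R
NULL

setOldClass("igraph")

#' Probe-level expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' probes-by-samples matrix of log2 expression intensities (assay
#' `"exprs"`) together with the per-sample design: donor, condition,
#' timepoint label and an explicit integer time ordering (`time_order`),
#' so that labels such as `"d6+24h"` need no parsing. Values are expected
#' to be already normalized and log2 transformed.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("ProbeExperiment", contains = "SummarizedExperiment")

.requiredSampleFields <- c("donor", "condition", "timepoint", "time_order")

.validExperiment <- function(object, idWhat) {
  msg <- character()
  v <- assay(object, "exprs")
  ids <- rownames(object)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, sprintf("%s ids must be non-empty", idWhat))
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicated %s id(s): %s", idWhat,
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  sids <- colnames(object)
  if (is.null(sids) || anyDuplicated(sids))
    msg <- c(msg, "sample ids must be present and unique")
  if (!is.numeric(v) || any(!is.finite(v)))
    msg <- c(msg, "expression values must all be finite numbers")
  missingCols <- setdiff(.requiredSampleFields, colnames(colData(object)))
  if (length(missingCols))
    msg <- c(msg, paste("missing sample metadata column(s):",
                        paste(missingCols, collapse = ", ")))
  if ("time_order" %in% colnames(colData(object)) &&
      any(!is.finite(colData(object)$time_order)))
    msg <- c(msg, "time_order must be finite numeric ranks")
  if (length(msg)) msg else TRUE
}

setValidity("ProbeExperiment", function(object) .validExperiment(object, "probe"))

#' Gene-level expression experiment
#'
#' Produced by [mergeProbesToGenes()]: one row per gene symbol, with the
#' representative probe recorded in `rowData(x)$probe_id` as provenance.
#' Shares the sample metadata contract of [ProbeExperiment-class].
#'
#' @export
setClass("GeneExperiment", contains = "SummarizedExperiment")

setValidity("GeneExperiment", function(object) {
  res <- .validExperiment(object, "gene")
  msg <- if (isTRUE(res)) character() else res
  if (!"probe_id" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must record the representative 'probe_id' per gene")
  if (length(msg)) msg else TRUE
})

#' Gene signature collection
#'
#' Named gene sets (signature name -> character vector of gene symbols),
#' optionally tagged with a source collection per signature, as read from
#' a GMT file by [readGMT()].
#'
#' @slot sets named list of character vectors (unique names, non-empty sets).
#' @slot collection character vector parallel to `sets` (may be empty).
#' @export
setClass("SignatureSet",
         representation(sets = "list", collection = "character"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
      msg <- c(msg, "signature names must be present and unique")
    if (!all(vapply(s, function(g) is.character(g) && length(g) > 0, logical(1))))
      msg <- c(msg, "every signature must be a non-empty character vector")
  }
  if (length(object@collection) && length(object@collection) != length(s))
    msg <- c(msg, "collection labels must match the number of signatures")
  if (length(msg)) msg else TRUE
})

#' @rdname SignatureSet-class
#' @param sets named list of character vectors of gene symbols.
#' @param collection optional per-signature source-collection labels.
#' @export
SignatureSet <- function(sets = list(), collection = character()) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  new("SignatureSet", sets = sets, collection = as.character(collection))
}

#' Sparsified co-expression graph
#'
#' The symmetrized top-k Spearman correlation graph: an undirected
#' weighted graph over gene symbols in which each gene contributed its k
#' most positively correlated partners, with stage counters recording the
#' number of genes, the number of distinct pairs evaluated
#' (`n * (n-1) / 2`) and the number of undirected edges retained.
#'
#' @slot graph an [igraph::igraph] object (undirected, weighted, no loops).
#' @slot k integer; edges contributed per gene.
#' @slot nGenes integer; number of nodes.
#' @slot nPairsTotal double; pairs evaluated by the correlation stage.
#' @slot nEdgesRetained integer; undirected edges kept after symmetrization.
#' @export
setClass("CorrelationGraph",
         representation(graph = "igraph", k = "integer", nGenes = "integer",
                        nPairsTotal = "numeric", nEdgesRetained = "integer"))

setValidity("CorrelationGraph", function(object) {
  msg <- character()
  g <- object@graph
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "graph must not contain self-loops")
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) > 0 && (is.null(w) || any(!is.finite(w)) || any(w <= 0) || any(w > 1)))
    msg <- c(msg, "edge weights must lie in (0, 1]")
  if (object@nGenes != igraph::vcount(g))
    msg <- c(msg, "nGenes counter disagrees with the graph")
  if (object@nEdgesRetained != igraph::ecount(g))
    msg <- c(msg, "nEdgesRetained counter disagrees with the graph")
  if (length(msg)) msg else TRUE
})

#' Module partition of a network
#'
#' A gene -> module assignment with its weighted Newman--Girvan
#' modularity. Module labels are `"M1"`, `"M2"`, ... ordered by
#' non-increasing module size ([relabelPartition()] enforces this).
#'
#' @slot membership named character vector, gene -> module label.
#' @slot modularity modularity score Q of the assignment on its graph.
#' @export
setClass("Partition",
         representation(membership = "character", modularity = "numeric"))

setValidity("Partition", function(object) {
  msg <- character()
  m <- object@membership
  if (length(m)) {
    if (is.null(names(m)) || anyDuplicated(names(m)))
      msg <- c(msg, "membership must be named by unique gene ids")
    if (anyNA(m) || any(m == ""))
      msg <- c(msg, "every gene must carry a module label")
  }
  q <- object@modularity
  if (length(q) != 1L || (!is.na(q) && (q < -0.5 - 1e-9 || q > 1 + 1e-9)))
    msg <- c(msg, "modularity must be a single value in [-0.5, 1] (or NA if unset)")
  if (length(msg)) msg else TRUE
})

#' @rdname Partition-class
#' @param membership named character vector of module labels.
#' @param modularity modularity score Q.
#' @export
Partition <- function(membership, modularity = NA_real_) {
  new("Partition", membership = membership, modularity = as.numeric(modularity))
}

#' Louvain ensemble result
#'
#' The retained best-by-modularity partitions from an ensemble of seeded
#' Louvain runs, ordered by non-increasing Q (ties broken by run index).
#'
#' @slot partitions list of [Partition-class], Q non-increasing.
#' @slot nRuns total Louvain runs performed.
#' @slot kept number of partitions retained.
#' @slot baseSeed first seed of the consecutive seed sequence.
#' @slot summary data.frame with one row per retained run:
#'   `run`, `seed`, `Q`, `nModules`.
#' @export
setClass("EnsembleResult",
         representation(partitions = "list", nRuns = "integer",
                        kept = "integer", baseSeed = "integer",
                        summary = "data.frame"))

setValidity("EnsembleResult", function(object) {
  msg <- character()
  if (object@kept > object@nRuns) msg <- c(msg, "kept must be <= nRuns")
  if (length(object@partitions) != object@kept)
    msg <- c(msg, "number of stored partitions must equal 'kept'")
  qs <- vapply(object@partitions, function(p) p@modularity, numeric(1))
  if (length(qs) > 1 && any(diff(qs) > 1e-12))
    msg <- c(msg, "partitions must be ordered by non-increasing modularity")
  if (length(msg)) msg else TRUE
})

#' Pairwise overlap significance matrix
#'
#' Hypergeometric overlap significance between two families of sets
#' (modules of two networks, or differential-expression sets), stored as
#' raw overlap counts and -log10 p values (floored at 0, capped at 300).
#'
#' @slot neglog10p numeric matrix of -log10 upper-tail p values.
#' @slot counts integer matrix of raw overlap sizes.
#' @slot population size of the universe the test was performed against.
#' @export
setClass("OverlapMatrix",
         representation(neglog10p = "matrix", counts = "matrix",
                        population = "numeric"))

setValidity("OverlapMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@neglog10p), dim(object@counts)))
    msg <- c(msg, "significance and count matrices must share dimensions")
  if (any(object@neglog10p < 0) || any(!is.finite(object@neglog10p)))
    msg <- c(msg, "-log10 p entries must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Synthetic time-course dataset with planted structure
#'
#' Output of [simulateTimecourse()]: a probe-level experiment plus the
#' ground truth it was generated from (gene -> module partition with null
#' genes labelled `"M0"`, the noiseless gene-by-group expression surface,
#' per-(condition, timepoint) true differential sets, and planted module
#' signatures with decoys).
#'
#' @slot expr [ProbeExperiment-class] of simulated probe intensities.
#' @slot annotation data.frame with columns `probe_id`, `gene`.
#' @slot truePartition [Partition-class]; planted gene modules, nulls `"M0"`.
#' @slot noiseless genes-by-groups matrix of noise-free expression.
#' @slot groups data.frame describing the group columns
#'   (`condition`, `timepoint`, `time_order`).
#' @slot trueDE nested list: condition -> timepoint -> list(induced, repressed).
#' @slot signatures [SignatureSet-class]; one exact signature per planted
#'   module plus random decoy sets.
#' @slot config the [simConfig()] list the dataset was generated from.
#' @export
setClass("SyntheticDataset",
         representation(expr = "ProbeExperiment", annotation = "data.frame",
                        truePartition = "Partition", noiseless = "matrix",
                        groups = "data.frame", trueDE = "list",
                        signatures = "SignatureSet", config = "list"))
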