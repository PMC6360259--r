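#' @include AllClasses.R
NULL

# Internal edge-list view of a CorrelationGraph: 1-based endpoint indices
# (a <= b, no self-loops at this stage), weights, node names.
.graphEdges <- function(graph) {
  g <- if (is(graph, "CorrelationGraph")) asIgraph(graph) else graph
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  list(n = igraph::vcount(g),
       a = pmin(el[, 1], el[, 2]), b = pmax(el[, 1], el[, 2]),
       w = as.numeric(w), names = igraph::V(g)$name)
}

#' Weighted Newman--Girvan modularity of a partition
#'
#' Q = (1/2W) * sum_ij (w_ij - s_i s_j / 2W) delta(c_i, c_j), with W the
#' total edge weight and s_i the weighted degree of node i.
#'
#' @param graph a [CorrelationGraph-class].
#' @param partition a [Partition-class] covering every graph node (extra
#'   genes are ignored).
#' @return modularity Q in `[-0.5, 1]`.
#' @export
graphModularity <- function(graph, partition) {
  e <- .graphEdges(graph)
  mem <- moduleAssignments(partition)
  missing <- setdiff(e$names, names(mem))
  if (length(missing))
    stop("partition does not cover graph node(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  W <- sum(e$w)
  if (W <= 0) stop("graph has zero total edge weight; modularity undefined")
  comm <- match(mem[e$names], unique(mem[e$names]))
  deg <- numeric(e$n)
  agg <- rowsum(c(e$w, e$w), c(e$a, e$b))
  deg[as.integer(rownames(agg))] <- agg[, 1]
  tot <- rowsum(deg, comm)
  within <- e$w[comm[e$a] == comm[e$b]]
  sum(within) / W - sum((tot / (2 * W))^2)
}

# One Louvain level: local moving on the (possibly aggregated) graph.
# Edges: a/b/w with a <= b; a == b are self-loops carrying the internal
# weight of an aggregated community (contributing 2w to its degree).
# Returns the community labels (renumbered 1..K) and whether any node moved.
.localMove <- function(n, a, b, w) {
  selfw <- numeric(n)
  isLoop <- a == b
  if (any(isLoop)) {
    agg <- rowsum(w[isLoop], a[isLoop])
    selfw[as.integer(rownames(agg))] <- agg[, 1]
  }
  a2 <- a[!isLoop]; b2 <- b[!isLoop]; w2 <- w[!isLoop]
  # adjacency arrays: both directions of every non-loop edge
  from <- c(a2, b2); to <- c(b2, a2); ww <- c(w2, w2)
  ord <- order(from, method = "radix")
  from <- from[ord]; to <- to[ord]; ww <- ww[ord]
  # start index of each node's slice
  cnt <- tabulate(from, nbins = n)
  stopIdx <- cumsum(cnt)
  startIdx <- stopIdx - cnt + 1L
  deg <- numeric(n)
  if (length(w2)) {
    agg <- rowsum(c(w2, w2), c(a2, b2))
    deg[as.integer(rownames(agg))] <- agg[, 1]
  }
  deg <- deg + 2 * selfw
  m2 <- sum(deg)
  if (m2 <= 0) return(list(comm = seq_len(n), moved = FALSE))
  comm <- seq_len(n)
  tot <- deg
  visit <- sample.int(n)
  movedAny <- FALSE
  repeat {
    movedPass <- FALSE
    for (v in visit) {
      if (cnt[v] == 0L) next
      idx <- startIdx[v]:stopIdx[v]
      nbc <- comm[to[idx]]
      lw <- rowsum(ww[idx], nbc)
      cand <- as.integer(rownames(lw))
      cv <- comm[v]
      tot[cv] <- tot[cv] - deg[v]
      gain <- lw[, 1] - deg[v] * tot[cand] / m2
      stay <- if (cv %in% cand) gain[match(cv, cand)] else -deg[v] * tot[cv] / m2
      best <- which(gain == max(gain))
      bestC <- min(cand[best])
      if (max(gain) > stay + 1e-12 && bestC != cv) {
        comm[v] <- bestC
        tot[bestC] <- tot[bestC] + deg[v]
        movedPass <- TRUE
        movedAny <- TRUE
      } else {
        tot[cv] <- tot[cv] + deg[v]
      }
    }
    if (!movedPass) break
  }
  list(comm = match(comm, sort(unique(comm))), moved = movedAny)
}

# Full Louvain: repeated local moving + graph aggregation until no node
# moves. Visit order is randomized from the caller's RNG state.
.louvain <- function(n, a, b, w) {
  assign <- seq_len(n)   # original node -> current community
  repeat {
    nCur <- max(assign)
    res <- .localMove(nCur, a, b, w)
    assign <- res$comm[assign]
    if (!res$moved) break
    # aggregate: communities become nodes; parallel edges and loops merge
    ca <- res$comm[a]; cb <- res$comm[b]
    key <- paste(pmin(ca, cb), pmax(ca, cb))
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    a <- as.integer(vapply(parts, `[[`, character(1), 1L))
    b <- as.integer(vapply(parts, `[[`, character(1), 2L))
    w <- agg[, 1]
  }
  assign
}

#' Relabel a module assignment in size order
#'
#' Assigns labels `"M1"`, `"M2"`, ... by non-increasing module size (ties
#' broken by the lexicographically smallest member gene, so labelling is
#' deterministic).
#'
#' @param membership named vector (gene -> arbitrary module key).
#' @param modularity Q to store.
#' @return a [Partition-class].
#' @export
relabelPartition <- function(membership, modularity = NA_real_) {
  keys <- split(names(membership), as.character(membership))
  firstGene <- vapply(keys, function(g) min(g), character(1))
  ord <- order(-lengths(keys), firstGene, method = "radix")
  newLab <- setNames(paste0("M", seq_along(keys)), names(keys)[ord])
  Partition(setNames(unname(newLab[as.character(membership)]),
                     names(membership)), modularity)
}

#' Single seeded Louvain run
#'
#' Two-phase Louvain (greedy local moving to a modularity local optimum,
#' then community aggregation, repeated until stable) with the node visit
#' order shuffled by `seed`. Deterministic given (graph, seed); the
#' caller's RNG state is left untouched. Isolated nodes remain singleton
#' modules. An edgeless graph yields all-singleton modules with Q = 0 by
#' convention.
#'
#' @param graph a [CorrelationGraph-class].
#' @param seed integer seed for the visit-order shuffle.
#' @return a [Partition-class] with modules labelled in size order and
#'   the modularity of the assignment.
#' @export
louvainRun <- function(graph, seed = 42L) {
  e <- .graphEdges(graph)
  if (e$n == 0L) stop("empty graph")
  if (!length(e$w)) {
    mem <- setNames(paste0("M", seq_len(e$n)), e$names)
    return(relabelPartition(setNames(seq_len(e$n), e$names), 0))
  }
  assign <- withSeed(seed, .louvain(e$n, e$a, e$b, e$w))
  mem <- setNames(assign, e$names)
  part <- relabelPartition(mem)
  part@modularity <- graphModularity(graph, part)
  validObject(part)
  part
}

#' Ensemble of seeded Louvain clusterings
#'
#' Runs [louvainRun()] with the consecutive seeds `baseSeed`,
#' `baseSeed + 1`, ..., `baseSeed + nRuns - 1` and retains the `keep`
#' partitions of highest modularity (ties broken by run index). The
#' defaults match the analysis design of 10,000 runs with the 100 best
#' kept; desk-scale analyses typically use fewer runs.
#'
#' @param graph a [CorrelationGraph-class].
#' @param nRuns number of independent runs.
#' @param keep partitions to retain (<= nRuns).
#' @param baseSeed first seed of the sequence.
#' @return an [EnsembleResult-class]; its `summary` table records
#'   run index, seed, Q and module count for every run, flagging the
#'   retained ones.
#' @export
clusterEnsemble <- function(graph, nRuns = 10000, keep = 100, baseSeed = 42L) {
  nRuns <- as.integer(nRuns); keep <- as.integer(keep)
  if (keep > nRuns) stop("keep must be <= nRuns")
  if (nRuns < 1L) stop("nRuns must be >= 1")
  seeds <- as.integer(baseSeed) + seq_len(nRuns) - 1L
  parts <- vector("list", nRuns)
  for (i in seq_len(nRuns)) parts[[i]] <- louvainRun(graph, seeds[i])
  qs <- vapply(parts, modularityScore, numeric(1))
  nmod <- vapply(parts, function(p) length(moduleSizes(p)), integer(1))
  ord <- order(-qs, seq_len(nRuns), method = "radix")
  keptIdx <- ord[seq_len(keep)]
  summary <- data.frame(run = seq_len(nRuns), seed = seeds, Q = qs,
                        nModules = nmod,
                        kept = seq_len(nRuns) %in% keptIdx)
  new("EnsembleResult", partitions = parts[keptIdx], nRuns = nRuns,
      kept = keep, baseSeed = as.integer(baseSeed), summary = summary)
}

#' Select the final partition from an ensemble
#'
#' `"max_modularity"` (default) returns the highest-Q retained
#' partition. `"enrichment"` scores every retained partition by the sum
#' over its modules of -log10 of the module's best signature FDR
#' (floored at 1e-300) and returns the argmax — the "most informative"
#' clustering; ties go to the higher-Q partition.
#'
#' @param ensemble an [EnsembleResult-class].
#' @param strategy `"max_modularity"` or `"enrichment"`.
#' @param signatures a [SignatureSet-class]; required for `"enrichment"`.
#' @param population gene universe for the enrichment test; required for
#'   `"enrichment"`.
#' @return a [Partition-class].
#' @export
selectPartition <- function(ensemble,
                            strategy = c("max_modularity", "enrichment"),
                            signatures = NULL, population = NULL) {
  strategy <- match.arg(strategy)
  parts <- ensemblePartitions(ensemble)
  if (!length(parts)) stop("empty ensemble")
  if (strategy == "max_modularity") return(parts[[1L]])
  if (is.null(signatures) || is.null(population))
    stop("strategy 'enrichment' requires 'signatures' and 'population'")
  scores <- vapply(parts, function(p) {
    tab <- enrichModules(p, signatures, population, minSize = 1,
                         maxSize = Inf, fdrThreshold = 1, top = Inf)
    if (!nrow(tab)) return(0)
    best <- tapply(tab$fdr, tab$module, min)
    sum(negLog10(best))
  }, numeric(1))
  qs <- vapply(parts, modularityScore, numeric(1))
  parts[[order(-scores, -qs, seq_along(parts), method = "radix")[1L]]]
}
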