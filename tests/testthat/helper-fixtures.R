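# Fixture builders and independent brute-force oracles. Everything is
# generated in code; no stored data files.

# Small probe-level experiment with a fully crossed design.
makeProbeExperiment <- function(nProbes = 6, conditions = c("C1", "C2"),
                                timepoints = c("t1", "t2"), donors = 2,
                                seed = 1, values = NULL) {
  design <- expand.grid(donor = paste0("D", seq_len(donors)),
                        timepoint = timepoints, condition = conditions,
                        stringsAsFactors = FALSE)
  design$time_order <- match(design$timepoint, timepoints)
  design$sample_id <- paste(design$condition, design$timepoint,
                            design$donor, sep = "_")
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(nProbes * nrow(design), 8, 1),
                     nProbes, nrow(design))
  }
  rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  ProbeExperiment(values, design[, c("sample_id", "donor", "condition",
                                     "timepoint", "time_order")])
}

# Build a CorrelationGraph directly from an edge table (for clustering
# and IO tests that don't need the correlation stage).
makeGraph <- function(edges, nodes = NULL, k = 3L) {
  nodes <- if (is.null(nodes)) sort(unique(c(edges$a, edges$b))) else nodes
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$a, nodes),
                                    match(edges$b, nodes)),
                           weight = edges$w)
  methods::new("CorrelationGraph", graph = g, k = as.integer(k),
               nGenes = length(nodes), nPairsTotal = pairCount(length(nodes)),
               nEdgesRetained = as.integer(nrow(edges)))
}

twoTriangles <- function() {
  makeGraph(data.frame(a = c("a", "b", "c", "d", "e", "f"),
                       b = c("b", "c", "a", "e", "f", "d"),
                       w = 1))
}

# Canonical representation of an edge set for comparisons.
edgeSetOf <- function(cg) {
  el <- igraph::as_edgelist(asIgraph(cg))
  if (!nrow(el)) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

# Brute-force top-k retention oracle: fully sorts every row and unions
# the per-gene choices, independent of the package implementation.
bruteForceTopK <- function(rho, k) {
  genes <- rownames(rho)
  out <- character()
  for (i in seq_len(nrow(rho))) {
    r <- rho[i, ]
    r[i] <- NA
    cand <- data.frame(j = seq_along(r), rho = r, name = genes)
    cand <- cand[!is.na(cand$rho) & cand$rho > 0, ]
    cand <- cand[order(-cand$rho, cand$name), ]
    for (j in utils::head(cand$j, k))
      out <- c(out, paste(min(genes[i], genes[j]),
                          max(genes[i], genes[j]), sep = "|"))
  }
  sort(unique(out))
}

# Random symmetric correlation-like matrix with unit diagonal.
randomCorrMatrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  rownames(m) <- colnames(m) <- sprintf("g%03d", seq_len(n))
  m
}

# All set partitions of n elements as membership vectors (restricted
# growth strings); n <= 8 keeps this below Bell(8) = 4140.
allSetPartitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxLabel) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (lab in seq_len(maxLabel + 1L))
      recurse(c(prefix, lab), max(maxLabel, lab))
  }
  recurse(integer(), 0L)
  out
}

# Exhaustive-enumeration modularity optimum (independent oracle).
bruteBestModularity <- function(cg) {
  nodes <- graphNodes(cg)
  best <- -Inf
  for (p in allSetPartitions(length(nodes))) {
    q <- graphModularity(cg, Partition(setNames(as.character(p), nodes)))
    if (q > best) best <- q
  }
  best
}

# Random connected-ish sparse weighted graph on n nodes.
randomSparseGraph <- function(n, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < min(1, 2.5 / n + 0.15)
  # ensure no isolated modularity degeneracy: at least a spanning path
  path <- cbind(seq_len(n - 1), 2:n)
  sel <- unique(rbind(pairs[keep, , drop = FALSE], path))
  nodes <- sprintf("n%02d", seq_len(n))
  makeGraph(data.frame(a = nodes[sel[, 1]], b = nodes[sel[, 2]],
                       w = round(runif(nrow(sel), 0.2, 1), 3)))
}

# Direct summation oracle for the hypergeometric upper tail.
sumHyperTail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
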