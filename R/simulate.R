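#' @include AllClasses.R
NULL

#' Configuration for the synthetic time-course generator
#'
#' Defaults emulate a two-condition, multi-donor expression time course
#' with planted co-expression modules on an array-like platform: 400
#' genes in 8 modules (plus a 10% fraction of null genes with no module
#' trajectory), 8 ordered timepoints under 2 conditions with 3 donors
#' each, a mean of 1.3 probes per gene (1 + Poisson(0.3)), gene loadings
#' uniform on 0.5--1.5, smooth module trajectories of unit standard
#' deviation scaled to a 2 log2-unit amplitude, donor offsets of sd 0.1,
#' probe offsets of sd 0.3, biological noise sd 0.5 at the gene level
#' and measurement noise sd 0.25 at the probe level.
#'
#' @param nGenes,nModules gene and planted-module counts.
#' @param probesPerGene mean probes per gene; multiplicity is
#'   1 + Poisson(probesPerGene - 1), so the minimum is 1.
#' @param timepoints ordered character vector of timepoint labels.
#' @param conditions condition labels.
#' @param donors donors per condition (same donor ids across conditions).
#' @param loadingRange range of the per-gene trajectory loading.
#' @param amplitude standard deviation of each module trajectory across
#'   groups, in log2 units.
#' @param donorSd sd of the per-(gene, donor) baseline offset.
#' @param probeOffsetSd sd of the constant per-probe affinity offset.
#' @param noiseSd sd of the gene-level (biological) Gaussian noise.
#' @param probeNoiseSd sd of the probe-level measurement noise.
#' @param nullFraction fraction of genes with zero loading ("M0").
#' @param baselineMean,baselineSd distribution of per-gene baseline
#'   log2 intensity.
#' @param deThreshold log2 difference above which a noiseless change
#'   counts as a true differential event (default log2(1.5)).
#' @param nDecoys decoy signatures planted alongside the module
#'   signatures.
#' @param seed RNG seed; the whole dataset is drawn from one stream
#'   seeded once, so regeneration is bit-identical.
#' @return list with class `"SimConfig"`.
#' @export
simConfig <- function(nGenes = 400, nModules = 8, probesPerGene = 1.3,
                      timepoints = paste0("t", 1:8),
                      conditions = c("C1", "C2"), donors = 3,
                      loadingRange = c(0.5, 1.5), amplitude = 2,
                      donorSd = 0.1, probeOffsetSd = 0.3,
                      noiseSd = 0.5, probeNoiseSd = 0.25,
                      nullFraction = 0.1, baselineMean = 8,
                      baselineSd = 1, deThreshold = log2(1.5),
                      nDecoys = 20, seed = 1) {
  stopifnot(nGenes > 0, nModules > 0, probesPerGene >= 1,
            length(timepoints) >= 2, length(conditions) >= 1, donors >= 1,
            noiseSd > 0, nullFraction >= 0, nullFraction < 1)
  if ((nGenes - round(nullFraction * nGenes)) / nModules < 4)
    stop("module count too high: planted modules need >= 4 genes each")
  structure(as.list(environment()), class = "SimConfig")
}

# Smooth module trajectories: per (module, condition) a cubic polynomial
# in normalized time with iid standard-normal coefficients, evaluated on
# the condition x timepoint grid; rows are then orthogonalized across
# modules (QR) to remove accidental collinearity and rescaled to unit sd
# times the configured amplitude. Needs nModules <= 4 * nConditions
# (the dimension of the evaluated polynomial space).
.moduleTrajectories <- function(cfg, groupKeys, groupCondition, groupTime) {
  nM <- cfg$nModules
  nG <- length(groupKeys)
  tNorm <- (groupTime - min(groupTime)) / diff(range(groupTime))
  raw <- matrix(0, nM, nG)
  for (m in seq_len(nM)) for (cond in cfg$conditions) {
    cf <- rnorm(4)
    idx <- groupCondition == cond
    tt <- tNorm[idx]
    raw[m, idx] <- cf[1] + cf[2] * tt + cf[3] * tt^2 + cf[4] * tt^3
  }
  if (nM > 4 * length(cfg$conditions))
    stop("nModules may not exceed 4 * number of conditions ",
         "(rank of the cubic trajectory space)")
  qd <- qr.Q(qr(t(raw)))[, seq_len(nM), drop = FALSE]
  traj <- t(qd)
  traj <- traj / apply(traj, 1L, sd) * cfg$amplitude
  dimnames(traj) <- list(paste0("M", seq_len(nM)), groupKeys)
  traj
}

#' Simulate a multi-donor time course with planted modules
#'
#' Generates probe-level log2 expression for a condition x timepoint x
#' donor design. Gene-level value = baseline + loading x module
#' trajectory(condition, timepoint) + donor offset + N(0, noiseSd^2);
#' probe value = gene value + probe offset + N(0, probeNoiseSd^2). Null
#' genes carry zero loading and are labelled `"M0"` in the true
#' partition. All randomness comes from a single stream seeded once
#' (draw order: module assignment, trajectories, loadings, baselines,
#' donor offsets, gene noise, probe multiplicities, probe offsets, probe
#' noise, decoy signatures), so the same config reproduces the dataset
#' bit-for-bit.
#'
#' @param config a [simConfig()].
#' @return a [SyntheticDataset-class].
#' @export
simulateTimecourse <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, .simulate(config))
}

.simulate <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$nGenes))
  nNull <- round(cfg$nullFraction * cfg$nGenes)
  base <- rep(paste0("M", seq_len(cfg$nModules)),
              length.out = cfg$nGenes - nNull)
  labels <- sample(c(base, rep("M0", nNull)))
  names(labels) <- genes

  tOrd <- seq_along(cfg$timepoints)
  design <- expand.grid(donor = paste0("D", seq_len(cfg$donors)),
                        timepoint = cfg$timepoints,
                        condition = cfg$conditions,
                        stringsAsFactors = FALSE)
  design$time_order <- tOrd[match(design$timepoint, cfg$timepoints)]
  design$sample_id <- paste(design$condition, design$timepoint,
                            design$donor, sep = "_")
  groups <- unique(design[, c("condition", "timepoint", "time_order")])
  groupKeys <- paste0(groups$condition, "@", groups$timepoint)
  groups <- data.frame(key = groupKeys, groups, row.names = NULL,
                       stringsAsFactors = FALSE)

  traj <- .moduleTrajectories(cfg, groupKeys, groups$condition,
                              groups$time_order)
  loading <- runif(cfg$nGenes, cfg$loadingRange[1], cfg$loadingRange[2])
  loading[labels == "M0"] <- 0
  baseline <- rnorm(cfg$nGenes, cfg$baselineMean, cfg$baselineSd)

  # noiseless gene x group surface (the planted truth for dynamics/DE)
  noiseless <- matrix(baseline, cfg$nGenes, nrow(groups))
  inMod <- labels != "M0"
  noiseless[inMod, ] <- noiseless[inMod, ] +
    loading[inMod] * traj[labels[inMod], , drop = FALSE]
  dimnames(noiseless) <- list(genes, groupKeys)

  donorIds <- unique(design$donor)
  donorEff <- matrix(rnorm(cfg$nGenes * length(donorIds), 0, cfg$donorSd),
                     cfg$nGenes, length(donorIds),
                     dimnames = list(genes, donorIds))
  sampleGroup <- match(paste0(design$condition, "@", design$timepoint),
                       groupKeys)
  geneVals <- noiseless[, sampleGroup, drop = FALSE] +
    donorEff[, design$donor, drop = FALSE] +
    matrix(rnorm(cfg$nGenes * nrow(design), 0, cfg$noiseSd),
           cfg$nGenes, nrow(design))
  colnames(geneVals) <- design$sample_id

  nProbes <- 1L + rpois(cfg$nGenes, cfg$probesPerGene - 1)
  geneOfProbe <- rep(seq_len(cfg$nGenes), nProbes)
  probeIds <- sprintf("ILMN_%05d", seq_along(geneOfProbe))
  offsets <- rnorm(length(probeIds), 0, cfg$probeOffsetSd)
  probeVals <- geneVals[geneOfProbe, , drop = FALSE] + offsets +
    matrix(rnorm(length(probeIds) * nrow(design), 0, cfg$probeNoiseSd),
           length(probeIds), nrow(design))
  rownames(probeVals) <- probeIds

  meta <- design[, c("sample_id", "donor", "condition", "timepoint",
                     "time_order")]
  expr <- ProbeExperiment(probeVals, meta)
  annotation <- data.frame(probe_id = probeIds,
                           gene = genes[geneOfProbe],
                           stringsAsFactors = FALSE)

  trueDE <- .trueDESets(noiseless, groups, cfg$deThreshold)
  sigs <- .plantedSignatures(labels, genes, cfg$nDecoys)

  new("SyntheticDataset", expr = expr, annotation = annotation,
      truePartition = Partition(labels, NA_real_), noiseless = noiseless,
      groups = groups, trueDE = trueDE, signatures = sigs,
      config = unclass(cfg))
}

# True differential sets: per condition, each later timepoint against
# the condition's first timepoint; induced/repressed by the sign of the
# noiseless difference, threshold strict.
.trueDESets <- function(noiseless, groups, threshold) {
  out <- list()
  for (cond in unique(groups$condition)) {
    rows <- groups[groups$condition == cond, , drop = FALSE]
    rows <- rows[order(rows$time_order), , drop = FALSE]
    baseKey <- rows$key[1L]
    condOut <- list()
    for (i in seq_len(nrow(rows))[-1L]) {
      d <- noiseless[, rows$key[i]] - noiseless[, baseKey]
      condOut[[rows$timepoint[i]]] <- list(
        induced = rownames(noiseless)[d > threshold],
        repressed = rownames(noiseless)[d < -threshold])
    }
    out[[cond]] <- condOut
  }
  out
}

.plantedSignatures <- function(labels, genes, nDecoys) {
  mods <- split(names(labels), labels)
  mods <- mods[names(mods) != "M0"]
  sets <- mods
  names(sets) <- paste0("Planted_", names(mods))
  if (nDecoys > 0) {
    sizes <- pmax(5L, rpois(nDecoys, 25))
    for (i in seq_len(nDecoys))
      sets[[sprintf("Decoy_%02d", i)]] <- sample(genes,
                                                 min(sizes[i], length(genes)))
  }
  SignatureSet(sets, collection = c(rep("planted", length(mods)),
                                    rep("decoy", max(nDecoys, 0))))
}

#' Planted signature database for a synthetic dataset
#'
#' One exact signature per planted module plus `nDecoys` random gene
#' sets drawn from the full gene population; reproducible from the
#' given seed.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param nDecoys number of decoy sets.
#' @param seed RNG seed for the decoy draws (defaults to the dataset
#'   seed + 1000).
#' @return a [SignatureSet-class].
#' @export
plantedSignatures <- function(dataset, nDecoys = 20, seed = NULL) {
  stopifnot(is(dataset, "SyntheticDataset"))
  labels <- moduleAssignments(truePartition(dataset))
  if (is.null(seed)) seed <- dataset@config$seed + 1000
  withSeed(seed, .plantedSignatures(labels, names(labels), nDecoys))
}

#' True noiseless difference between two groups
#'
#' Per-gene difference of the noiseless expression surface between two
#' (condition, timepoint) cells — the planted effect size any
#' differential caller is trying to recover.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param groupA,groupB lists with elements `condition` and `timepoint`.
#' @return named numeric vector (A minus B), one entry per gene.
#' @export
trueDifference <- function(dataset, groupA, groupB) {
  stopifnot(is(dataset, "SyntheticDataset"))
  keyA <- paste0(groupA$condition, "@", groupA$timepoint)
  keyB <- paste0(groupB$condition, "@", groupB$timepoint)
  nl <- noiselessProfile(dataset)
  if (!keyA %in% colnames(nl) || !keyB %in% colnames(nl))
    stop("unknown group(s): ", keyA, " / ", keyB)
  nl[, keyA] - nl[, keyB]
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-adjusted agreement between two partitions of the
#' same gene universe, from the pair-counting contingency table:
#' `(sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.
#'
#' @param partA,partB [Partition-class] objects (or named label vectors)
#'   over the same genes.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjustedRandIndex <- function(partA, partB) {
  a <- if (is(partA, "Partition")) moduleAssignments(partA) else partA
  b <- if (is(partB, "Partition")) moduleAssignments(partB) else partB
  if (!setequal(names(a), names(b)))
    stop("partitions cover different gene universes")
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sumIJ <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)  # both partitions trivial
  (sumIJ - expected) / (maxIdx - expected)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Writes `expr.tsv`, `meta.tsv`, `annot.tsv`, `truth_partition.tsv`,
#' `truth_de.tsv` and `sigs.gmt` so any pipeline stage can be exercised
#' from files.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionTSV(syntheticExpr(dataset),
                     file.path(dir, "expr.tsv"),
                     file.path(dir, "meta.tsv"))
  write.table(syntheticAnnotation(dataset), file.path(dir, "annot.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writePartitionTSV(truePartition(dataset),
                    file.path(dir, "truth_partition.tsv"))
  de <- trueDESets(dataset)
  rows <- do.call(rbind, lapply(names(de), function(cond)
    do.call(rbind, lapply(names(de[[cond]]), function(tp)
      do.call(rbind, lapply(c("induced", "repressed"), function(dr) {
        g <- de[[cond]][[tp]][[dr]]
        if (!length(g)) return(NULL)
        data.frame(condition = cond, timepoint = tp, direction = dr,
                   gene = g, stringsAsFactors = FALSE)
      }))))))
  if (is.null(rows))
    rows <- data.frame(condition = character(), timepoint = character(),
                       direction = character(), gene = character())
  write.table(rows, file.path(dir, "truth_de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeGMT(plantedSignatureSet(dataset), file.path(dir, "sigs.gmt"))
  invisible(dir)
}

#' Module-recovery score against the planted truth
#'
#' Adjusted Rand index between a recovered partition and the planted
#' one, evaluated over the genes that carry a planted module (present in
#' both partitions). Background ("M0") genes have no true module to
#' recover — they are mutually uncorrelated by construction — so they
#' are excluded from the score rather than treated as one class.
#'
#' @param partition recovered [Partition-class].
#' @param dataset the [SyntheticDataset-class] it was derived from.
#' @return list with `ari` (the score), `n_scored` (genes entering the
#'   score) and `ari_all` (ARI over all shared genes with "M0" kept as a
#'   class, for reference).
#' @export
moduleRecoveryARI <- function(partition, dataset) {
  stopifnot(is(dataset, "SyntheticDataset"))
  truth <- moduleAssignments(truePartition(dataset))
  rec <- moduleAssignments(partition)
  shared <- intersect(names(rec), names(truth))
  planted <- shared[truth[shared] != "M0"]
  list(ari = adjustedRandIndex(rec[planted], truth[planted]),
       n_scored = length(planted),
       ari_all = adjustedRandIndex(rec[shared], truth[shared]))
}
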