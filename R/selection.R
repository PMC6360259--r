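#' @include AllClasses.R
NULL

#' Welch two-sample t-test on log2 expression values
#'
#' Thin wrapper around [stats::t.test()] (unequal variances,
#' Welch--Satterthwaite degrees of freedom) returning the pieces the
#' probe-selection stage needs. Two groups with zero variance and equal
#' means are reported as t = 0, p = 1 rather than an error.
#'
#' @param x,y numeric vectors of log2 values, each of length >= 2.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2, p.value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p.value = 0))
  }
  fit <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p.value = fit$p.value)
}

#' Selection configuration
#'
#' Thresholds for informative-probe selection and differential calling.
#' The probe-selection defaults are an unadjusted p < 0.01 with linear
#' fold change > 1.2 (long course; use `pThreshold = 0.05` for the short
#' course), and a variance filter at sigma^2 > 0.05 across per-group
#' medians; differential-expression sets for overlap analyses use
#' BH-adjusted p < 0.05 with fold change > 1.5 (`adjust = TRUE`).
#'
#' @param pThreshold (adjusted) p-value cut-off, strict.
#' @param fcThreshold linear fold-change cut-off (> 1), strict, applied as
#'   |mean difference on log2 scale| > log2(fcThreshold).
#' @param adjust logical; apply Benjamini--Hochberg adjustment across the
#'   probes of one contrast before thresholding.
#' @param varianceThreshold sigma^2 cut-off on log2 scale, strict.
#' @return a list with class `"SelectionConfig"`.
#' @export
selectionConfig <- function(pThreshold = 0.01, fcThreshold = 1.2,
                            adjust = FALSE, varianceThreshold = 0.05) {
  stopifnot(pThreshold > 0, fcThreshold > 1, varianceThreshold > 0)
  structure(list(pThreshold = pThreshold, fcThreshold = fcThreshold,
                 adjust = adjust, varianceThreshold = varianceThreshold),
            class = "SelectionConfig")
}

.groupColumns <- function(x, group) {
  cd <- colData(x)
  sel <- rep(TRUE, ncol(x))
  for (f in names(group)) {
    if (!f %in% colnames(cd)) stop("unknown metadata field '", f, "'")
    sel <- sel & (cd[[f]] %in% group[[f]])
  }
  colnames(x)[sel]
}

#' Resolve a contrast group to sample ids
#'
#' A group is either a character vector of sample ids or a named list of
#' metadata filters, e.g. `list(condition = "C1", timepoint = "t1")`.
#'
#' @param x a [ProbeExperiment-class] or [GeneExperiment-class].
#' @param group group specification.
#' @return character vector of sample ids.
#' @export
resolveGroup <- function(x, group) {
  ids <- if (is.character(group)) group else .groupColumns(x, group)
  missing <- setdiff(ids, colnames(x))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  ids
}

#' Differentially expressed probes for one contrast
#'
#' Per-probe Welch t-tests between two sample groups with fold-change and
#' p-value thresholds (both strict). A probe is "up" when
#' mean(A) - mean(B) > log2(fcThreshold) and its (optionally BH-adjusted)
#' p-value falls below the threshold; "down" is symmetric.
#'
#' @param x a [ProbeExperiment-class] (or gene-level experiment).
#' @param groupA,groupB contrast groups (see [resolveGroup()]); must be
#'   disjoint and each of size >= 2.
#' @param config a [selectionConfig()].
#' @return list with character vectors `up` and `down`, plus the
#'   per-probe statistics in `table` (probe, delta, p, p_adj).
#' @export
differentialProbes <- function(x, groupA, groupB, config = selectionConfig()) {
  a <- resolveGroup(x, groupA)
  b <- resolveGroup(x, groupB)
  if (!length(a) || !length(b)) stop("empty contrast group")
  if (length(intersect(a, b))) stop("contrast groups must be disjoint")
  va <- assay(x, "exprs")[, a, drop = FALSE]
  vb <- assay(x, "exprs")[, b, drop = FALSE]
  delta <- rowMeans(va) - rowMeans(vb)
  p <- vapply(seq_len(nrow(va)), function(i)
    welchTTest(va[i, ], vb[i, ])$p.value, numeric(1))
  pAdj <- if (isTRUE(config$adjust)) p.adjust(p, method = "BH") else p
  cut <- log2(config$fcThreshold)
  sig <- pAdj < config$pThreshold
  up <- rownames(va)[sig & delta > cut]
  down <- rownames(va)[sig & delta < -cut]
  list(up = up, down = down,
       table = data.frame(probe = rownames(va), delta = delta, p = p,
                          p_adj = pAdj, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Variance filter over per-group medians
#'
#' For each probe, takes the median across donors within each
#' (condition, timepoint) group — a single-donor group contributes its
#' one value — then the unbiased variance of those medians; probes with
#' variance strictly above the threshold pass. Set
#' `byCondition = FALSE` to pool conditions at each timepoint.
#'
#' @param x a [ProbeExperiment-class].
#' @param config a [selectionConfig()]; `varianceThreshold` is used.
#' @param byCondition group by condition x timepoint (default) or by
#'   timepoint only.
#' @return character vector of passing probe ids.
#' @export
varianceFilter <- function(x, config = selectionConfig(), byCondition = TRUE) {
  cd <- colData(x)
  key <- if (byCondition) paste(cd$condition, cd$timepoint, sep = "\r")
         else as.character(cd$timepoint)
  groups <- split(seq_len(ncol(x)), key)
  if (length(groups) < 2L)
    stop("variance filter needs at least two (condition, timepoint) groups")
  v <- assay(x, "exprs")
  med <- vapply(groups, function(idx)
    .rowMedians(v[, idx, drop = FALSE]), numeric(nrow(v)))
  vars <- apply(med, 1L, var)
  rownames(v)[vars > config$varianceThreshold]
}

# row medians via apply; no extra dependency needed at these sizes
.rowMedians <- function(m) apply(m, 1L, median)

#' Merge differential and variance-selected probes
#'
#' Non-redundant union of the up/down sets of every contrast with the
#' variance-passing probes.
#'
#' @param deResults list of results from [differentialProbes()].
#' @param varianceSet character vector from [varianceFilter()].
#' @return character vector of selected probe ids (unique, sorted by
#'   first appearance).
#' @export
selectInformative <- function(deResults, varianceSet = character()) {
  de <- unlist(lapply(deResults, function(r) c(r$up, r$down)),
               use.names = FALSE)
  unique(c(de, varianceSet))
}

#' Merge selected probes to genes
#'
#' Drops probes without a gene annotation; when several selected probes
#' map to one gene, keeps the probe with the largest variance across all
#' samples (ties broken by lexicographically smaller probe id). The
#' chosen probe is recorded per gene as provenance.
#'
#' @param x a [ProbeExperiment-class].
#' @param selected character vector of selected probe ids (subset of
#'   `rownames(x)`).
#' @param annotation data.frame with columns `probe_id`, `gene` (see
#'   [readProbeAnnotation()]).
#' @return a [GeneExperiment-class].
#' @export
mergeProbesToGenes <- function(x, selected, annotation) {
  if (!length(selected)) stop("empty probe selection")
  bad <- setdiff(selected, rownames(x))
  if (length(bad))
    stop("selected probe(s) absent from the matrix: ",
         paste(utils::head(bad, 10), collapse = ", "))
  ann <- annotation[match(selected, annotation$probe_id), ]
  keep <- !is.na(ann$gene) & nzchar(ann$gene)
  probes <- selected[keep]
  genes <- ann$gene[keep]
  if (!length(probes))
    stop("no selected probe has a gene annotation")
  v <- assay(x, "exprs")[probes, , drop = FALSE]
  vr <- apply(v, 1L, var)
  ord <- order(genes, -vr, probes, method = "radix")
  first <- !duplicated(genes[ord])
  pick <- ord[first]
  m <- v[pick, , drop = FALSE]
  rownames(m) <- genes[pick]
  se <- SummarizedExperiment(
    assays = list(exprs = m),
    colData = colData(x),
    rowData = S4Vectors::DataFrame(probe_id = probes[pick],
                                   row.names = genes[pick]))
  new("GeneExperiment", se)
}

#' Standard automatic contrast battery for a time course
#'
#' Builds the contrast battery used for informative-probe selection:
#' every pair of conditions at each shared timepoint, and within each
#' condition every timepoint against the baseline (earliest
#' `time_order`) timepoint. Groups with fewer than 2 samples are
#' skipped.
#'
#' @param x a [ProbeExperiment-class].
#' @return list of contrasts, each a list with elements `A`, `B`
#'   (metadata filter lists) and a human-readable `label`.
#' @export
autoContrasts <- function(x) {
  cd <- as.data.frame(colData(x))
  tps <- unique(cd[, c("timepoint", "time_order")])
  tps <- tps[order(tps$time_order), , drop = FALSE]
  conds <- sort(unique(cd$condition))
  nOf <- function(cond, tp)
    sum(cd$condition == cond & cd$timepoint == tp)
  out <- list()
  for (tp in tps$timepoint) {
    if (length(conds) < 2) break
    for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
      if (nOf(conds[i], tp) >= 2 && nOf(conds[j], tp) >= 2)
        out[[length(out) + 1L]] <- list(
          A = list(condition = conds[i], timepoint = tp),
          B = list(condition = conds[j], timepoint = tp),
          label = sprintf("%s_vs_%s@%s", conds[i], conds[j], tp))
    }
  }
  base <- tps$timepoint[1L]
  for (cond in conds) for (tp in tps$timepoint[-1L]) {
    if (nOf(cond, tp) >= 2 && nOf(cond, base) >= 2)
      out[[length(out) + 1L]] <- list(
        A = list(condition = cond, timepoint = tp),
        B = list(condition = cond, timepoint = base),
        label = sprintf("%s@%s_vs_%s", cond, tp, base))
  }
  out
}
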