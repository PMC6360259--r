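#' @include AllClasses.R
NULL

#' Donor-median expression per (condition, timepoint) group
#'
#' Summarizes a gene-level experiment to one column per
#' (condition, timepoint) cell: the median across the donors of that
#' cell (a single-donor cell contributes its one sample). Columns are
#' ordered by condition, then by `time_order`, and named
#' `condition@timepoint`; the group design is attached as the
#' `"groups"` attribute.
#'
#' @param x a [GeneExperiment-class] (or [ProbeExperiment-class]).
#' @return genes-by-groups numeric matrix.
#' @export
groupMedians <- function(x) {
  cd <- as.data.frame(colData(x))
  key <- paste0(cd$condition, "@", cd$timepoint)
  groups <- unique(data.frame(key = key, condition = cd$condition,
                              timepoint = cd$timepoint,
                              time_order = cd$time_order,
                              stringsAsFactors = FALSE))
  groups <- groups[order(groups$condition, groups$time_order,
                         method = "radix"), , drop = FALSE]
  v <- assay(x, "exprs")
  out <- vapply(groups$key, function(kk)
    apply(v[, key == kk, drop = FALSE], 1L, median), numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(v), groups$key))
  attr(out, "groups") <- groups
  out
}

#' Row-wise z-scores of a profile matrix
#'
#' Per gene: subtract the row mean and divide by the unbiased (n-1) row
#' standard deviation. Constant rows become all-zero and are listed in
#' the `"constantRows"` attribute.
#'
#' @param profile genes-by-groups matrix (e.g. from [groupMedians()]).
#' @return matrix of the same shape; group attributes are preserved.
#' @export
zscoreRows <- function(profile) {
  mu <- rowMeans(profile)
  s <- apply(profile, 1L, sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  out <- (profile - mu) / s
  out[const, ] <- 0
  attr(out, "groups") <- attr(profile, "groups")
  attr(out, "constantRows") <- rownames(profile)[const]
  out
}

#' Fold change of each group against its condition's baseline
#'
#' Log2 difference of every group column against the baseline column of
#' the same condition. The baseline defaults to each condition's
#' earliest timepoint (smallest `time_order`); pass a single timepoint
#' label, or a named vector condition -> timepoint label, to override.
#'
#' @param profile genes-by-groups matrix from [groupMedians()] (its
#'   `"groups"` attribute is required).
#' @param baseline baseline timepoint specification (see above).
#' @return matrix of log2 fold changes; baseline columns are all zero.
#' @export
foldChangeVsBaseline <- function(profile, baseline = NULL) {
  groups <- attr(profile, "groups")
  if (is.null(groups)) stop("profile must carry a 'groups' attribute")
  out <- profile
  for (cond in unique(groups$condition)) {
    rows <- groups[groups$condition == cond, , drop = FALSE]
    tp <- if (is.null(baseline)) rows$timepoint[which.min(rows$time_order)]
          else if (!is.null(names(baseline))) baseline[[cond]]
          else baseline
    baseKey <- rows$key[rows$timepoint == tp]
    if (length(baseKey) != 1L)
      stop("missing baseline group for condition '", cond, "'")
    out[, rows$key] <- profile[, rows$key, drop = FALSE] -
      profile[, baseKey]
  }
  attr(out, "groups") <- groups
  attr(out, "baseline") <- baseline
  out
}

#' Mean module profiles
#'
#' Unweighted mean of the member-gene rows of each module; modules are
#' ordered by label index.
#'
#' @param profile genes-by-groups matrix.
#' @param partition a [Partition-class]; every module gene must be a row
#'   of `profile`.
#' @return modules-by-groups matrix.
#' @export
moduleMeanProfile <- function(profile, partition) {
  mem <- moduleAssignments(partition)
  missing <- setdiff(names(mem), rownames(profile))
  if (length(missing))
    stop("module gene(s) absent from profile rows: ",
         paste(utils::head(missing, 10), collapse = ", "))
  mods <- split(names(mem), mem)
  mods <- mods[order(as.integer(sub("^M", "", names(mods))))]
  out <- t(vapply(mods, function(g)
    colMeans(profile[g, , drop = FALSE]), numeric(ncol(profile))))
  dimnames(out) <- list(names(mods), colnames(profile))
  attr(out, "groups") <- attr(profile, "groups")
  out
}

#' Hierarchical row ordering by Pearson correlation, average linkage
#'
#' Agglomerative clustering of rows with distance 1 - Pearson r and
#' average linkage; returns the leaf order. Rows with zero variance get
#' r = 0 (distance 1) against every other row. Deterministic given the
#' input; ties follow the input row order via [stats::hclust()].
#'
#' @param m matrix with at least 2 rows.
#' @return integer vector: row indices in leaf order, with the `hclust`
#'   tree attached as attribute `"hclust"`.
#' @export
hierarchicalOrder <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  s <- apply(m, 1L, sd)
  r <- suppressWarnings(cor(t(m), method = "pearson"))
  r[s == 0, ] <- 0
  r[, s == 0] <- 0
  diag(r) <- 1
  h <- hclust(as.dist(1 - r), method = "average")
  structure(h$order, hclust = h)
}
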