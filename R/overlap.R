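#' @include AllClasses.R
NULL

# Shared kernel: all overlap significances in the package reduce to this
# one call (upper-tail hypergeometric, -log10 floored at 0, capped 300).
.overlapPair <- function(setA, setB, N) {
  k <- length(intersect(setA, setB))
  p <- hypergeomUpperTail(k, length(setA), length(setB), N)
  c(count = k, neglog10 = negLog10(p))
}

.overlapMatrix <- function(listA, listB, N) {
  cnt <- matrix(0L, length(listA), length(listB),
                dimnames = list(names(listA), names(listB)))
  sig <- matrix(0, length(listA), length(listB),
                dimnames = list(names(listA), names(listB)))
  for (i in seq_along(listA)) for (j in seq_along(listB)) {
    r <- .overlapPair(listA[[i]], listB[[j]], N)
    cnt[i, j] <- as.integer(r["count"])
    sig[i, j] <- r["neglog10"]
  }
  new("OverlapMatrix", neglog10p = sig, counts = cnt, population = N)
}

#' Gene-level overlap of modules between two networks
#'
#' Entry (i, j) is the -log10 upper-tail hypergeometric p-value of the
#' overlap between module i of partition A and module j of partition B,
#' drawn from a shared gene population.
#'
#' @param partA,partB [Partition-class] objects; all their genes must be
#'   in `population`.
#' @param population character vector, the shared gene universe.
#' @return an [OverlapMatrix-class], modules of A as rows.
#' @export
moduleOverlapMatrix <- function(partA, partB, population) {
  population <- unique(as.character(population))
  if (!length(population)) stop("empty population")
  memA <- moduleAssignments(partA); memB <- moduleAssignments(partB)
  out <- setdiff(c(names(memA), names(memB)), population)
  if (length(out))
    stop("partition gene(s) outside the population: ",
         paste(utils::head(out, 10), collapse = ", "))
  .overlapMatrix(split(names(memA), memA), split(names(memB), memB),
                 length(population))
}

#' Signature-level overlap of modules between two networks
#'
#' For each module of either enrichment table, takes the set of
#' signature names passing the prefilter (raw p < `pThreshold`, signature
#' size within `[minSize, maxSize]`), then tests the overlap of those
#' name sets between every module pair of the two tables
#' hypergeometrically against the signature universe. By default the
#' universe is every signature surviving the prefilter in either table.
#'
#' @param enrichA,enrichB unfiltered enrichment tables from
#'   [enrichModules()] (call with `fdrThreshold = 1, top = Inf`), built
#'   from the same signature database.
#' @param pThreshold raw p prefilter (default 0.001).
#' @param minSize,maxSize signature size bounds for the prefilter
#'   (defaults 5 and 1000).
#' @param universe optional explicit signature-name universe (character)
#'   or its size (single number).
#' @return an [OverlapMatrix-class], modules of A as rows.
#' @export
signatureOverlapMatrix <- function(enrichA, enrichB, pThreshold = 0.001,
                                   minSize = 5, maxSize = 1000,
                                   universe = NULL) {
  pick <- function(tab) {
    sel <- tab$p < pThreshold & tab$signature_size >= minSize &
      tab$signature_size <= maxSize
    split(tab$signature[sel], factor(tab$module[sel],
                                     levels = unique(tab$module)))
  }
  sigA <- pick(enrichA); sigB <- pick(enrichB)
  N <- if (is.null(universe))
    length(unique(c(unlist(sigA), unlist(sigB))))
  else if (is.numeric(universe)) universe
  else length(unique(universe))
  if (N < 1) stop("signature universe is empty")
  .overlapMatrix(sigA, sigB, N)
}

#' Differential-expression set
#'
#' One direction of a differential contrast: the genes induced (or
#' repressed) at a timepoint of a condition relative to the course
#' baseline.
#'
#' @param condition condition label.
#' @param timepoint timepoint label.
#' @param direction `"induced"` or `"repressed"`.
#' @param genes character vector of gene (or probe) ids.
#' @return list with class `"DESet"`.
#' @export
deSet <- function(condition, timepoint,
                  direction = c("induced", "repressed"), genes) {
  direction <- match.arg(direction)
  structure(list(condition = condition, timepoint = timepoint,
                 direction = direction, genes = unique(as.character(genes))),
            class = "DESet")
}

#' Pairwise overlap heatmap of differential-expression sets
#'
#' All-by-all hypergeometric overlap significance between DE sets of one
#' direction (induced and repressed are compared separately), against the
#' population of genes tested for differential expression.
#'
#' @param sets list of [deSet()] objects, all of the same direction.
#' @param population character vector, the tested-gene universe.
#' @return an [OverlapMatrix-class] with rows/columns labelled
#'   `condition@timepoint`; symmetric.
#' @export
deOverlapHeatmap <- function(sets, population) {
  if (!length(sets)) stop("no DE sets supplied")
  dirs <- unique(vapply(sets, `[[`, character(1), "direction"))
  if (length(dirs) != 1L)
    stop("mixed directions in one call: ", paste(dirs, collapse = ", "))
  population <- unique(as.character(population))
  if (!length(population)) stop("empty population")
  gl <- lapply(sets, function(s) intersect(s$genes, population))
  names(gl) <- vapply(sets, function(s)
    paste0(s$condition, "@", s$timepoint), character(1))
  .overlapMatrix(gl, gl, length(population))
}

#' Three-way Venn region counts
#'
#' Counts of the 7 exclusive regions of three gene sets; the counts sum
#' to the size of the union.
#'
#' @param setA,setB,setC character vectors.
#' @return named integer vector with elements `A`, `B`, `C`, `AB`, `AC`,
#'   `BC`, `ABC` (each region exclusive of the others).
#' @export
vennPartition <- function(setA, setB, setC) {
  a <- unique(setA); b <- unique(setB); c <- unique(setC)
  u <- unique(c(a, b, c))
  inA <- u %in% a; inB <- u %in% b; inC <- u %in% c
  out <- c(A = sum(inA & !inB & !inC),
           B = sum(!inA & inB & !inC),
           C = sum(!inA & !inB & inC),
           AB = sum(inA & inB & !inC),
           AC = sum(inA & !inB & inC),
           BC = sum(!inA & inB & inC),
           ABC = sum(inA & inB & inC))
  storage.mode(out) <- "integer"
  out
}
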