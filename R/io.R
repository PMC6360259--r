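#' @include AllClasses.R
NULL

#' Construct a probe-level experiment
#'
#' @param values numeric matrix of log2 intensities, probes x samples,
#'   with probe ids as rownames and sample ids as colnames.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `donor`, `condition`, `timepoint`, `time_order` (integer rank of the
#'   timepoint within the course).
#' @return a validated [ProbeExperiment-class].
#' @export
ProbeExperiment <- function(values, samples) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(samples))
    stop("sample metadata must contain a 'sample_id' column")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  orphanExpr <- setdiff(colnames(values), samples$sample_id)
  orphanMeta <- setdiff(samples$sample_id, colnames(values))
  if (length(orphanExpr))
    stop("sample(s) in expression matrix lack metadata: ",
         paste(orphanExpr, collapse = ", "))
  if (length(orphanMeta))
    stop("metadata sample(s) absent from expression matrix: ",
         paste(orphanMeta, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(samples[setdiff(colnames(samples), "sample_id")],
                             row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  new("ProbeExperiment", se)
}

#' Read a probe-level expression matrix with sample metadata
#'
#' Reads a tab-delimited expression file (first column `probe_id`,
#' remaining columns one per sample, UTF-8, decimal point) together with
#' a sample metadata TSV (`sample_id`, `donor`, `condition`, `timepoint`,
#' `time_order`). Values are taken as-is: they are expected to be
#' normalized, log2-scale intensities already.
#'
#' @param path expression TSV.
#' @param metadataPath sample metadata TSV.
#' @return a [ProbeExperiment-class].
#' @export
readExpressionTSV <- function(path, metadataPath) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    dec = ".", sep = "\t", colClasses = NA)
  if (ncol(tab) < 2L)
    stop("expression file must have a probe_id column plus sample columns")
  if (colnames(tab)[1L] != "probe_id")
    stop("first column of the expression file must be named 'probe_id'")
  probes <- as.character(tab[[1L]])
  if (anyDuplicated(probes))
    stop("duplicated probe id(s) in expression file: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- probes
  meta <- read.delim(metadataPath, check.names = FALSE,
                     stringsAsFactors = FALSE, sep = "\t")
  need <- c("sample_id", .requiredSampleFields)
  if (!all(need %in% colnames(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  ProbeExperiment(m, meta)
}

#' Write an experiment back to expression + metadata TSVs
#'
#' Inverse of [readExpressionTSV()]; values are written at full precision
#' so a write/read round trip reproduces the object exactly.
#'
#' @param x a [ProbeExperiment-class] or [GeneExperiment-class].
#' @param path,metadataPath output TSV paths.
#' @export
writeExpressionTSV <- function(x, path, metadataPath = NULL) {
  v <- assay(x, "exprs")
  df <- data.frame(probe_id = rownames(v),
                   as.data.frame(format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    cd <- as.data.frame(colData(x))
    meta <- data.frame(sample_id = rownames(cd), cd,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a probe -> gene annotation table
#'
#' Two tab-separated columns, `probe_id` and `gene`. Probes with an empty
#' gene field are kept as explicitly unmapped (dropped at probe merging).
#'
#' @param path annotation TSV.
#' @return data.frame with columns `probe_id`, `gene`.
#' @export
readProbeAnnotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                    colClasses = "character")
  if (!all(c("probe_id", "gene") %in% colnames(tab)))
    stop("annotation must have columns 'probe_id' and 'gene'")
  if (anyDuplicated(tab$probe_id))
    stop("duplicated probe id(s) in annotation: ",
         paste(unique(tab$probe_id[duplicated(tab$probe_id)]), collapse = ", "))
  tab[, c("probe_id", "gene")]
}

#' Read a GMT gene-signature file
#'
#' Standard GMT: one signature per line, tab-separated fields
#' `name`, `description`, then member gene symbols. Duplicate genes
#' within a line are deduplicated; the description field is stored as the
#' collection label.
#'
#' @param path GMT file.
#' @return a [SignatureSet-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(SignatureSet())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate signature name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  SignatureSet(sets, collection = desc)
}

#' Write a signature collection as GMT
#' @param x a [SignatureSet-class].
#' @param path output file.
#' @export
writeGMT <- function(x, path) {
  stopifnot(is(x, "SignatureSet"))
  desc <- if (length(x@collection)) x@collection else rep("na", length(x@sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(x@sets), desc, x@sets)
  writeLines(unname(lines), path)
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Export a network with module labels as GEXF
#'
#' Writes the graph for Gephi-style viewers: one node per gene with a
#' string `module` attribute from the partition, undirected edges with
#' the Spearman correlation as the native GEXF `weight`. Weights are
#' written at full precision so a write/read round trip is lossless.
#'
#' @param graph a [CorrelationGraph-class].
#' @param partition a [Partition-class] covering every graph node.
#' @param path output `.gexf` file.
#' @export
writeNetworkGEXF <- function(graph, partition, path) {
  stopifnot(is(graph, "CorrelationGraph"), is(partition, "Partition"))
  g <- asIgraph(graph)
  nodes <- igraph::V(g)$name
  mem <- moduleAssignments(partition)
  missing <- setdiff(nodes, names(mem))
  if (length(missing))
    stop("partition is missing graph node(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  nodeLines <- sprintf(
    '      <node id="%s" label="%s"><attvalues><attvalue for="module" value="%s"/></attvalues></node>',
    .xmlEscape(nodes), .xmlEscape(nodes), .xmlEscape(unname(mem[nodes])))
  edgeLines <- if (nrow(el)) sprintf(
    '      <edge id="e%d" source="%s" target="%s" weight="%.17g"/>',
    seq_len(nrow(el)) - 1L, .xmlEscape(el[, 1]), .xmlEscape(el[, 2]), w)
  else character()
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <meta><creator>pgcna</creator><keywords>k=%d</keywords></meta>',
            graph@k),
    '  <graph defaultedgetype="undirected" mode="static">',
    '    <attributes class="node">',
    '      <attribute id="module" title="module" type="string"/>',
    '    </attributes>',
    '    <nodes>', nodeLines, '    </nodes>',
    '    <edges>', edgeLines, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GEXF network written by [writeNetworkGEXF()]
#'
#' @param path `.gexf` file.
#' @return list with elements `graph` (a [CorrelationGraph-class]) and
#'   `partition` (a [Partition-class] rebuilt from the node module
#'   attribute; its modularity is recomputed on the read graph).
#' @export
readNetworkGEXF <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodeEls <- xml2::xml_find_all(doc, ".//g:node", ns)
  ids <- xml2::xml_attr(nodeEls, "id")
  mods <- xml2::xml_attr(
    xml2::xml_find_first(nodeEls, ".//g:attvalue[@for='module']", ns), "value")
  edgeEls <- xml2::xml_find_all(doc, ".//g:edge", ns)
  src <- xml2::xml_attr(edgeEls, "source")
  tgt <- xml2::xml_attr(edgeEls, "target")
  w <- as.numeric(xml2::xml_attr(edgeEls, "weight"))
  kw <- xml2::xml_text(xml2::xml_find_first(doc, ".//g:keywords", ns))
  k <- if (!is.na(kw) && grepl("^k=", kw)) as.integer(sub("^k=", "", kw)) else NA_integer_
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(src))
    g <- igraph::add_edges(g, rbind(src, tgt), weight = w)
  cg <- new("CorrelationGraph", graph = g,
            k = if (is.na(k)) 1L else k,
            nGenes = length(ids), nPairsTotal = pairCount(length(ids)),
            nEdgesRetained = length(src))
  mem <- setNames(mods, ids)
  q <- if (length(src)) graphModularity(cg, Partition(mem, 0)) else 0
  list(graph = cg, partition = Partition(mem, q))
}

#' Export a network as GraphML
#'
#' Secondary export format; delegates to [igraph::write_graph()] with the
#' module label attached as a node attribute.
#'
#' @inheritParams writeNetworkGEXF
#' @export
writeNetworkGraphML <- function(graph, partition, path) {
  stopifnot(is(graph, "CorrelationGraph"), is(partition, "Partition"))
  g <- asIgraph(graph)
  mem <- moduleAssignments(partition)
  missing <- setdiff(igraph::V(g)$name, names(mem))
  if (length(missing))
    stop("partition is missing graph node(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  igraph::V(g)$module <- unname(mem[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a partition as a two-column TSV (gene, module)
#' @param partition a [Partition-class].
#' @param path output TSV.
#' @export
writePartitionTSV <- function(partition, path) {
  mem <- moduleAssignments(partition)
  write.table(data.frame(gene = names(mem), module = unname(mem),
                         stringsAsFactors = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition TSV written by [writePartitionTSV()]
#' @param path TSV with columns `gene`, `module`.
#' @return a [Partition-class] (modularity unset).
#' @export
readPartitionTSV <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                    colClasses = "character")
  if (!all(c("gene", "module") %in% colnames(tab)))
    stop("partition file must have columns 'gene' and 'module'")
  Partition(setNames(tab$module, tab$gene), NA_real_)
}
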