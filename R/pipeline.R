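#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Collects every stage parameter of the select -> network -> cluster ->
#' enrich -> dynamics workflow. Every threshold has a named default;
#' the long-course and short-course example configurations under
#' `system.file("extdata", package = "pgcna")` differ only in the
#' selection p-value.
#'
#' @param exprPath,metadataPath,annotationPath input TSVs (see
#'   [readExpressionTSV()], [readProbeAnnotation()]).
#' @param outDir output directory (created if needed).
#' @param gmtPath optional GMT signature file; enables the enrichment
#'   stage (and is required when `strategy = "enrichment"`).
#' @param selection list of [selectionConfig()] arguments.
#' @param k edges retained per gene.
#' @param nRuns,keep,baseSeed Louvain ensemble parameters.
#' @param strategy final-partition selection strategy
#'   (see [selectPartition()]).
#' @param enrichment list of [enrichModules()] filter arguments.
#' @param truthPartitionPath optional planted-truth partition TSV; when
#'   present the manifest reports the adjusted Rand index against it.
#' @param comparePartitionPath optional second-network partition TSV;
#'   when present a gene-level module overlap table is written.
#' @return list with class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(exprPath, metadataPath, annotationPath, outDir,
                           gmtPath = NULL,
                           selection = list(), k = 3, nRuns = 10000,
                           keep = 100, baseSeed = 42,
                           strategy = "max_modularity",
                           enrichment = list(),
                           truthPartitionPath = NULL,
                           comparePartitionPath = NULL) {
  if (is.null(exprPath) || is.null(metadataPath) || is.null(annotationPath))
    stop("expression, metadata and annotation paths are all required")
  paths <- c(exprPath, metadataPath, annotationPath, gmtPath,
             truthPartitionPath, comparePartitionPath)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (strategy == "enrichment" && is.null(gmtPath))
    stop("strategy 'enrichment' requires a GMT signature file")
  sel <- do.call(selectionConfig, selection)
  enr <- utils::modifyList(list(minSize = 5, maxSize = 1500,
                                fdrThreshold = 0.1, top = 30), enrichment)
  structure(list(exprPath = exprPath, metadataPath = metadataPath,
                 annotationPath = annotationPath, gmtPath = gmtPath,
                 outDir = outDir, selection = sel, k = k,
                 nRuns = as.integer(nRuns), keep = as.integer(keep),
                 baseSeed = as.integer(baseSeed), strategy = strategy,
                 enrichment = enr,
                 truthPartitionPath = truthPartitionPath,
                 comparePartitionPath = comparePartitionPath),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipelineConfig()]: top-level keys
#' `expr`, `meta`, `annot`, `gmt`, `out_dir`, `truth_partition`,
#' `compare_partition`, plus sections `selection` (p_threshold,
#' fc_threshold, adjust, variance_threshold), `network` (k), `cluster`
#' (n_runs, keep, base_seed, strategy) and `enrichment` (min_size,
#' max_size, fdr_threshold, top). Relative paths are resolved against
#' the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  rp <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(root, p)
  }
  sel <- y$selection %||% list()
  cl <- y$cluster %||% list()
  pipelineConfig(
    exprPath = rp(y$expr), metadataPath = rp(y$meta),
    annotationPath = rp(y$annot), gmtPath = rp(y$gmt),
    outDir = y$out_dir %||% ".",
    selection = Filter(Negate(is.null), list(
      pThreshold = sel$p_threshold, fcThreshold = sel$fc_threshold,
      adjust = sel$adjust, varianceThreshold = sel$variance_threshold)),
    k = (y$network %||% list())$k %||% 3,
    nRuns = cl$n_runs %||% 10000, keep = cl$keep %||% 100,
    baseSeed = cl$base_seed %||% 42,
    strategy = cl$strategy %||% "max_modularity",
    enrichment = Filter(Negate(is.null), list(
      minSize = (y$enrichment %||% list())$min_size,
      maxSize = (y$enrichment %||% list())$max_size,
      fdrThreshold = (y$enrichment %||% list())$fdr_threshold,
      top = (y$enrichment %||% list())$top)),
    truthPartitionPath = rp(y$truth_partition),
    comparePartitionPath = rp(y$compare_partition))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full workflow
#'
#' Executes selection -> network -> clustering -> (enrichment) ->
#' (overlap) -> dynamics, writing all artifacts into `config$outDir`:
#' `genes.tsv`, `net.gexf`, `net.graphml`, `partition.tsv`,
#' `ensemble.tsv`, `enrichment.tsv` (when a GMT is given),
#' `module_overlap.tsv` (when a comparison partition is given),
#' `profiles_z.tsv`, `profiles_fc.tsv`, `module_profiles.tsv` and a JSON
#' `manifest.json` with seeds, thresholds and per-stage counts. A stage
#' failure aborts with the stage name; the partial manifest is still
#' written with the error recorded.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()],
#'   [readPipelineConfig()]).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("pgcna")),
                   parameters = list(
                     k = config$k, n_runs = config$nRuns,
                     keep = config$keep, base_seed = config$baseSeed,
                     strategy = config$strategy,
                     selection = unclass(config$selection),
                     enrichment = config$enrichment),
                   stages = list(), outputs = character())
  fail <- function(stage, e) {
    manifest$error <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) fail(name, e))
    message(sprintf("[pgcna] %-10s %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  out <- function(name) {
    p <- file.path(config$outDir, name)
    manifest$outputs <<- c(manifest$outputs, name)
    p
  }

  expr <- stage("read", readExpressionTSV(config$exprPath,
                                          config$metadataPath))
  annot <- stage("read", readProbeAnnotation(config$annotationPath))

  geneMat <- NULL
  stage("select", {
    contrasts <- autoContrasts(expr)
    de <- lapply(contrasts, function(ct)
      differentialProbes(expr, ct$A, ct$B, config$selection))
    varSet <- varianceFilter(expr, config$selection)
    selected <- selectInformative(de, varSet)
    geneMat <- mergeProbesToGenes(expr, selected, annot)
    manifest$stages$select <- list(
      n_probes = nrow(expr), n_contrasts = length(contrasts),
      probes_de = length(unique(unlist(lapply(de, function(r)
        c(r$up, r$down))))),
      probes_variance = length(varSet),
      probes_selected = length(selected),
      merged_genes = nrow(geneMat))
    writeExpressionTSV(geneMat, out("genes.tsv"))
  })

  graph <- stage("network", {
    g <- buildNetwork(geneMat, k = config$k)
    manifest$stages$network <- networkStats(g)
    g
  })

  population <- unique(annot$gene[nzchar(annot$gene) & !is.na(annot$gene)])
  sigs <- if (!is.null(config$gmtPath)) readGMT(config$gmtPath)

  partition <- NULL
  stage("cluster", {
    ens <- clusterEnsemble(graph, nRuns = config$nRuns, keep = config$keep,
                           baseSeed = config$baseSeed)
    partition <- selectPartition(ens, config$strategy,
                                  signatures = sigs,
                                  population = population)
    manifest$stages$cluster <- list(
      n_runs = config$nRuns, kept = config$keep,
      best_Q = modularityScore(ensemblePartitions(ens)[[1]]),
      selected_Q = modularityScore(partition),
      modules_found = length(moduleSizes(partition)))
    write.table(ensembleSummary(ens), out("ensemble.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writePartitionTSV(partition, out("partition.tsv"))
    writeNetworkGEXF(graph, partition, out("net.gexf"))
    writeNetworkGraphML(graph, partition, out("net.graphml"))
  })

  if (!is.null(sigs)) stage("enrich", {
    tab <- enrichModules(partition, sigs, population,
                         minSize = config$enrichment$minSize,
                         maxSize = config$enrichment$maxSize,
                         fdrThreshold = config$enrichment$fdrThreshold,
                         top = config$enrichment$top)
    manifest$stages$enrich <- list(
      n_signatures = length(sigs), rows_reported = nrow(tab))
    write.table(tab, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  if (!is.null(config$comparePartitionPath)) stage("overlap", {
    other <- readPartitionTSV(config$comparePartitionPath)
    pop <- unique(c(population, names(moduleAssignments(other))))
    om <- moduleOverlapMatrix(partition, other, pop)
    write.table(overlapSignificance(om), out("module_overlap.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    manifest$stages$overlap <- list(population = length(pop))
  })

  stage("dynamics", {
    med <- groupMedians(geneMat)
    z <- zscoreRows(med)
    fc <- foldChangeVsBaseline(med)
    modProf <- moduleMeanProfile(z, partition)
    write.table(data.frame(gene = rownames(z), z, check.names = FALSE),
                out("profiles_z.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene = rownames(fc), fc, check.names = FALSE),
                out("profiles_fc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(module = rownames(modProf), modProf,
                           check.names = FALSE),
                out("module_profiles.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$dynamics <- list(groups = ncol(med))
  })

  if (!is.null(config$truthPartitionPath)) stage("evaluate", {
    truth <- readPartitionTSV(config$truthPartitionPath)
    tm <- moduleAssignments(truth)
    rm_ <- moduleAssignments(partition)
    shared <- intersect(names(tm), names(rm_))
    manifest$stages$evaluate <- list(
      shared_genes = length(shared),
      ari_vs_truth = adjustedRandIndex(rm_[shared], tm[shared]))
  })

  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
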