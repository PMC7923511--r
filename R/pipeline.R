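## End-to-end orchestration: read -> drop empty -> collapse duplicates ->
## outlier filter -> distances -> dimension -> PAM -> characterization ->
## views, with a manifest recording every parameter, seed and per-stage
## object count so a run is reproducible from the manifest alone.

#' Pipeline configuration
#'
#' Defaults follow the package's reference analysis settings: Jaccard
#' distance, twice-mean dimension selection, loading-length cutoff 0.3,
#' edge threshold 0.6, report cutoff 0.60.
#'
#' @param input path to a matrix file, or a [BinaryMatrix-class] directly.
#' @param format input dialect for [readBinaryMatrix()].
#' @param labels optional label-table path.
#' @param metric distance metric.
#' @param criterion dimension criterion; `dimension` pins q manually.
#' @param dimension optional pinned component count (overrides criterion).
#' @param delta Thresher loading-length cutoff.
#' @param tau adjacency edge threshold.
#' @param cutoff report frequency cutoff.
#' @param downsampleTarget optional target size for the graph view; `NULL`
#'   disables down-sampling.
#' @param seed RNG seed for the down-sampling draw.
#' @param outDir output directory; `NULL` keeps everything in memory.
#' @return config list.
#' @export
pipelineConfig <- function(input, format = "dense", labels = NULL,
                           metric = "jaccard", criterion = "twice-mean",
                           dimension = NULL, delta = 0.3, tau = 0.6,
                           cutoff = 0.60, downsampleTarget = NULL,
                           seed = 1L, outDir = NULL) {
  if (!metric %in% binaryMetrics())
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(binaryMetrics(), collapse = ", "))
  if (is.character(input) && !file.exists(input))
    stop("input file not found: ", input)
  list(input = input, format = format, labels = labels, metric = metric,
       criterion = criterion, dimension = dimension, delta = delta,
       tau = tau, cutoff = cutoff, downsampleTarget = downsampleTarget,
       seed = as.integer(seed), outDir = outDir)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipelineConfig()]
#'   arguments.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' Run the full pattern-recognition pipeline
#'
#' Stages, in order: read/validate, drop empty features, collapse duplicate
#' features, remove outlier features by loading length, sample distances,
#' dimension estimation, PAM at the chosen (or pinned) K, feature
#' clustering into event groups, event-frequency characterization, and the
#' graph/MDS/dendrogram view structures. A failing stage aborts with its
#' name; artifacts from completed stages are kept in the returned list
#' (and on disk when `outDir` is set).
#'
#' @param cfg list from [pipelineConfig()] or [readPipelineConfig()].
#' @return list with the per-stage artifacts and a `manifest` recording
#'   parameters, seeds, and object counts.
#' @export
runPipeline <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()
  m <- stage("read", {
    if (is(cfg$input, "BinaryMatrix")) cfg$input
    else readBinaryMatrix(cfg$input, format = cfg$format,
                          labels = cfg$labels)
  })
  d0 <- ncol(binValues(m))
  m <- stage("drop_empty", dropEmpty(m))
  red <- stage("collapse", collapseDuplicates(m))
  res$map <- red$map
  d1 <- ncol(binValues(red$reduced))
  filt <- stage("thresher_filter",
                thresherFilter(red$reduced, delta = cfg$delta))
  res$filter <- filt
  m2 <- filt$kept
  d2 <- ncol(binValues(m2))
  res$reduced <- m2
  dm <- stage("distance", binaryDistance(m2, metric = cfg$metric,
                                         axis = "samples"))
  res$distance <- dm
  est <- stage("dimension", {
    if (!is.null(cfg$dimension))
      estimateDimension(m2, criterion = "manual", manualQ = cfg$dimension)
    else estimateDimension(m2, criterion = cfg$criterion)
  })
  res$dimension <- est
  K <- chosenDimension(est)
  sp <- stage("pam", pamCluster(dm, K))
  res$partition <- sp
  res$palette <- makePalette(sp)
  fp <- stage("cluster_features", clusterFeatures(m2, metric = cfg$metric))
  res$featurePartition <- fp
  groups <- stage("event_signature", eventSignature(fp, res$map))
  res$events <- groups
  ft <- stage("event_frequency", eventFrequency(m2, sp, groups, res$map))
  res$frequency <- ft
  res$coverage <- coverageSummary(ft)
  res$report <- clusterReport(
    ft,
    prevalence = if (length(diseaseLabels(m)))
      diseasePrevalence(sp, diseaseLabels(m)) else NULL,
    cutoff = cfg$cutoff)
  views <- stage("views", {
    ds <- NULL
    gdm <- dm
    if (!is.null(cfg$downsampleTarget)) {
      ds <- densityDownsample(dm, cfg$downsampleTarget, seed = cfg$seed)
      sub <- as.matrix(dm)[ds$kept, ds$kept]
      gdm <- asBinaryDistance(sub, metric = cfg$metric)
    }
    list(downsample = ds,
         graph = adjacencyGraph(gdm, tau = cfg$tau, partition = sp,
                                palette = res$palette),
         mds = classicalMDS(dm, k = 2),
         dendrogram = hclustWard(dm))
  })
  res$views <- views
  res$manifest <- list(
    package = as.character(utils::packageVersion("cytopattern")),
    parameters = cfg[c("metric", "criterion", "dimension", "delta", "tau",
                       "cutoff", "downsampleTarget", "seed")],
    counts = list(
      samples = nrow(binValues(m2)),
      featuresInput = d0, featuresAfterDedup = d1,
      featuresAfterFilter = d2,
      chosenQ = K, K = K,
      clusterSizes = as.integer(tabulate(clusterLabels(sp), K)),
      featureClusters = nClusters(fp),
      edges = igraph::ecount(views$graph)),
    inputChecksum = sum(binValues(m2)) + 0.0)
  if (!is.null(cfg$outDir)) .write_pipeline(res, m2, cfg)
  res
}

.write_pipeline <- function(res, m2, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outDir, f)
  writeBinaryMatrix(m2, out("reduced_matrix.tsv"))
  writeDedupMap(res$map, out("dedup_map.tsv"))
  sp <- res$partition
  utils::write.table(
    data.frame(object = names(clusterLabels(sp)),
               cluster = unname(clusterLabels(sp)),
               is_medoid = names(clusterLabels(sp)) %in% medoids(sp)),
    out("partition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$report, out("cluster_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(res$views$mds),
                                res$views$mds),
                     out("mds_coordinates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeGraph(res$views$graph, out("adjacency_edges.tsv"))
  jsonlite::write_json(res$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Compare distance metrics on one data set
#'
#' Runs the distance / dimension / PAM leg once per metric and tabulates
#' the chosen dimension, mean silhouette, edge count at the adjacency
#' threshold, and (when ground truth is supplied) the adjusted Rand index
#' against it.
#'
#' @param m a [BinaryMatrix-class] (already reduced, typically).
#' @param metrics character vector of at least two metric ids.
#' @param truth optional named ground-truth labels.
#' @param tau adjacency threshold for the edge count.
#' @param K optional fixed cluster count; default: each metric's chosen
#'   dimension.
#' @return data.frame, one row per metric.
#' @export
compareMetrics <- function(m, metrics, truth = NULL, tau = 0.6, K = NULL) {
  if (length(metrics) < 2L) stop("supply at least two metrics to compare")
  bad <- setdiff(metrics, binaryMetrics())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  est <- estimateDimension(m)     # spectrum is metric-independent
  rows <- lapply(metrics, function(met) {
    dm <- binaryDistance(m, metric = met)
    k <- if (is.null(K)) chosenDimension(est) else K
    sp <- pamCluster(dm, k)
    sil <- if (k >= 2) silhouetteWidths(dm, sp)$mean else NA_real_
    ari <- if (!is.null(truth))
      mclust::adjustedRandIndex(clusterLabels(sp)[names(truth)], truth)
    else NA_real_
    data.frame(metric = met, chosenQ = k, meanSilhouette = sil, ari = ari,
               edges = igraph::ecount(adjacencyGraph(dm, tau = tau)))
  })
  do.call(rbind, rows)
}
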