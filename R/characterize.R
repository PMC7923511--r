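## Cluster characterization: elementary cytogenetic event groups, per-
## sample-cluster event frequencies, threshold coverage, disease
## prevalence, and the two-way heatmap ordering.

#' Cluster features into elementary event groups
#'
#' Runs the feature-axis leg of the pipeline on an already deduplicated
#' (and typically outlier-filtered) matrix: feature-wise distances, PC
#' dimension on the transposed matrix, then PAM with K equal to the chosen
#' dimension. Features that always co-occur end up in the same group, which
#' is what makes the groups read as single cytogenetic events.
#'
#' @param m a reduced [BinaryMatrix-class].
#' @param metric distance metric (default `"jaccard"`).
#' @param K number of feature clusters; default (`NULL`) takes the chosen
#'   dimension of the transposed, correlation-scaled matrix under the
#'   broken-stick criterion -- on the feature axis the question is how many
#'   distinct co-occurrence directions rise above random variance
#'   fragmentation, which is exactly the broken-stick null. Forced to 1
#'   when only one feature remains.
#' @param criterion dimension-selection criterion, see [selectDimension()].
#' @return a [Partition-class] over features.
#' @export
clusterFeatures <- function(m, metric = "jaccard", K = NULL,
                            criterion = "broken-stick") {
  d <- ncol(binValues(m))
  if (d == 1L)
    return(new("Partition",
               labels = stats::setNames(1L, featureNames(m)),
               medoids = featureNames(m), K = 1L, cost = 0))
  if (is.null(K)) {
    est <- estimateDimension(t(binValues(m)), criterion = criterion,
                             standardize = TRUE)
    K <- min(chosenDimension(est), d)
  }
  pamCluster(binaryDistance(m, metric = metric, axis = "features"), K)
}

.classify_types <- function(types) {
  has <- c(Loss = "Loss" %in% types, Gain = "Gain" %in% types,
           Fusion = "Fusion" %in% types)
  if (has["Fusion"]) {
    if (has["Loss"] && has["Gain"]) "mixed"
    else if (has["Loss"]) "fusion+loss"
    else if (has["Gain"]) "fusion+gain"
    else "fusion-only"
  } else if (has["Loss"] && has["Gain"]) "mixed"
  else if (has["Loss"]) "loss-only"
  else if (has["Gain"]) "gain-only"
  else "unknown"
}

#' Describe event groups by bands, types and chromosomes
#'
#' Expands each feature cluster through the dedup map, parses the member
#' headers, and classifies the group by which event types it contains
#' (loss-only, gain-only, fusion-only, fusion+loss, fusion+gain, mixed).
#'
#' @param fp feature [Partition-class] from [clusterFeatures()].
#' @param map [DedupMap-class] used to expand representatives (or `NULL`
#'   when the matrix was never collapsed).
#' @param strict passed to [parseFeatureNames()].
#' @return data.frame with one row per group: `group`, `klass`,
#'   `nChromosomes`, `chromosomes`, `types`, `nBands`, and list-columns
#'   `bands`, `members`.
#' @export
eventSignature <- function(fp, map = NULL, strict = TRUE) {
  groups <- sort(unique(fp@labels))
  rows <- lapply(groups, function(g) {
    reps <- names(fp@labels)[fp@labels == g]
    members <- if (is.null(map)) reps else expandEvents(map, reps)
    info <- parseFeatureNames(members, strict = strict)
    if (any(info$etype == "Unknown") && !strict)
      message("group ", g, " contains unparseable features")
    klass <- .classify_types(unique(info$etype))
    if (klass == "mixed")
      message("event group ", g, " has mixed loss/gain content")
    chroms <- sort(unique(stats::na.omit(info$chromosome)))
    data.frame(group = g, klass = klass,
               nChromosomes = length(chroms),
               chromosomes = paste(chroms, collapse = ","),
               types = paste(sort(unique(info$etype)), collapse = ","),
               nBands = length(unique(info$band)),
               bands = I(list(sort(unique(info$band)))),
               members = I(list(members)))
  })
  do.call(rbind, rows)
}

#' Per-sample-cluster event-group frequencies
#'
#' A sample exhibits an event group if any member feature (expanded through
#' the dedup map) equals 1; the table entry is the fraction of each sample
#' cluster exhibiting each group. Counting is integer-exact; rounding only
#' happens in rendered reports.
#'
#' @param m the [BinaryMatrix-class] the sample partition was computed on
#'   (reduced matrix; members outside its columns are ignored after
#'   expansion back through `map`).
#' @param sp sample [Partition-class].
#' @param groups data.frame from [eventSignature()].
#' @param map [DedupMap-class] or `NULL`.
#' @return a [FrequencyTable-class] (rows = sample clusters, columns =
#'   event groups).
#' @export
eventFrequency <- function(m, sp, groups, map = NULL) {
  vals <- binValues(m)
  lab <- sp@labels[rownames(vals)]
  if (anyNA(lab)) stop("sample partition does not cover the matrix")
  sizes <- tabulate(lab, sp@K)
  if (any(sizes == 0L)) stop("empty sample cluster")
  freq <- matrix(0, sp@K, nrow(groups),
                 dimnames = list(paste0("C", seq_len(sp@K)),
                                 paste0("G", groups$group)))
  for (r in seq_len(nrow(groups))) {
    feats <- intersect(groups$members[[r]], colnames(vals))
    if (!length(feats))    # members may name collapsed duplicates
      feats <- intersect(
        if (is.null(map)) character(0) else representatives(map),
        groups$members[[r]])
    carrier <- rowSums(vals[, feats, drop = FALSE]) > 0
    cnt <- tapply(carrier, lab, sum)
    freq[, r] <- as.numeric(cnt[as.character(seq_len(sp@K))]) / sizes
  }
  new("FrequencyTable", freq = freq, clusterSizes = as.integer(sizes))
}

#' Coverage of clusters by high-frequency events
#'
#' For each threshold t, counts the sample clusters in which at least one
#' event group reaches frequency t (row maximum at or above t). Counts are
#' non-decreasing as t decreases.
#'
#' @param ft a [FrequencyTable-class].
#' @param thresholds decreasing vector in (0, 1]; the defaults mirror the
#'   conventional 99/95/90/80/70/60% ladder.
#' @return named integer vector of cluster counts per threshold.
#' @export
coverageSummary <- function(ft, thresholds = c(0.99, 0.95, 0.90, 0.80,
                                               0.70, 0.60)) {
  if (length(thresholds) == 0L) return(stats::setNames(integer(0), character(0)))
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  rowmax <- apply(ft@freq, 1, max)
  stats::setNames(vapply(thresholds, function(t) sum(rowmax >= t), integer(1)),
                  paste0(thresholds * 100, "%"))
}

#' Most frequent events per sample cluster
#'
#' Lists, per cluster, the event groups reaching the frequency cutoff,
#' sorted by descending frequency with ties broken by group id; clusters
#' with no qualifying event are reported as uncharacterized (`NA` group).
#' Cutoff comparison uses exact (unrounded) frequencies.
#'
#' @param ft a [FrequencyTable-class].
#' @param cutoff frequency cutoff in (0, 1], default 0.60.
#' @return data.frame with columns `cluster`, `size`, `group`, `frequency`.
#' @export
topEvents <- function(ft, cutoff = 0.60) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  rows <- lapply(seq_len(nrow(ft@freq)), function(c) {
    f <- ft@freq[c, ]
    hit <- which(f >= cutoff)
    if (!length(hit))
      return(data.frame(cluster = rownames(ft@freq)[c],
                        size = ft@clusterSizes[c],
                        group = NA_character_, frequency = NA_real_))
    hit <- hit[order(-f[hit], hit)]
    data.frame(cluster = rownames(ft@freq)[c], size = ft@clusterSizes[c],
               group = colnames(ft@freq)[hit], frequency = unname(f[hit]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disease prevalence per sample cluster
#'
#' @param sp sample [Partition-class].
#' @param labels named character vector sample id -> disease; samples
#'   without a label are counted under `"unknown"`.
#' @return matrix of fractions (rows = clusters, columns = diseases); each
#'   row sums to 1.
#' @export
diseasePrevalence <- function(sp, labels) {
  ids <- names(sp@labels)
  dis <- labels[ids]
  dis[is.na(dis)] <- "unknown"
  tab <- table(cluster = sp@labels, disease = dis)
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  rownames(frac) <- paste0("C", rownames(tab))
  frac
}

#' Two-way ordering for the frequency heatmap
#'
#' Rows (event groups) and columns (sample clusters) are each clustered
#' with distance `1 - Pearson correlation` and Ward linkage; correlations
#' with a zero-variance profile are treated as 0 (with a message).
#'
#' @param ft a [FrequencyTable-class] with at least 2 rows and 2 columns.
#' @return list with `rowOrder`, `colOrder` (leaf orders over event groups
#'   and sample clusters) and the two `hclust` trees (`rowTree`,
#'   `colTree`). "Rows" of the heatmap are event groups, matching the
#'   convention of events-by-clusters displays.
#' @export
heatmapOrder <- function(ft) {
  f <- ft@freq
  if (nrow(f) < 2L || ncol(f) < 2L) stop("need >= 2 rows and >= 2 columns")
  corDist <- function(x) {        # rows of x are the objects
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
      message("zero-variance profile(s); correlation set to 0 for them")
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    stats::as.dist(1 - cc)
  }
  rowTree <- stats::hclust(corDist(t(f)), method = "ward.D2")  # event groups
  colTree <- stats::hclust(corDist(f), method = "ward.D2")     # sample clusters
  list(rowOrder = colnames(f)[rowTree$order],
       colOrder = rownames(f)[colTree$order],
       rowTree = rowTree, colTree = colTree)
}

#' Render a Table-1-style cluster report
#'
#' @param ft a [FrequencyTable-class].
#' @param prevalence optional matrix from [diseasePrevalence()].
#' @param cutoff frequency cutoff for reported events.
#' @param digits decimals for rendered frequencies (comparisons are exact).
#' @return data.frame with one row per cluster: id, size, formatted event
#'   list, formatted disease mix; sorted by descending top frequency.
#' @export
clusterReport <- function(ft, prevalence = NULL, cutoff = 0.60, digits = 2) {
  te <- topEvents(ft, cutoff)
  split_te <- split(te, te$cluster)
  rows <- lapply(rownames(ft@freq), function(cl) {
    tc <- split_te[[cl]]
    events <- if (all(is.na(tc$group))) "(uncharacterized)" else
      paste(sprintf("%s:%s", tc$group, formatC(round(tc$frequency, digits),
                                               format = "f", digits = digits)),
            collapse = "; ")
    mix <- ""
    if (!is.null(prevalence) && cl %in% rownames(prevalence)) {
      p <- prevalence[cl, ]
      p <- sort(p[p > 0], decreasing = TRUE)
      mix <- paste(sprintf("%s:%s", names(p),
                           formatC(round(p, digits), format = "f",
                                   digits = digits)), collapse = "; ")
    }
    data.frame(cluster = cl, size = tc$size[1], topFrequency =
                 suppressWarnings(max(tc$frequency, na.rm = TRUE)),
               events = events, diseases = mix)
  })
  out <- do.call(rbind, rows)
  out$topFrequency[!is.finite(out$topFrequency)] <- NA
  out <- out[order(-ifelse(is.na(out$topFrequency), -1, out$topFrequency)), ]
  rownames(out) <- NULL
  out
}
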