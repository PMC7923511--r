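## Planted-structure recovery benchmark on synthetic cohorts.
##
## Runs the full analysis leg (reduce -> filter -> distance -> PAM ->
## dimension -> feature groups -> frequencies) against the generator's
## ground truth, once per seed, and scores cluster recovery, dimension
## recovery, and penetrance recovery. This is the package's own evidence
## that the pipeline finds what was planted.

#' Score pipeline recovery against synthetic ground truth
#'
#' For each seed: simulates a cohort, reduces and filters features,
#' computes Jaccard distances, clusters samples with PAM at the true K,
#' estimates the PC dimension with the default twice-mean rule, clusters
#' features at the true event count, and compares the recovered
#' event-frequency table with the planted penetrances.
#'
#' Sample clusters are matched to planted clusters by Hungarian alignment;
#' each feature group is attributed to the planted event contributing most
#' of its member features. The penetrance error is the mean absolute
#' difference over the planted signature entries (cluster/event pairs with
#' positive planted penetrance); a signature entry whose cluster or event
#' went unrecovered contributes its full penetrance as error.
#'
#' @param seeds integer vector of simulation seeds.
#' @param spec base [simSpec()]; its `seed` field is replaced per run.
#' @param metric distance metric for the run.
#' @return data.frame with one row per seed: `seed`, `ari` (adjusted Rand
#'   index of PAM at true K vs ground truth), `chosenQ` (twice-mean
#'   dimension of the filtered matrix), `freqMAE` (penetrance recovery
#'   error), `featureARI` (feature clusters vs planted events).
#' @export
recoveryStudy <- function(seeds = 1:25, spec = defaultSimSpec(),
                          metric = "jaccard") {
  rows <- lapply(seeds, function(sd) {
    spec$seed <- as.integer(sd)
    sim <- simulateCohort(spec)
    red <- collapseDuplicates(dropEmpty(sim$matrix))
    filt <- thresherFilter(red$reduced)
    m2 <- filt$kept
    dm <- binaryDistance(m2, metric)
    truth <- sim$truth$clusters
    sp <- pamCluster(dm, spec$K)
    ari <- mclust::adjustedRandIndex(
      clusterLabels(sp)[names(truth)], truth)
    est <- estimateDimension(m2)
    fp <- clusterFeatures(m2, metric = metric, K = spec$nEvents)
    truthf <- sim$truth$featureEvent
    fAri <- mclust::adjustedRandIndex(
      expandedFeatureLabels(fp, red$map, truthf),
      truthf[names(expandedFeatureLabels(fp, red$map, truthf))])
    groups <- eventSignature(fp, red$map)
    ft <- eventFrequency(m2, sp, groups, red$map)
    data.frame(seed = sd, ari = ari, chosenQ = chosenDimension(est),
               freqMAE = .penetrance_mae(ft, sp, groups, sim, red$map),
               featureARI = fAri)
  })
  do.call(rbind, rows)
}

## feature labels expanded through the dedup map, for truth comparison
expandedFeatureLabels <- function(fp, map, truthf) {
  lab <- clusterLabels(fp)
  out <- integer(0)
  for (rep in names(lab)) {
    mem <- if (rep %in% representatives(map)) expandEvents(map, rep) else rep
    out <- c(out, stats::setNames(rep(lab[[rep]], length(mem)), mem))
  }
  out[names(out) %in% names(truthf)]
}

.penetrance_mae <- function(ft, sp, groups, sim, map) {
  pen <- sim$truth$penetrance
  truth <- sim$truth$clusters
  truthf <- sim$truth$featureEvent
  refP <- asPartition(truth)
  al <- alignLabels(refP, sp)             # sp cluster -> planted cluster
  ## attribute each recovered group to the planted event with the most
  ## member features
  g2e <- vapply(seq_len(nrow(groups)), function(r) {
    ev <- truthf[groups$members[[r]]]
    ev <- ev[!is.na(ev) & ev != "outlier"]
    if (!length(ev)) NA_character_
    else names(sort(table(ev), decreasing = TRUE))[1]
  }, character(1))
  errs <- c()
  for (c in seq_len(nrow(pen))) for (e in seq_len(ncol(pen))) {
    p <- pen[c, e]
    if (p <= 0) next
    j <- which(al$mapping == c)           # recovered cluster matching c
    g <- which(g2e == colnames(pen)[e])
    got <- if (length(j) == 1L && length(g) >= 1L)
      max(ft@freq[j, g]) else 0
    errs <- c(errs, abs(got - p))
  }
  mean(errs)
}
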