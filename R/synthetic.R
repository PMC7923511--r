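## Synthetic karyotype cohorts with known ground truth.
##
## The generator emulates the structure of band-level LGF data: elementary
## cytogenetic events (a whole-arm gain, a recurrent translocation, ...)
## set a block of B adjacent band features to 1 together; each planted
## sample cluster carries its signature events with a per-event penetrance;
## background noise flips 0 -> 1 (false aberration calls) so event blocks
## stay internally consistent the way real whole-arm events are; and a set
## of low-prevalence nuisance features plays the role of uninformative
## outliers.

.sim_chroms <- c(as.character(1:22), "X", "Y")

#' Simulation specification
#'
#' @param n number of samples.
#' @param K number of planted clusters.
#' @param proportions cluster mixing proportions (default equal), summing
#'   to 1.
#' @param nEvents number of elementary events (feature blocks).
#' @param blockSize bands per event block (B).
#' @param penetrance probability that a cluster-signature event is present
#'   in a member sample.
#' @param noise per-cell 0 -> 1 flip probability.
#' @param nOutliers count of iid nuisance features.
#' @param outlierRate Bernoulli rate of the nuisance features.
#' @param symmetricNoise also flip 1 -> 0 with the same rate (off by
#'   default; robustness testing only).
#' @param seed RNG seed.
#' @return validated `simSpec` list.
#' @export
simSpec <- function(n = 600L, K = 5L, proportions = NULL, nEvents = 12L,
                    blockSize = 8L, penetrance = 0.9, noise = 0.01,
                    nOutliers = 40L, outlierRate = 0.02,
                    symmetricNoise = FALSE, seed = 42L) {
  if (K < 1 || n < K) stop("need n >= K >= 1")
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("mixing proportions must sum to 1")
  if (length(proportions) != K) stop("need one proportion per cluster")
  if (nEvents < K) stop("need at least one event per cluster")
  if (penetrance < 0 || penetrance > 1 || noise < 0 || noise > 1)
    stop("penetrance and noise must lie in [0, 1]")
  ## signatures: event e belongs to cluster ((e - 1) mod K) + 1, so the
  ## clusters have disjoint event sets (distinct cytogenetic entities)
  signatures <- split(seq_len(nEvents), ((seq_len(nEvents) - 1L) %% K) + 1L)
  spec <- list(n = as.integer(n), K = as.integer(K),
               proportions = proportions, nEvents = as.integer(nEvents),
               blockSize = as.integer(blockSize), penetrance = penetrance,
               noise = noise, nOutliers = as.integer(nOutliers),
               outlierRate = outlierRate,
               symmetricNoise = isTRUE(symmetricNoise),
               signatures = signatures, seed = as.integer(seed))
  class(spec) <- "simSpec"
  spec
}

#' Default simulation conditions
#'
#' The reference cohort used across the recovery tests: 600 samples in 5
#' equally likely clusters, 12 events of 8 bands each (disjoint cluster
#' signatures), penetrance 0.9, 1% one-way noise, 40 nuisance features at
#' 2% prevalence, seed 42. Pure: repeated calls return identical specs.
#'
#' @return a `simSpec`.
#' @export
defaultSimSpec <- function() simSpec()

## feature names for event blocks and outliers, in the lgf_io dialect
.sim_feature_names <- function(spec) {
  et <- c("L", "G", "F")
  ev <- unlist(lapply(seq_len(spec$nEvents), function(e) {
    chrom <- .sim_chroms[((e - 1L) %% 12L) + 1L]
    arm <- if (e %% 2L == 0L) "q" else "p"
    code <- et[((e - 1L) %% 3L) + 1L]
    idx <- seq_len(spec$blockSize) + spec$blockSize * ((e - 1L) %/% 12L)
    sprintf("%s%s%d.%s", chrom, arm, idx, code)
  }))
  out <- character(spec$nOutliers)
  if (spec$nOutliers > 0) {
    chroms <- .sim_chroms[13:24]
    out <- vapply(seq_len(spec$nOutliers), function(j) {
      chrom <- chroms[((j - 1L) %% length(chroms)) + 1L]
      arm <- if (j %% 2L == 0L) "p" else "q"
      idx <- 90L + ((j - 1L) %/% length(chroms))   # out of event index range
      sprintf("%s%s%d.%s", chrom, arm, idx, et[((j - 1L) %% 3L) + 1L])
    }, character(1))
  }
  list(event = ev, outlier = out)
}

#' Simulate a cohort
#'
#' Draws cluster memberships from the mixing proportions, plants each
#' signature event (all block features at once) with its penetrance, adds
#' one-way 0 -> 1 noise and the nuisance features, and returns the matrix
#' together with the full ground truth. Deterministic given `spec$seed`.
#'
#' @param spec a [simSpec()].
#' @return list with `matrix` (a [BinaryMatrix-class]; cluster ids stored
#'   as pseudo-disease labels) and `truth` (list: `clusters` named integer,
#'   `featureEvent` named vector mapping features to event id or
#'   `"outlier"`, `penetrance` K x nEvents matrix).
#' @export
simulateCohort <- function(spec = defaultSimSpec()) {
  stopifnot(inherits(spec, "simSpec"))
  fn <- .sim_feature_names(spec)
  withSeed(spec$seed, {
    cl <- sample.int(spec$K, spec$n, replace = TRUE, prob = spec$proportions)
    if (length(unique(cl)) < spec$K)
      stop("empty planted cluster at n = ", spec$n, "; increase n")
    pen <- matrix(0, spec$K, spec$nEvents,
                  dimnames = list(paste0("C", seq_len(spec$K)),
                                  paste0("E", seq_len(spec$nEvents))))
    for (c in seq_len(spec$K)) pen[c, spec$signatures[[c]]] <- spec$penetrance
    ## event carrier draw per sample x event
    carry <- matrix(stats::runif(spec$n * spec$nEvents) <
                      pen[cl, , drop = FALSE], spec$n, spec$nEvents)
    x <- carry[, rep(seq_len(spec$nEvents), each = spec$blockSize),
               drop = FALSE]
    storage.mode(x) <- "integer"
    if (spec$noise > 0) {
      flips <- matrix(stats::runif(length(x)) < spec$noise, nrow(x))
      if (spec$symmetricNoise) x <- (x + flips) %% 2L else x[flips] <- 1L
    }
    if (spec$nOutliers > 0) {
      o <- matrix(as.integer(stats::runif(spec$n * spec$nOutliers) <
                               spec$outlierRate), spec$n)
      x <- cbind(x, o)
    }
    ids <- sprintf("S%04d", seq_len(spec$n))
    dimnames(x) <- list(ids, c(fn$event, fn$outlier))
    truth <- list(
      clusters = stats::setNames(cl, ids),
      featureEvent = stats::setNames(
        c(rep(paste0("E", seq_len(spec$nEvents)), each = spec$blockSize),
          rep("outlier", spec$nOutliers)),
        c(fn$event, fn$outlier)),
      penetrance = pen)
    m <- BinaryMatrix(x, labels = stats::setNames(paste0("C", cl), ids))
    list(matrix = m, truth = truth)
  })
}
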