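#' @import methods
NULL

setOldClass("dist")
setOldClass("hclust")

#' BinaryMatrix: a samples-by-features 0/1 aberration matrix
#'
#' The central container of the package: one row per patient karyotype, one
#' column per band-level Loss/Gain/Fusion (LGF) feature, every entry 0 or 1.
#' An optional disease label per sample supports prevalence reports.
#'
#' @slot binmat integer matrix of 0/1 values; rownames are unique sample ids,
#'   colnames are unique raw feature headers.
#' @slot labels named character vector mapping sample ids to disease names.
#'   May be empty; samples without an entry are treated as "unknown".
#'
#' @seealso [BinaryMatrix()], [readBinaryMatrix()], [parseFeatureNames()]
#' @export
setClass("BinaryMatrix",
  representation(binmat = "matrix", labels = "character"),
  prototype(labels = character(0))
)

setValidity("BinaryMatrix", function(object) {
  m <- object@binmat
  msg <- character(0)
  if (nrow(m) < 1L || ncol(m) < 1L)
    msg <- c(msg, "matrix must have at least one sample and one feature")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "sample ids (rownames) must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "feature headers (colnames) must be present and unique")
  if (!all(m %in% c(0L, 1L)))
    msg <- c(msg, "all entries must be 0 or 1")
  if (length(object@labels) > 0) {
    if (is.null(names(object@labels)))
      msg <- c(msg, "labels must be named by sample id")
    else if (!all(names(object@labels) %in% rownames(m)))
      msg <- c(msg, "labels refer to unknown sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' DedupMap: provenance of collapsed duplicate features
#'
#' Records, for each representative feature retained by
#' [collapseDuplicates()], the full set of original features whose 0/1
#' columns were identical to it. The member lists partition the original
#' feature set, so whole-arm events spanning many bands stay interpretable.
#'
#' @slot members named list; names are representative feature headers, each
#'   element a character vector of original member headers (representative
#'   first).
#' @export
setClass("DedupMap", representation(members = "list"))

setValidity("DedupMap", function(object) {
  mem <- object@members
  if (is.null(names(mem)) || anyDuplicated(names(mem)))
    return("members must be uniquely named by representative")
  all_members <- unlist(mem, use.names = FALSE)
  if (anyDuplicated(all_members))
    return("member lists must be disjoint (a partition)")
  ok <- vapply(seq_along(mem), function(i) mem[[i]][1] == names(mem)[i], logical(1))
  if (!all(ok))
    return("each representative must be the first entry of its member list")
  TRUE
})

#' BinaryDistance: a pairwise distance matrix over samples or features
#'
#' Wraps a `stats::dist` object together with the metric used and the axis
#' (samples or features) it was computed over.
#'
#' @slot dist a `dist` object with `Labels` set to the object ids.
#' @slot metric metric identifier, one of [binaryMetrics()].
#' @slot axis `"samples"` or `"features"`.
#' @export
setClass("BinaryDistance",
  representation(dist = "dist", metric = "character", axis = "character")
)

setValidity("BinaryDistance", function(object) {
  if (!object@axis %in% c("samples", "features"))
    return("axis must be 'samples' or 'features'")
  if (is.null(attr(object@dist, "Labels")))
    return("distance object must carry labels")
  TRUE
})

#' EigenSpectrum: eigenvalues of the column-centered covariance
#'
#' @slot eigenvalues non-increasing, non-negative eigenvalues, padded with
#'   zeros to the number of features; small values are clipped at zero.
#' @slot n number of samples the spectrum was computed from.
#' @export
setClass("EigenSpectrum",
  representation(eigenvalues = "numeric", n = "integer")
)

setValidity("EigenSpectrum", function(object) {
  ev <- object@eigenvalues
  if (any(ev < 0)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev))) return("eigenvalues must be non-increasing")
  TRUE
})

#' DimensionEstimate: Auer-Gervini step function plus the selected dimension
#'
#' Holds the maximum a posteriori component count as a step function of the
#' exponential prior rate theta, the broken-stick reference, the "long step"
#' candidate dimensions, and the dimension finally chosen.
#'
#' @slot steps data.frame with columns `q`, `thetaLo`, `thetaHi`, `length`;
#'   q strictly decreasing as theta increases, intervals tiling (0, thetaMax].
#' @slot brokenStickQ integer broken-stick dimension (may be 0).
#' @slot candidates integer vector of long-step candidate dimensions.
#' @slot chosenQ the selected dimension (>= 1).
#' @slot criterion one of `"twice-mean"`, `"longest-step"`, `"broken-stick"`,
#'   `"manual"`.
#' @export
setClass("DimensionEstimate",
  representation(steps = "data.frame", brokenStickQ = "integer",
                 candidates = "integer", chosenQ = "integer",
                 criterion = "character")
)

setValidity("DimensionEstimate", function(object) {
  if (object@chosenQ < 1L) return("chosenQ must be >= 1")
  if (object@criterion != "manual" && length(object@candidates) &&
      !(object@chosenQ %in% c(object@candidates, object@steps$q)))
    return("chosenQ must come from the step function unless manual")
  TRUE
})

#' Partition: cluster labels plus medoids
#'
#' @slot labels named integer vector, object id -> cluster id in 1..K.
#' @slot medoids character vector of K object ids; `medoids[k]` belongs to
#'   cluster k.
#' @slot K number of clusters.
#' @slot cost total distance of objects to their cluster medoids (NA when
#'   the partition did not come from a distance-based fit).
#' @export
setClass("Partition",
  representation(labels = "integer", medoids = "character", K = "integer",
                 cost = "numeric")
)

setValidity("Partition", function(object) {
  lab <- object@labels
  if (is.null(names(lab))) return("labels must be named by object id")
  if (any(lab < 1L | lab > object@K)) return("labels must lie in 1..K")
  if (length(object@medoids)) {
    if (length(object@medoids) != object@K)
      return("need one medoid per cluster")
    if (!all(object@medoids %in% names(lab)))
      return("medoids must be labeled objects")
    if (any(lab[object@medoids] != seq_len(object@K)))
      return("medoid k must belong to cluster k")
  }
  TRUE
})

#' FrequencyTable: sample-cluster by event-group fractions
#'
#' Entry (c, g) is the fraction of samples in cluster c that carry at least
#' one member feature of event group g.
#'
#' @slot freq numeric matrix in `[0,1]`, rows = sample clusters, columns =
#'   event groups.
#' @slot clusterSizes integer vector of cluster sizes, aligned with rows.
#' @export
setClass("FrequencyTable",
  representation(freq = "matrix", clusterSizes = "integer")
)

setValidity("FrequencyTable", function(object) {
  if (any(object@freq < 0 | object@freq > 1))
    return("frequencies must lie in [0,1]")
  if (length(object@clusterSizes) != nrow(object@freq))
    return("one cluster size per row required")
  TRUE
})
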