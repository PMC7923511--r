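#' Accessors for BinaryMatrix objects
#'
#' @param x a [BinaryMatrix-class] object.
#' @return `sampleNames` and `featureNames` return character vectors;
#'   `binValues` the underlying integer 0/1 matrix; `diseaseLabels` the named
#'   label vector (possibly empty).
#' @name BinaryMatrix-accessors
#' @aliases sampleNames featureNames diseaseLabels binValues
NULL

#' @rdname BinaryMatrix-accessors
#' @export
setMethod("sampleNames", "BinaryMatrix", function(x) rownames(x@binmat))

#' @rdname BinaryMatrix-accessors
#' @export
setMethod("featureNames", "BinaryMatrix", function(x) colnames(x@binmat))

#' @rdname BinaryMatrix-accessors
#' @export
setMethod("diseaseLabels", "BinaryMatrix", function(x) x@labels)

#' @rdname BinaryMatrix-accessors
#' @export
setMethod("binValues", "BinaryMatrix", function(x) x@binmat)

#' @export
setMethod("dim", "BinaryMatrix", function(x) dim(x@binmat))

setMethod("show", "BinaryMatrix", function(object) {
  d <- dim(object@binmat)
  dens <- mean(object@binmat)
  cat("BinaryMatrix:", d[1], "samples x", d[2], "LGF features\n")
  cat(sprintf("  1-density: %.1f%%; disease labels: %s\n", 100 * dens,
              if (length(object@labels)) "yes" else "no"))
})

#' Accessors for DedupMap objects
#'
#' @param x a [DedupMap-class] object.
#' @return `representatives` returns the retained feature headers;
#'   `multiplicity` a named integer vector of member counts.
#' @name DedupMap-accessors
#' @aliases representatives multiplicity
NULL

#' @rdname DedupMap-accessors
#' @export
setMethod("representatives", "DedupMap", function(x) names(x@members))

#' @rdname DedupMap-accessors
#' @export
setMethod("multiplicity", "DedupMap",
          function(x) vapply(x@members, length, integer(1)))

setMethod("show", "DedupMap", function(object) {
  mult <- vapply(object@members, length, integer(1))
  cat("DedupMap:", length(mult), "representatives covering", sum(mult),
      "original features\n")
})

#' Accessors for Partition objects
#'
#' @param x a [Partition-class] object.
#' @return `clusterLabels` returns the named integer label vector, `medoids`
#'   the medoid ids, `nClusters` the cluster count K.
#' @name Partition-accessors
#' @aliases clusterLabels medoids nClusters
NULL

#' @rdname Partition-accessors
#' @export
setMethod("clusterLabels", "Partition", function(x) x@labels)

#' @rdname Partition-accessors
#' @export
setMethod("medoids", "Partition", function(x) x@medoids)

#' @rdname Partition-accessors
#' @export
setMethod("nClusters", "Partition", function(x) x@K)

setMethod("show", "Partition", function(object) {
  sizes <- tabulate(object@labels, object@K)
  cat("Partition:", length(object@labels), "objects in", object@K,
      "clusters\n")
  cat("  sizes:", paste(sizes, collapse = " "), "\n")
  if (!is.na(object@cost)) cat(sprintf("  total cost: %.4f\n", object@cost))
})

#' Accessors for DimensionEstimate objects
#'
#' @param x a [DimensionEstimate-class] object.
#' @return `chosenDimension` returns the selected component count;
#'   `stepFunction` the step table (q, thetaLo, thetaHi, length).
#' @name DimensionEstimate-accessors
#' @aliases chosenDimension stepFunction
NULL

#' @rdname DimensionEstimate-accessors
#' @export
setMethod("chosenDimension", "DimensionEstimate", function(x) x@chosenQ)

#' @rdname DimensionEstimate-accessors
#' @export
setMethod("stepFunction", "DimensionEstimate", function(x) x@steps)

setMethod("show", "DimensionEstimate", function(object) {
  cat("DimensionEstimate: chosen q =", object@chosenQ,
      sprintf("(%s)\n", object@criterion))
  cat("  broken-stick q =", object@brokenStickQ, "; long-step candidates:",
      if (length(object@candidates)) paste(object@candidates, collapse = ", ")
      else "none", "\n")
})

setMethod("show", "BinaryDistance", function(object) {
  cat("BinaryDistance:", attr(object@dist, "Size"), "objects, metric",
      shQuote(object@metric), "over", object@axis, "\n")
})

#' @export
setMethod("as.matrix", "BinaryDistance", function(x, ...) as.matrix(x@dist))

setMethod("show", "EigenSpectrum", function(object) {
  ev <- object@eigenvalues
  cat("EigenSpectrum:", length(ev), "eigenvalues from", object@n,
      "samples;", sum(ev > 0), "positive\n")
})

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable:", nrow(object@freq), "sample clusters x",
      ncol(object@freq), "event groups\n")
})
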