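#' @rdname BinaryMatrix-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname BinaryMatrix-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname BinaryMatrix-accessors
#' @export
setGeneric("diseaseLabels", function(x) standardGeneric("diseaseLabels"))

#' @rdname BinaryMatrix-accessors
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname DedupMap-accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname DedupMap-accessors
#' @export
setGeneric("multiplicity", function(x) standardGeneric("multiplicity"))

#' @rdname Partition-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname Partition-accessors
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' @rdname Partition-accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname DimensionEstimate-accessors
#' @export
setGeneric("chosenDimension", function(x) standardGeneric("chosenDimension"))

#' @rdname DimensionEstimate-accessors
#' @export
setGeneric("stepFunction", function(x) standardGeneric("stepFunction"))
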