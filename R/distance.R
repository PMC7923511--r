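## Binary distance metrics on 2x2 contingency counts.
##
## Every metric is a function of the four counts (N11, N10, N01, N00) of a
## pair of 0/1 vectors, where Nij counts positions with value i in the first
## vector and j in the second. The Jaccard distance 1 - N11/(N11+N10+N01)
## ignores 0-0 matches, which is what makes it suitable for sparse
## aberration profiles; the remaining metrics follow the standard
## binary-similarity survey conventions (Choi et al.).

.metric_names <- c("jaccard", "sokalMichener", "hamming", "russellRao",
                   "pearson", "goodmanKruskal", "manhattan", "canberra",
                   "binary", "euclidean")

#' Registered binary metrics
#'
#' @return character vector of the ten metric identifiers accepted by
#'   [metricDistance()] and [binaryDistance()].
#' @export
binaryMetrics <- function() .metric_names

#' 2x2 contingency counts of two 0/1 vectors
#'
#' @param u,v 0/1 vectors of equal length.
#' @return named integer vector `c(n11, n10, n01, n00)` summing to
#'   `length(u)`.
#' @examples
#' contingencyCounts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
#' @export
contingencyCounts <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length (", length(u), " vs ", length(v), ")")
  if (length(u) < 1L) stop("vectors must be non-empty")
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    stop("inputs must be 0/1 vectors")
  n11 <- sum(u == 1 & v == 1)
  n10 <- sum(u == 1 & v == 0)
  n01 <- sum(u == 0 & v == 1)
  c(n11 = n11, n10 = n10, n01 = n01, n00 = length(u) - n11 - n10 - n01)
}

## Core formulas, vectorized over count vectors of equal length.
## Degenerate-denominator conventions: identical vectors are always at
## distance 0; Pearson with a zero marginal is 0 for equal vectors else 1;
## Goodman-Kruskal with 2n == sigma' is 0.
.metric_fun <- function(name) {
  switch(name,
    jaccard = , binary = function(n11, n10, n01, n00) {
      den <- n11 + n10 + n01
      ifelse(den == 0, 0, 1 - n11 / den)
    },
    sokalMichener = function(n11, n10, n01, n00)
      1 - (n11 + n00) / (n11 + n10 + n01 + n00),
    hamming = function(n11, n10, n01, n00)
      (n10 + n01) / (n11 + n10 + n01 + n00),
    russellRao = function(n11, n10, n01, n00)
      1 - n11 / (n11 + n10 + n01 + n00),
    pearson = function(n11, n10, n01, n00) {
      den2 <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
      phi <- ifelse(den2 > 0,
                    (n11 * n00 - n10 * n01) / sqrt(den2), NA_real_)
      ifelse(den2 > 0, (1 - phi) / 2, ifelse(n10 + n01 == 0, 0, 1))
    },
    goodmanKruskal = function(n11, n10, n01, n00) {
      n <- n11 + n10 + n01 + n00
      sig <- pmax(n11, n10) + pmax(n01, n00) + pmax(n11, n01) + pmax(n10, n00)
      sigp <- pmax(n11 + n01, n10 + n00) + pmax(n11 + n10, n01 + n00)
      ifelse(2 * n == sigp, 0, 1 - (sig - sigp) / (2 * n - sigp))
    },
    manhattan = function(n11, n10, n01, n00) n10 + n01,
    canberra = function(n11, n10, n01, n00) n10 + n01,
    euclidean = function(n11, n10, n01, n00) sqrt(n10 + n01),
    stop("unknown metric '", name, "'; valid metrics: ",
         paste(.metric_names, collapse = ", "))
  )
}

#' Evaluate a binary metric on contingency counts
#'
#' @param counts named vector as returned by [contingencyCounts()], or any
#'   numeric vector `(n11, n10, n01, n00)` in that order.
#' @param metric one of [binaryMetrics()].
#' @return non-negative distance. Normalized metrics (all but `manhattan`,
#'   `canberra`, `euclidean`) lie in `[0,1]`.
#' @examples
#' metricDistance(contingencyCounts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1)),
#'                "jaccard")   # 0.5
#' @export
metricDistance <- function(counts, metric = "jaccard") {
  if (!metric %in% .metric_names)
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(.metric_names, collapse = ", "))
  f <- .metric_fun(metric)
  unname(f(counts[[1]], counts[[2]], counts[[3]], counts[[4]]))
}

#' Pairwise binary distance matrix over samples or features
#'
#' Computes the full pairwise distance matrix for a [BinaryMatrix-class]
#' under one of the ten registered metrics. Contingency counts are obtained
#' for all pairs at once through cross-products of the 0/1 matrix, so the
#' result is independent of evaluation order.
#'
#' @param m a [BinaryMatrix-class].
#' @param metric one of [binaryMetrics()] (default `"jaccard"`).
#' @param axis compare `"samples"` (rows, default) or `"features"` (columns).
#' @return a [BinaryDistance-class] with zero diagonal and exact symmetry.
#' @export
binaryDistance <- function(m, metric = "jaccard",
                           axis = c("samples", "features")) {
  axis <- match.arg(axis)
  if (!metric %in% .metric_names)
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(.metric_names, collapse = ", "))
  x <- binValues(m)
  if (axis == "features") x <- t(x)
  if (nrow(x) < 2L) stop("need at least 2 objects on axis '", axis, "'")
  storage.mode(x) <- "double"
  n11 <- tcrossprod(x)
  ones <- rowSums(x)
  n10 <- outer(ones, ones, function(a, b) a) - n11
  n01 <- t(n10)
  n00 <- ncol(x) - n11 - n10 - n01
  f <- .metric_fun(metric)
  dmat <- f(n11, n10, n01, n00)
  dmat[cbind(seq_len(nrow(x)), seq_len(nrow(x)))] <- 0
  dmat <- (dmat + t(dmat)) / 2   # enforce exact symmetry against fp jitter
  dimnames(dmat) <- list(rownames(x), rownames(x))
  new("BinaryDistance", dist = stats::as.dist(dmat), metric = metric,
      axis = axis)
}

#' Build a BinaryDistance from a plain matrix or dist
#'
#' Convenience for feeding externally computed distances (or toy instances)
#' into the clustering and visualization layers.
#'
#' @param d symmetric matrix or `dist` object with labels.
#' @param metric metric tag to record (default `"external"`).
#' @param axis axis tag to record.
#' @return a [BinaryDistance-class].
#' @export
asBinaryDistance <- function(d, metric = "external", axis = "samples") {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (is.null(rownames(d)))
      dimnames(d) <- list(paste0("o", seq_len(nrow(d))),
                          paste0("o", seq_len(nrow(d))))
    d <- stats::as.dist(d)
  }
  if (is.null(attr(d, "Labels")))
    attr(d, "Labels") <- paste0("o", seq_len(attr(d, "Size")))
  new("BinaryDistance", dist = d, metric = metric, axis = axis)
}

#' Write / read a labeled distance matrix as TSV
#'
#' @param bd a [BinaryDistance-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistance <- function(bd, path) {
  dm <- as.matrix(bd)
  tab <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
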