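## Visual structures on a distance matrix: density-dependent down-sampling,
## thresholded adjacency graphs, classical MDS, Ward dendrograms, and a
## shared cluster palette so the same cluster keeps the same color in every
## view.

#' Density-dependent down-sampling
#'
#' Keeps object i with probability `min(1, TD / LD_i)`, where the local
#' density `LD_i` counts neighbors within `radius` (including i itself) and
#' the target density TD is calibrated by bisection so the expected number
#' of kept objects equals `target`. Dense regions are under-sampled, so
#' rare clusters survive sub-sampling better than under uniform thinning.
#'
#' @param dm a [BinaryDistance-class].
#' @param target requested subset size, `1 <= target <= n`.
#' @param radius neighborhood radius; `"auto"` (default) uses the 5th
#'   percentile of the off-diagonal distances.
#' @param seed integer RNG seed for the Bernoulli draws.
#' @return list with `kept` (object ids), `densities` (named counts),
#'   `radius`, `target`, `seed`, and `keepProb` (per-object probability).
#' @export
densityDownsample <- function(dm, target, radius = "auto", seed = 1L) {
  if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
  d <- as.matrix(dm)
  n <- nrow(d)
  if (target < 1 || target > n) stop("target must lie in 1..", n)
  if (identical(radius, "auto")) {
    radius <- unname(stats::quantile(d[lower.tri(d)], 0.05))
    if (radius <= 0) radius <- min(d[lower.tri(d)][d[lower.tri(d)] > 0], 1)
  }
  if (radius <= 0) stop("radius must be positive")
  ld <- rowSums(d < radius)              # self counts: d[i,i] = 0 < radius
  expected <- function(td) sum(pmin(1, td / ld))
  if (target >= n) {
    td <- max(ld)
  } else {
    lo <- 0; hi <- max(ld)
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      if (expected(mid) < target) lo <- mid else hi <- mid
    }
    td <- hi
  }
  prob <- pmin(1, td / ld)
  keep <- withSeed(seed, stats::runif(n) < prob)
  list(kept = rownames(d)[keep], densities = stats::setNames(ld, rownames(d)),
       radius = radius, target = as.integer(target), seed = as.integer(seed),
       keepProb = stats::setNames(prob, rownames(d)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so deterministic draws do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Thresholded adjacency graph
#'
#' Connects objects i and j by an undirected edge exactly when
#' `d(i, j) < tau`. The default threshold 0.6 on Jaccard distance connects
#' karyotypes sharing more than 40% of their aberrations.
#'
#' @param dm a [BinaryDistance-class].
#' @param tau distance threshold (> 0), default 0.6.
#' @param partition optional [Partition-class]; cluster labels and palette
#'   colors are attached as node attributes.
#' @param palette optional palette from [makePalette()]; defaults to a
#'   palette built from `partition`.
#' @return an `igraph` graph with edge attribute `distance` and node
#'   attributes `cluster`/`color` when a partition is supplied.
#' @export
adjacencyGraph <- function(dm, tau = 0.6, partition = NULL, palette = NULL) {
  if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
  if (tau < 0) stop("tau must be non-negative")
  d <- as.matrix(dm)
  adj <- (d < tau)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  igraph::E(g)$distance <- d[ends]
  if (!is.null(partition)) {
    lab <- partition@labels[rownames(d)]
    if (is.null(palette)) palette <- makePalette(partition)
    igraph::V(g)$cluster <- unname(lab)
    igraph::V(g)$color <- unname(palette[as.character(lab)])
  }
  g
}

#' Write a graph as edge-list TSV or GraphML
#'
#' @param g an `igraph` graph from [adjacencyGraph()].
#' @param path output path.
#' @param format `"edgelist"` (TSV with distance column) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeGraph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    tab <- data.frame(from = el[, 1], to = el[, 2],
                      distance = igraph::E(g)$distance)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and embeds on the top-k
#' eigenvectors; for Euclidean-realizable inputs the embedded distances
#' reproduce the originals. When fewer than k positive eigenvalues exist
#' the remaining coordinates are zero-filled with a warning.
#'
#' @param dm a [BinaryDistance-class].
#' @param k embedding dimension (default 2).
#' @return n x k coordinate matrix with object-id rownames.
#' @export
classicalMDS <- function(dm, k = 2) {
  if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
  if (k < 1) stop("k must be >= 1")
  kEff <- min(k, attr(dm@dist, "Size") - 1L)
  fit <- stats::cmdscale(dm@dist, k = kEff, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive eigenvalue(s); padding to k = ",
            k, " with zeros")
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  colnames(pts) <- paste0("PCo", seq_len(k))
  pts
}

#' Embedding coordinates with a pluggable backend
#'
#' Classical MDS is the built-in backend; any function taking the distance
#' matrix and returning n x 2 coordinates (for example a t-SNE wrapper run
#' with a fixed seed) can be plugged in for non-linear views.
#'
#' @param dm a [BinaryDistance-class].
#' @param method `"mds"` or a function `(dist matrix) -> n x 2 matrix`.
#' @param ... passed to the backend.
#' @return n x 2 coordinate matrix.
#' @export
embedCoords <- function(dm, method = "mds", ...) {
  if (is.function(method)) {
    if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
    coords <- method(as.matrix(dm), ...)
    stopifnot(nrow(coords) == attr(dm@dist, "Size"), ncol(coords) >= 2)
    rownames(coords) <- attr(dm@dist, "Labels")
    coords[, 1:2]
  } else classicalMDS(dm, k = 2, ...)
}

#' Ward-linkage dendrogram
#'
#' Agglomerative clustering with the Ward.D2 convention (Lance-Williams
#' update on squared distances). For non-Euclidean inputs such as Jaccard
#' distances the tree is a heuristic view, not an exact variance
#' decomposition.
#'
#' @param dm a [BinaryDistance-class].
#' @return an `hclust` object with non-decreasing merge heights.
#' @export
hclustWard <- function(dm) {
  if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
  if (attr(dm@dist, "Size") < 2) stop("need at least 2 objects")
  stats::hclust(dm@dist, method = "ward.D2")
}

.base_palette <- c(
  "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#A65628",
  "#F781BF", "#999999", "#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3",
  "#A6D854", "#FFD92F", "#E5C494", "#1B9E77", "#D95F02", "#7570B3")

#' Shared cluster color palette
#'
#' Reference clusters receive colors by descending cluster size (ties by
#' cluster id) from an 18-color base palette; when clusters outnumber the
#' base colors the palette cycles with progressively lighter shades, so
#' every cluster is colored and large clusters get the most distinct hues.
#'
#' @param ref the reference [Partition-class].
#' @return named character vector, cluster id -> color.
#' @export
makePalette <- function(ref) {
  sizes <- tabulate(ref@labels, ref@K)
  ord <- order(-sizes, seq_len(ref@K))
  cols <- .cyclicColors(ref@K)
  out <- character(ref@K)
  out[ord] <- cols
  stats::setNames(out, seq_len(ref@K))
}

.cyclicColors <- function(k) {
  reps <- ceiling(k / length(.base_palette))
  cols <- unlist(lapply(seq_len(reps) - 1L, function(cycle) {
    shade <- cycle / max(1, reps)    # later cycles blend toward white
    vapply(.base_palette, function(col) {
      rgb <- grDevices::col2rgb(col) / 255
      rgb <- rgb + (1 - rgb) * shade * 0.6
      grDevices::rgb(rgb[1], rgb[2], rgb[3])
    }, character(1), USE.NAMES = FALSE)
  }))
  cols[seq_len(k)]
}

#' Route a palette through a label alignment
#'
#' Clusters of `other` matched to a reference cluster inherit its color;
#' unmatched clusters take the next unused palette entries. Together with
#' [alignLabels()] this keeps the same biological cluster the same color
#' across clustering methods.
#'
#' @param other the [Partition-class] to color.
#' @param pal reference palette from [makePalette()].
#' @param map alignment from [alignLabels()] (other -> reference).
#' @return named character vector, other-cluster id -> color.
#' @export
recolor <- function(other, pal, map) {
  mapped <- map$mapping
  out <- character(other@K)
  extra <- .cyclicColors(length(pal) + other@K)
  nextFree <- length(pal)
  for (j in seq_len(other@K)) {
    tgt <- mapped[as.character(j)]
    if (!is.na(tgt) && as.character(tgt) %in% names(pal)) {
      out[j] <- pal[as.character(tgt)]
    } else {
      nextFree <- nextFree + 1L
      out[j] <- extra[nextFree]
    }
  }
  stats::setNames(out, seq_len(other@K))
}
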