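## Deterministic Partitioning Around Medoids.
##
## Classical Kaufman-Rousseeuw BUILD + SWAP with fully specified
## tie-breaking (always the lowest object index), so repeated runs are
## bit-reproducible and small instances can be checked against the
## exhaustive optimum. No random restarts.

#' Partitioning Around Medoids on a distance matrix
#'
#' BUILD greedily adds the medoid giving the largest cost reduction
#' (first medoid: the object minimizing total distance to all others).
#' SWAP repeatedly applies the best-improving medoid/non-medoid exchange
#' until none lowers the total cost. All ties break toward the lowest
#' object index, and assignment ties toward the lowest-indexed medoid, so
#' the result is deterministic.
#'
#' @param dm a [BinaryDistance-class] (or anything [asBinaryDistance()]
#'   accepts).
#' @param K number of clusters, `1 <= K <= n`.
#' @return a [Partition-class]; cluster ids follow the medoids sorted by
#'   object index.
#' @export
pamCluster <- function(dm, K) {
  if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
  d <- as.matrix(dm)
  n <- nrow(d)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must lie in 1..", n)
  ## BUILD
  med <- which.min(colSums(d))
  while (length(med) < K) {
    d1 <- apply(d[, med, drop = FALSE], 1, min)   # current nearest-medoid dist
    gain <- colSums(pmax(d1 - d, 0))              # gain[j]: adding j as medoid
    gain[med] <- -Inf
    med <- c(med, which.max(gain))                # which.max: lowest index tie
  }
  med <- sort(med)
  ## SWAP (K = 1 needs none: BUILD's first medoid is already the global
  ## minimizer of total distance)
  if (K < n && K >= 2L) {
    repeat {
      dmed <- d[, med, drop = FALSE]
      ord <- apply(dmed, 1, order)                # per object: medoid ranking
      nearest <- ord[1, ]
      d1 <- dmed[cbind(seq_len(n), nearest)]
      d2 <- if (K >= 2L) dmed[cbind(seq_len(n), ord[2, ])] else rep(Inf, n)
      best <- list(delta = -1e-12, m = NA, h = NA)
      nonmed <- setdiff(seq_len(n), med)
      for (mi in seq_len(K)) {
        ## removing medoid mi: objects served by it fall back to d2
        fallback <- ifelse(nearest == mi, d2, d1)
        for (h in nonmed) {
          delta <- sum(pmin(fallback, d[, h])) - sum(d1)
          if (delta < best$delta) best <- list(delta = delta, m = mi, h = h)
        }
      }
      if (is.na(best$m)) break
      med[best$m] <- best$h
      med <- sort(med)
    }
  }
  dmed <- d[, med, drop = FALSE]
  lab <- apply(dmed, 1, which.min)                # lowest medoid index on ties
  lab[med] <- seq_len(K)                          # a medoid anchors its cluster
  cost <- sum(dmed[cbind(seq_len(n), lab)])
  ids <- rownames(d)
  new("Partition", labels = stats::setNames(as.integer(lab), ids),
      medoids = ids[med], K = K, cost = cost)
}

#' Construct a Partition from a label vector
#'
#' @param labels named vector of cluster assignments (any values; mapped to
#'   1..K in order of first appearance of the sorted unique values).
#' @param medoids optional medoid ids aligned with clusters 1..K.
#' @return a [Partition-class] with `cost = NA`.
#' @export
asPartition <- function(labels, medoids = character(0)) {
  lev <- sort(unique(labels))
  lab <- stats::setNames(as.integer(match(labels, lev)), names(labels))
  new("Partition", labels = lab, medoids = medoids,
      K = length(lev), cost = NA_real_)
}

#' Silhouette widths for a partition
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance of i to its own
#' cluster's other members and `b` the smallest mean distance to another
#' cluster; members of singleton clusters score 0 by convention.
#'
#' @param dm a [BinaryDistance-class].
#' @param p a [Partition-class] with `K >= 2`.
#' @return list with `widths` (named per-object silhouettes) and `mean`.
#' @export
silhouetteWidths <- function(dm, p) {
  if (!is(dm, "BinaryDistance")) dm <- asBinaryDistance(dm)
  if (p@K < 2L) stop("silhouette requires K >= 2")
  d <- as.matrix(dm)
  lab <- p@labels[rownames(d)]
  sizes <- tabulate(lab, p@K)
  ## mean distance of each object to each cluster
  agg <- vapply(seq_len(p@K), function(c) rowSums(d[, lab == c, drop = FALSE]),
                numeric(nrow(d)))
  s <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    c <- lab[i]
    if (sizes[c] == 1L) { s[i] <- 0; next }
    a <- agg[i, c] / (sizes[c] - 1L)
    b <- min(agg[i, -c] / sizes[-c])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = stats::setNames(s, rownames(d)), mean = mean(s))
}

## Hungarian algorithm (potential/augmenting-path form) for square cost
## minimization; no installed package in the stack provides LSAP.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j+1]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match <- integer(n)          # row -> column
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

#' Align cluster labels between two partitions
#'
#' Cluster ids from independent runs or algorithms are arbitrary; this maps
#' the clusters of `other` onto those of `ref` by maximizing total member
#' overlap (Hungarian assignment on the K_ref x K_other contingency table).
#' Clusters of `other` left unmatched (or matched with zero overlap) get
#' fresh ids beyond K_ref. For very many clusters a greedy matching is
#' available.
#'
#' @param ref,other [Partition-class] objects over the same object set.
#' @param method `"hungarian"` (default) or `"greedy"`; hungarian falls back
#'   to greedy with a warning when `max(K) > 500`.
#' @return list with `mapping` (named integer: other-cluster id ->
#'   ref-or-fresh id) and `overlap` (the contingency matrix used).
#' @export
alignLabels <- function(ref, other, method = c("hungarian", "greedy")) {
  method <- match.arg(method)
  ids <- names(ref@labels)
  if (!setequal(ids, names(other@labels)))
    stop("partitions cover different object sets")
  tab <- table(factor(ref@labels[ids], levels = seq_len(ref@K)),
               factor(other@labels[ids], levels = seq_len(other@K)))
  tab <- matrix(as.numeric(tab), ref@K, other@K)
  if (method == "hungarian" && max(dim(tab)) > 500L) {
    warning("more than 500 clusters; falling back to greedy matching")
    method <- "greedy"
  }
  K <- max(dim(tab))
  mapping <- integer(other@K)
  if (method == "hungarian") {
    sq <- matrix(0, K, K)
    sq[seq_len(ref@K), seq_len(other@K)] <- tab
    match <- .hungarian(-sq)          # maximize overlap
    for (j in seq_len(other@K)) {
      i <- which(match == j)
      mapping[j] <- if (length(i) && i <= ref@K && tab[i, j] > 0) i else NA
    }
  } else {
    ord <- order(-tab)                # cell ranking by overlap
    usedR <- logical(ref@K); usedO <- logical(other@K)
    for (cell in ord) {
      i <- (cell - 1) %% ref@K + 1; j <- (cell - 1) %/% ref@K + 1
      if (!usedR[i] && !usedO[j] && tab[i, j] > 0) {
        mapping[j] <- i; usedR[i] <- usedO[j] <- TRUE
      }
    }
    mapping[mapping == 0] <- NA
  }
  fresh <- ref@K
  for (j in which(is.na(mapping))) {
    fresh <- fresh + 1L
    mapping[j] <- fresh
  }
  list(mapping = stats::setNames(as.integer(mapping), seq_len(other@K)),
       overlap = tab)
}

#' Relabel a partition through an alignment map
#'
#' @param other the [Partition-class] to relabel.
#' @param map result of [alignLabels()].
#' @return a [Partition-class] with identical memberships under the
#'   reference ids.
#' @export
applyAlignment <- function(other, map) {
  newlab <- map$mapping[other@labels]
  K <- max(newlab)
  med <- character(0)
  if (length(other@medoids)) {
    med <- rep(NA_character_, K)
    med[map$mapping] <- other@medoids
  }
  new("Partition",
      labels = stats::setNames(as.integer(newlab), names(other@labels)),
      medoids = if (length(med) && !anyNA(med)) med else character(0),
      K = as.integer(K), cost = other@cost)
}
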