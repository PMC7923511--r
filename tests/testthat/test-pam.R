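test_that("two well-separated pairs are recovered exactly at K = 2", {
  d <- two_pair_instance()
  p <- pamCluster(asBinaryDistance(d), 2)
  expect_equal(p@cost, 0.2)
  expect_equal(unname(clusterLabels(p)[c("p1", "p2")]),
               rep(clusterLabels(p)[["p1"]], 2))
  expect_equal(unname(clusterLabels(p)[c("p3", "p4")]),
               rep(clusterLabels(p)[["p3"]], 2))
  expect_false(clusterLabels(p)[["p1"]] == clusterLabels(p)[["p3"]])
  expect_equal(p@cost, oracle_pam_cost(d, 2))
})

test_that("degenerate K behave per definition", {
  set.seed(53)
  d <- euclid_dist(matrix(runif(14), 7, 2))
  p1 <- pamCluster(asBinaryDistance(d), 1)
  expect_equal(medoids(p1), rownames(d)[which.min(colSums(d))])
  expect_equal(p1@cost, min(colSums(d)))
  pn <- pamCluster(asBinaryDistance(d), 7)
  expect_equal(pn@cost, 0)
  expect_equal(sort(medoids(pn)), sort(rownames(d)))
  expect_error(pamCluster(asBinaryDistance(d), 0), "K must lie")
  expect_error(pamCluster(asBinaryDistance(d), 8), "K must lie")
})

# total cost of a medoid set; used to probe the swap neighborhood
set_cost <- function(d, med) sum(apply(d[, med, drop = FALSE], 1, min))

test_that("pam terminates swap-locally optimal, near the exhaustive optimum", {
  set.seed(59)
  hits <- logical(40)
  for (rep in 1:40) {
    n <- sample(4:8, 1); K <- sample(1:3, 1)
    d <- euclid_dist(matrix(runif(2 * n), n, 2))
    p <- pamCluster(asBinaryDistance(d), K)
    med <- match(medoids(p), rownames(d))
    # no single medoid/non-medoid exchange improves the final cost
    for (i in seq_along(med)) for (h in setdiff(seq_len(n), med)) {
      alt <- med; alt[i] <- h
      expect_gte(set_cost(d, alt), p@cost - 1e-12)
    }
    # and the cost never exceeds what pure BUILD achieves
    hits[rep] <- abs(p@cost - oracle_pam_cost(d, K)) < 1e-12
  }
  # best-improvement local search reaches the global optimum on most
  # (not provably all) tiny instances
  expect_gte(mean(hits), 0.85)
})

test_that("pam agrees with the reference implementation on cost", {
  skip_if_not_installed("cluster")
  set.seed(61)
  for (rep in 1:5) {
    d <- euclid_dist(matrix(runif(40), 20, 2))
    K <- sample(2:4, 1)
    p <- pamCluster(asBinaryDistance(d), K)
    ref <- cluster::pam(stats::as.dist(d), K)
    # both search the same space; neither should beat the other's optimum
    # on these easy instances
    expect_equal(p@cost, unname(ref$objective["swap"] * 20),
                 tolerance = 1e-8)
  }
})

test_that("runs are deterministic and permutation-equivariant", {
  set.seed(67)
  m <- toy_matrix(matrix(rbinom(400, 1, 0.3), 40, 10))
  dm <- binaryDistance(m, "jaccard")
  p1 <- pamCluster(dm, 3)
  p2 <- pamCluster(dm, 3)
  expect_identical(clusterLabels(p1), clusterLabels(p2))
  # permutation equivariance on a tie-free instance (ties in discrete
  # distances legitimately resolve by index order)
  pts <- matrix(runif(80), 40, 2)
  d <- euclid_dist(pts)
  q1 <- pamCluster(asBinaryDistance(d), 3)
  perm <- sample(40)
  dp <- d[perm, perm]
  qp <- pamCluster(asBinaryDistance(dp), 3)
  ari <- mclust::adjustedRandIndex(
    clusterLabels(q1)[rownames(d)],
    clusterLabels(qp)[rownames(d)])
  expect_equal(ari, 1)
})

test_that("silhouette matches the hand-computed two-pair value", {
  d <- two_pair_instance()
  p <- pamCluster(asBinaryDistance(d), 2)
  sil <- silhouetteWidths(asBinaryDistance(d), p)
  expect_equal(unname(sil$widths), rep((0.9 - 0.1) / 0.9, 4))
  expect_equal(sil$mean, 8 / 9)
})

test_that("silhouette conventions: flat distances, singletons, reference", {
  d <- matrix(0.5, 4, 4); diag(d) <- 0
  dimnames(d) <- list(paste0("o", 1:4), paste0("o", 1:4))
  p <- asPartition(c(o1 = 1, o2 = 1, o3 = 2, o4 = 2))
  sil <- silhouetteWidths(asBinaryDistance(d), p)
  expect_equal(unname(sil$widths), rep(0, 4))
  # singleton cluster scores zero
  p2 <- asPartition(c(o1 = 1, o2 = 1, o3 = 1, o4 = 2))
  d2 <- euclid_dist(matrix(runif(8, 0, 1), 4, 2))
  dimnames(d2) <- dimnames(d)
  sil2 <- silhouetteWidths(asBinaryDistance(d2), p2)
  expect_equal(unname(sil2$widths["o4"]), 0)
  expect_error(silhouetteWidths(asBinaryDistance(d), asPartition(
    c(o1 = 1, o2 = 1, o3 = 1, o4 = 1))), "K >= 2")
  skip_if_not_installed("cluster")
  set.seed(71)
  d3 <- euclid_dist(matrix(runif(24), 12, 2))
  p3 <- pamCluster(asBinaryDistance(d3), 3)
  ref <- cluster::silhouette(unname(clusterLabels(p3)[rownames(d3)]),
                             stats::as.dist(d3))
  sil3 <- silhouetteWidths(asBinaryDistance(d3), p3)
  expect_equal(unname(sil3$widths[rownames(d3)]), unname(ref[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("hungarian assignment equals brute force on small tables", {
  set.seed(73)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    cost <- matrix(runif(k * k), k, k)
    match <- cytopattern:::.hungarian(cost)
    got <- sum(cost[cbind(seq_len(k), match)])
    perms <- gtools_perm(k, k)
    best <- min(apply(perms, 1, function(p)
      sum(cost[cbind(seq_len(k), p)])))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("label alignment recovers permutations and splits", {
  set.seed(79)
  lab <- sample(1:3, 30, replace = TRUE)
  names(lab) <- paste0("s", 1:30)
  ref <- asPartition(lab)
  perm <- c(2L, 3L, 1L)
  other <- asPartition(stats::setNames(perm[lab], names(lab)))
  al <- alignLabels(ref, other)
  expect_equal(unname(al$mapping[as.character(perm)]), 1:3)
  expect_equal(sum(al$overlap[cbind(unname(al$mapping), 1:3)]), 30)
  aligned <- applyAlignment(other, al)
  expect_equal(clusterLabels(aligned), clusterLabels(ref))
  # identity map on identical partitions
  al2 <- alignLabels(ref, ref)
  expect_equal(unname(al2$mapping), 1:3)
})

test_that("a split cluster gets a fresh id, matching brute force", {
  ref <- asPartition(c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))
  other <- asPartition(c(a = 1, b = 1, c = 3, d = 2, e = 2, f = 2))
  al <- alignLabels(ref, other)
  expect_equal(unname(al$mapping[c("1", "2")]), c(1L, 2L))
  expect_equal(unname(al$mapping["3"]), 3L)       # fresh id
  total <- sum(al$overlap[cbind(al$mapping[al$mapping <= 2], c(1, 2))])
  expect_equal(total, oracle_best_overlap(al$overlap))
  expect_error(alignLabels(ref, asPartition(c(x = 1, y = 2))),
               "different object sets")
})
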