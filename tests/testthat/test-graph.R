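test_that("adjacency thresholding is exact", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.5
  d[1, 3] <- d[3, 1] <- 0.7
  d[2, 3] <- d[3, 2] <- 0.3
  dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  g <- adjacencyGraph(asBinaryDistance(d), tau = 0.6)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("a-b", "b-c"))
  expect_equal(igraph::ecount(adjacencyGraph(asBinaryDistance(d), tau = 0)),
               0)
  expect_equal(igraph::ecount(adjacencyGraph(asBinaryDistance(d), tau = 10)),
               3)   # n(n-1)/2
})

test_that("edge sets match a full pairwise rescan oracle", {
  set.seed(83)
  m <- toy_matrix(matrix(rbinom(500, 1, 0.3), 25, 20))
  dm <- binaryDistance(m, "jaccard")
  g <- adjacencyGraph(dm, tau = 0.6)
  d <- as.matrix(dm)
  want <- sum(d[upper.tri(d)] < 0.6)
  expect_equal(igraph::ecount(g), want)
  el <- igraph::as_edgelist(g)
  expect_true(all(d[el] < 0.6))
  expect_false(any(el[, 1] == el[, 2]))   # no self loops
})

test_that("classical MDS reconstructs Euclidean-realizable distances", {
  # collinear points 0, 1, 3
  d <- euclid_dist(matrix(c(0, 1, 3), 3, 1))
  xy <- classicalMDS(asBinaryDistance(d), k = 1)
  expect_equal(as.matrix(dist(xy)), unname(d), ignore_attr = TRUE,
               tolerance = 1e-10)
  # unit square in the plane
  sq <- euclid_dist(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  xy2 <- suppressWarnings(classicalMDS(asBinaryDistance(sq), k = 2))
  expect_equal(as.matrix(dist(xy2)), unname(sq), ignore_attr = TRUE,
               tolerance = 1e-8)
  # padding beyond the positive spectrum warns and zero-fills
  expect_warning(xy3 <- classicalMDS(asBinaryDistance(d), k = 3),
                 "padding")
  expect_equal(ncol(xy3), 3L)
  expect_equal(unname(xy3[, 3]), rep(0, 3))
})

test_that("Ward dendrograms merge tight pairs first with monotone heights", {
  d <- two_pair_instance()
  h <- hclustWard(asBinaryDistance(d))
  # first two merges join the pairs, last merge joins the groups
  expect_setequal(list(sort(as.numeric(-h$merge[1, ])),
                       sort(as.numeric(-h$merge[2, ]))),
                  list(c(1, 2), c(3, 4)))
  expect_true(all(h$merge[3, ] > 0))
  expect_true(!is.unsorted(h$height))
  h2 <- hclustWard(asBinaryDistance(euclid_dist(matrix(c(0, 5), 2, 1))))
  expect_equal(h2$height, 5)
  set.seed(89)
  d3 <- euclid_dist(matrix(runif(30), 15, 2))
  expect_true(!is.unsorted(hclustWard(asBinaryDistance(d3))$height))
})

test_that("palettes are stable, size-ordered, and alignment-aware", {
  lab <- stats::setNames(rep(1:3, c(5, 3, 2)), paste0("s", 1:10))
  ref <- asPartition(lab)
  pal <- makePalette(ref)
  expect_identical(pal, makePalette(ref))
  expect_equal(length(unique(pal)), 3L)
  # biggest cluster gets the first base color
  expect_equal(unname(pal["1"]), cytopattern:::.base_palette[1])
  # permuted labels keep the same colors on the same member sets
  perm <- c(3L, 1L, 2L)
  other <- asPartition(stats::setNames(perm[lab], names(lab)))
  al <- alignLabels(ref, other)
  pal2 <- recolor(other, pal, al)
  for (j in 1:3)
    expect_equal(unname(pal2[as.character(perm[j])]),
                 unname(pal[as.character(j)]))
  # many clusters: everything colored, cycling allowed
  big <- asPartition(stats::setNames(rep(1:140, 2), paste0("x", 1:280)))
  palBig <- makePalette(big)
  expect_equal(length(palBig), 140L)
  expect_true(all(nzchar(palBig)))
})

test_that("down-sampling is seeded, calibrated, and keeps everything at target n", {
  set.seed(97)
  d <- euclid_dist(matrix(runif(200), 100, 2))
  dm <- asBinaryDistance(d)
  ds1 <- densityDownsample(dm, 40, seed = 5)
  ds2 <- densityDownsample(dm, 40, seed = 5)
  expect_identical(ds1$kept, ds2$kept)
  expect_true(all(ds1$densities >= 1))
  full <- densityDownsample(dm, 100, seed = 1)
  expect_equal(length(full$kept), 100L)
  expect_error(densityDownsample(dm, 101), "target")
  expect_error(densityDownsample(dm, 10, radius = -1), "radius")
  # uniform density: all keep probabilities equal
  flat <- matrix(0.5, 30, 30); diag(flat) <- 0
  dimnames(flat) <- list(paste0("u", 1:30), paste0("u", 1:30))
  du <- densityDownsample(asBinaryDistance(flat), 12, radius = 0.4, seed = 2)
  expect_equal(length(unique(round(du$keepProb, 12))), 1L)
  # calibration: mean kept count over seeds close to target
  kept <- vapply(1:60, function(s)
    length(densityDownsample(dm, 40, seed = s)$kept), numeric(1))
  expect_lt(abs(mean(kept) - 40), max(1, 0.05 * 40))
})

test_that("embedding hook accepts a pluggable backend", {
  d <- euclid_dist(matrix(runif(20), 10, 2))
  dm <- asBinaryDistance(d)
  co <- embedCoords(dm)                   # built-in MDS
  expect_equal(dim(co), c(10L, 2L))
  backend <- function(dmat) matrix(seq_len(2 * nrow(dmat)), ncol = 2)
  co2 <- embedCoords(dm, method = backend)
  expect_equal(dim(co2), c(10L, 2L))
  expect_equal(rownames(co2), rownames(d))
})
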