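make_fp <- function(groups) {
  # groups: named list group id -> feature headers
  labs <- unlist(lapply(seq_along(groups), function(i)
    stats::setNames(rep(i, length(groups[[i]])), groups[[i]])))
  asPartition(labs)
}

test_that("event signatures classify by the loss/gain/fusion rule table", {
  fp <- make_fp(list(c("13q14.L", "13q13.L", "13q12.L"),
                     c("8q24.F", "14q32.F"),
                     c("1q21.F", "11q13.F", "19p13.F"),
                     c("9p21.L", "9p22.G")))
  sig <- eventSignature(fp)
  expect_equal(sig$klass,
               c("loss-only", "fusion-only", "fusion-only", "mixed"))
  expect_equal(sig$nChromosomes, c(1L, 2L, 3L, 1L))
  expect_equal(sig$chromosomes[2], "14,8")
  expect_equal(sort(sig$bands[[3]]), c("11q13", "19p13", "1q21"))
  # fusion plus loss content
  sig2 <- eventSignature(make_fp(list(c("4p16.F", "14q32.F", "17p13.L"))))
  expect_equal(sig2$klass, "fusion+loss")
})

test_that("signatures expand through the dedup map", {
  vals <- cbind(c(1L, 0L), c(1L, 0L), c(0L, 1L))
  m <- toy_matrix(vals, features = c("13q14.L", "13q13.L", "8q24.F"))
  red <- collapseDuplicates(m)
  fp <- make_fp(list("13q14.L", "8q24.F"))
  sig <- eventSignature(fp, red$map)
  expect_equal(sig$nBands, c(2L, 1L))            # 13q14 + 13q13
  expect_setequal(sig$members[[1]], c("13q14.L", "13q13.L"))
})

test_that("event frequencies count any-member carriers exactly", {
  vals <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L),
                c(0L, 0L, 1L), c(0L, 0L, 1L))
  m <- toy_matrix(vals, features = c("13q14.L", "13q13.L", "8q24.F"))
  sp <- asPartition(stats::setNames(c(1, 1, 1, 1, 2, 2), sampleNames(m)))
  fp <- make_fp(list(c("13q14.L", "13q13.L"), "8q24.F"))
  ft <- eventFrequency(m, sp, eventSignature(fp))
  expect_equal(unname(ft@freq["C1", ]), c(3 / 4, 0))  # 3 of 4 carry group 1
  expect_equal(unname(ft@freq["C2", ]), c(0, 1))
  expect_equal(ft@clusterSizes, c(4L, 2L))
  expect_true(all(ft@freq >= 0 & ft@freq <= 1))
})

test_that("coverage summary counts clusters by row maxima, monotonically", {
  ft <- new("FrequencyTable",
            freq = matrix(c(1.0, 0.2, 0.5, 0.61), 2, 2, byrow = TRUE,
                          dimnames = list(c("C1", "C2"), c("G1", "G2"))),
            clusterSizes = c(3L, 3L))
  expect_equal(unname(coverageSummary(ft, c(0.99, 0.60))), c(1L, 2L))
  expect_length(coverageSummary(ft, numeric(0)), 0L)
  expect_error(coverageSummary(ft, c(0.5, 1.2)), "thresholds")
  set.seed(101)
  for (rep in 1:10) {
    f <- matrix(runif(20), 4, 5)
    rf <- new("FrequencyTable", freq = f, clusterSizes = rep(2L, 4))
    counts <- coverageSummary(rf, sort(runif(5), decreasing = TRUE))
    expect_true(!is.unsorted(counts))
  }
})

test_that("top events respect the cutoff boundary and tie order", {
  ft <- new("FrequencyTable",
            freq = matrix(c(1.0, 0.59, 0.8, 0.8, 0.2, 0.1), 3, 2,
                          byrow = TRUE,
                          dimnames = list(paste0("C", 1:3), c("G1", "G2"))),
            clusterSizes = c(2L, 2L, 2L))
  te <- topEvents(ft, cutoff = 0.6)
  c1 <- te[te$cluster == "C1", ]
  expect_equal(c1$group, "G1")                   # 0.59 below the bar
  c2 <- te[te$cluster == "C2", ]
  expect_equal(c2$group, c("G1", "G2"))          # tie broken by group id
  c3 <- te[te$cluster == "C3", ]
  expect_true(is.na(c3$group))                   # uncharacterized
  # a stricter cutoff reports a subset
  te99 <- topEvents(ft, cutoff = 0.99)
  hits <- function(x) paste(x$cluster, x$group)[!is.na(x$group)]
  expect_true(all(hits(te99) %in% hits(te)))
  expect_error(topEvents(ft, 0), "cutoff")
})

test_that("disease prevalence fractions sum to one with unknown bucket", {
  sp <- asPartition(stats::setNames(rep(1:2, each = 5), paste0("s", 1:10)))
  labs <- stats::setNames(c(rep("CLL", 3), rep("ALL", 2), rep("MM", 5)),
                          paste0("s", 1:10))
  pr <- diseasePrevalence(sp, labs)
  expect_equal(pr["C1", "CLL"], 0.6)
  expect_equal(pr["C1", "ALL"], 0.4)
  expect_equal(unname(rowSums(pr)), c(1, 1))
  # missing labels fall into "unknown"
  pr2 <- diseasePrevalence(sp, labs[1:5])
  expect_equal(pr2["C2", "unknown"], 1)
  expect_equal(unname(rowSums(pr2)), c(1, 1))
})

test_that("heatmap ordering separates anticorrelated profiles", {
  freq <- rbind(c(0.90, 0.85, 0.10, 0.20),   # rows: sample clusters
                c(0.80, 0.90, 0.20, 0.10),   # cols: event groups
                c(0.10, 0.15, 0.90, 0.80),
                c(0.20, 0.10, 0.85, 0.90))
  dimnames(freq) <- list(paste0("C", 1:4), paste0("G", 1:4))
  ft <- new("FrequencyTable", freq = freq, clusterSizes = rep(5L, 4))
  ord <- heatmapOrder(ft)
  expect_setequal(ord$rowOrder, paste0("G", 1:4))
  # the top split separates the gain-like from the loss-like groups
  top <- stats::cutree(ord$rowTree, 2)
  expect_equal(top[["G1"]], top[["G2"]])
  expect_equal(top[["G3"]], top[["G4"]])
  expect_false(top[["G1"]] == top[["G3"]])
  # identical profiles merge at height zero
  f2 <- rbind(a = c(0.5, 0.9, 0.1), b = c(0.5, 0.9, 0.1),
              c = c(0.9, 0.1, 0.5))
  ft2 <- new("FrequencyTable", freq = f2, clusterSizes = rep(2L, 3))
  ord2 <- heatmapOrder(ft2)
  expect_equal(min(ord2$colTree$height), 0)
  expect_error(heatmapOrder(new("FrequencyTable",
                                freq = matrix(0.5, 1, 3),
                                clusterSizes = 1L)), ">= 2")
})

test_that("feature clustering recovers planted event blocks exactly when clean", {
  spec <- simSpec(n = 120, K = 3, nEvents = 3, blockSize = 4,
                  penetrance = 1, noise = 0, nOutliers = 0, seed = 7)
  sim <- simulateCohort(spec)
  red <- collapseDuplicates(dropEmpty(sim$matrix))
  # noiseless blocks collapse to one representative per event
  expect_equal(ncol(binValues(red$reduced)), 3L)
  expect_true(all(multiplicity(red$map) == 4L))
  fp <- clusterFeatures(red$reduced, K = 3)
  truthf <- sim$truth$featureEvent[names(clusterLabels(fp))]
  # one group per planted event: the contingency table is a permutation
  tab <- table(clusterLabels(fp), truthf)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # single-feature edge case
  one <- toy_matrix(matrix(c(1L, 0L), 2, 1), features = "8q24.F")
  fp1 <- clusterFeatures(one)
  expect_equal(nClusters(fp1), 1L)
})

test_that("cluster reports render frequencies and disease mixes", {
  ft <- new("FrequencyTable",
            freq = matrix(c(1.0, 0.2, 0.3, 0.4), 2, 2,
                          dimnames = list(c("C1", "C2"), c("G1", "G2"))),
            clusterSizes = c(4L, 6L))
  rep <- clusterReport(ft, cutoff = 0.6)
  expect_equal(rep$cluster, c("C1", "C2"))       # sorted by top frequency
  expect_match(rep$events[1], "G1:1.00")
  expect_equal(rep$events[2], "(uncharacterized)")
})
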