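test_that("eigen spectrum matches a dense covariance eigendecomposition", {
  set.seed(17)
  vals <- matrix(rbinom(300, 1, 0.4), 30, 10)
  m <- toy_matrix(vals)
  s <- eigenSpectrum(m)
  ref <- eigen(stats::cov(vals), symmetric = TRUE, only.values = TRUE)$values
  ref[ref < 0] <- 0
  expect_equal(s@eigenvalues, ref, tolerance = 1e-10)
  expect_equal(sum(s@eigenvalues), sum(apply(vals, 2, stats::var)),
               tolerance = 1e-10)
})

test_that("rank deficiencies show up as zero eigenvalues", {
  # third column constant: zero variance direction
  vals <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))
  s <- eigenSpectrum(toy_matrix(vals))
  expect_equal(s@eigenvalues[3], 0)
  # duplicated column: rank 1 spectrum
  c1 <- c(1L, 0L, 1L, 0L)
  s2 <- eigenSpectrum(toy_matrix(cbind(c1, c1)))
  expect_equal(sum(s2@eigenvalues > 0), 1L)
  expect_error(eigenSpectrum(toy_matrix(matrix(1L, 3, 3))), "zero")
})

test_that("broken-stick thresholds and rule match the closed form", {
  expect_equal(brokenStickThresholds(3), c(11 / 18, 5 / 18, 1 / 9))
  for (d in c(2, 5, 17, 50)) {
    b <- brokenStickThresholds(d)
    manual <- sapply(seq_len(d), function(k) sum(1 / (k:d)) / d)
    expect_equal(b, manual, tolerance = 1e-12)
    expect_equal(sum(b), 1)
  }
  mk <- function(props) new("EigenSpectrum", eigenvalues = sort(props,
                            decreasing = TRUE), n = 10L)
  expect_equal(brokenStick(mk(c(0.7, 0.2, 0.1))), 1L)
  expect_equal(brokenStick(mk(c(0.65, 0.3, 0.05))), 2L)
  expect_equal(brokenStick(mk(rep(1 / 4, 4))), 0L)
})

rand_spectrum <- function(d = NULL, n = NULL) {
  if (is.null(d)) d <- sample(4:25, 1)
  if (is.null(n)) n <- sample(10:200, 1)
  ev <- sort(rexp(d, rate = runif(1, 0.2, 2)), decreasing = TRUE)
  new("EigenSpectrum", eigenvalues = ev, n = as.integer(n))
}

test_that("hull step function equals the dense-theta-grid argmax", {
  set.seed(23)
  for (rep in 1:40) {
    s <- rand_spectrum()
    st <- auerGervini(s)
    thetaMax <- max(st$thetaHi)
    theta <- sort(runif(60, 0, thetaMax * 1.2))
    expect_equal(stepAt(st, theta), mapDimension(s, theta))
  }
})

test_that("the step function is non-increasing with expected limits", {
  set.seed(29)
  for (rep in 1:20) {
    s <- rand_spectrum()
    st <- auerGervini(s)
    expect_true(all(diff(st$q) < 0))             # q decreasing down the table
    expect_true(all(st$length > 0))
    # intervals tile (0, thetaMax]: largest q sits next to theta = 0
    expect_equal(st$thetaLo[1], 0)
    if (nrow(st) > 1)
      expect_equal(st$thetaLo[-1], st$thetaHi[-nrow(st)])
    # theta -> 0+: the largest hull q; theta beyond thetaMax: 0
    expect_equal(mapDimension(s, min(st$thetaHi) / 2)[1], max(st$q))
    expect_equal(mapDimension(s, max(st$thetaHi) * 2)[1], 0L)
  }
})

test_that("degenerate spectra give the single-step fallback", {
  s <- new("EigenSpectrum", eigenvalues = c(2, 0, 0), n = 5L)
  st <- auerGervini(s)
  expect_equal(st$q, 1L)
})

test_that("long-step candidates follow the twice-mean rule", {
  steps <- data.frame(q = c(11L, 9L, 8L, 5L, 2L),
                      thetaLo = c(0, 1, 2, 3, 4),
                      thetaHi = c(1, 2, 3, 4, 14))
  steps$length <- steps$thetaHi - steps$thetaLo
  s <- rand_spectrum(d = 12)
  est <- selectDimension(steps, s)
  expect_equal(est@candidates, 2L)       # mean 2.8, only 10 > 5.6
  expect_equal(chosenDimension(est), 2L)
  # all steps equal: no candidate, fall back to longest step
  eq <- data.frame(q = c(7L, 4L, 2L), thetaHi = 3:1, thetaLo = 2:0,
                   length = c(1, 1, 1))
  est2 <- selectDimension(eq, s)
  expect_equal(length(est2@candidates), 0L)
  expect_equal(est2@criterion, "longest-step")
  # manual pinning records the override
  est3 <- selectDimension(steps, s, criterion = "manual", manualQ = 7)
  expect_equal(chosenDimension(est3), 7L)
  expect_equal(est3@criterion, "manual")
  expect_error(selectDimension(steps, s, criterion = "manual", manualQ = 99),
               "manualQ")
})

test_that("scale invariance: rescaling the spectrum preserves the selection", {
  set.seed(41)
  for (rep in 1:10) {
    s <- rand_spectrum()
    for (c in c(0.01, 100)) {
      sc <- new("EigenSpectrum", eigenvalues = s@eigenvalues * c, n = s@n)
      expect_equal(brokenStick(sc), brokenStick(s))
      st <- auerGervini(s); stc <- auerGervini(sc)
      # same step ordering (same q sequence); theta axis reparametrized
      expect_equal(stc$q, st$q)
      expect_equal(selectDimension(stc, sc)@chosenQ,
                   selectDimension(st, s)@chosenQ)
    }
  }
})

test_that("loading-length filter keeps structure and drops noise features", {
  spec <- defaultSimSpec()
  dropped_noise <- kept_block <- logical(8)
  for (i in seq_len(8)) {
    spec$seed <- 100L + i
    sim <- simulateCohort(spec)
    filt <- thresherFilter(dropEmpty(sim$matrix))
    role <- sim$truth$featureEvent
    # pick one specific nuisance feature and one block member, check fate
    noise_feat <- names(role)[role == "outlier"][1]
    block_feat <- names(role)[role == "E1"][1]
    dropped_noise[i] <- noise_feat %in% filt$dropped
    kept_block[i] <- !(block_feat %in% filt$dropped)
  }
  expect_gte(mean(dropped_noise), 0.9)
  expect_true(all(kept_block))
})

test_that("delta = 0 drops nothing and lengths are bounded by 1", {
  set.seed(47)
  m <- toy_matrix(matrix(rbinom(200, 1, 0.4), 20, 10))
  filt <- thresherFilter(m, delta = 0, q = 3)
  expect_equal(length(filt$dropped), 0L)
  expect_true(all(filt$lengths <= 1 + 1e-8))
  expect_error(thresherFilter(m, delta = 1), "delta")
})
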