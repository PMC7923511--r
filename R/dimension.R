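## Principal-component dimension estimation.
##
## Two complementary rules are provided. The broken-stick model compares
## variance proportions with the expected ordered fragment lengths of a
## randomly broken unit stick. The Auer-Gervini method places an
## exponentially decaying prior (rate theta) on the component count q and
## reports the maximum a posteriori q as a step function of theta; "long"
## steps mark dimensions that stay optimal over a wide prior range and are
## the natural candidates. The same machinery drives the Thresher-style
## removal of outlier features with short loading vectors.

#' Eigenvalue spectrum of a binary matrix
#'
#' Eigenvalues of the column-mean-centered covariance matrix, computed
#' through the singular values of the centered data for numerical
#' stability. Values below `1e-12 * l1` are clipped to zero and the
#' spectrum is zero-padded to the number of features.
#'
#' @param m a [BinaryMatrix-class] (or plain numeric matrix), rows = the
#'   objects the covariance is taken over.
#' @param standardize divide centered columns by their standard deviation
#'   (correlation-mode PCA); zero-variance columns stay centered only.
#' @return an [EigenSpectrum-class].
#' @export
eigenSpectrum <- function(m, standardize = FALSE) {
  x <- if (is(m, "BinaryMatrix")) binValues(m) else as.matrix(m)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 samples and 2 features")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (standardize) {
    sds <- apply(xc, 2, stats::sd)
    sds[sds == 0] <- 1
    xc <- sweep(xc, 2, sds, "/")
  }
  sv <- svd(xc, nu = 0, nv = 0)$d
  ev <- sv^2 / (nrow(x) - 1)
  if (max(ev) == 0) stop("constant matrix: total variance is zero")
  ev[ev < 1e-12 * ev[1]] <- 0
  ev <- c(ev, numeric(max(0L, ncol(x) - length(ev))))[seq_len(ncol(x))]
  new("EigenSpectrum", eigenvalues = ev, n = nrow(x))
}

#' Broken-stick dimension
#'
#' The expected proportion of variance of the k-th largest of d random
#' stick fragments is `b_k = (1/d) * sum_{i=k..d} 1/i`. The rule keeps the
#' largest q such that the observed variance proportion exceeds `b_k` for
#' every `k <= q`; 0 when even the first component falls short.
#'
#' @param s an [EigenSpectrum-class].
#' @return integer dimension (possibly 0).
#' @export
brokenStick <- function(s) {
  ev <- s@eigenvalues
  d <- length(ev)
  prop <- ev / sum(ev)
  b <- rev(cumsum(rev(1 / seq_len(d)))) / d
  above <- prop > b
  if (!above[1]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

#' Broken-stick thresholds
#'
#' @param d number of components.
#' @return numeric vector `b_1..b_d`.
#' @export
brokenStickThresholds <- function(d) rev(cumsum(rev(1 / seq_len(d)))) / d

## Profile log-likelihood of retaining q components with isotropic residual
## variance, for q = 0..qmax (qmax keeps the residual sum strictly positive).
.ag_loglik <- function(ev, n) {
  pos <- sum(ev > 0)
  d <- length(ev)
  qmax <- min(d - 1L, pos - 1L)
  q <- 0:qmax
  cums <- c(0, cumsum(log(ev[seq_len(qmax)])))
  tails <- sum(ev) - c(0, cumsum(ev[seq_len(qmax)]))
  L <- -(n / 2) * (cums + (d - q) * log(tails / (d - q)))
  list(q = q, L = L)
}

#' Auer-Gervini step function
#'
#' With an exponential prior of rate theta on the component count, the MAP
#' dimension is `argmax_q [L(q) - theta * q]`, a non-increasing step
#' function of theta. It is computed exactly from the upper convex hull of
#' the profile log-likelihood points `(q, L(q))`: the breakpoint between
#' consecutive hull vertices `q_a < q_b` is the slope
#' `(L(q_b) - L(q_a)) / (q_b - q_a)`.
#'
#' @param s an [EigenSpectrum-class].
#' @return data.frame with columns `q`, `thetaLo`, `thetaHi`, `length`, one
#'   row per step with `q >= 1`, ordered by increasing theta (decreasing q);
#'   the intervals tile `(0, thetaMax]`, beyond which the MAP dimension is 0.
#'   Degenerate spectra with fewer than two positive eigenvalues give a
#'   single unit-length step at q = 1.
#' @export
auerGervini <- function(s) {
  ev <- s@eigenvalues
  if (sum(ev > 0) < 2L)
    return(data.frame(q = 1L, thetaLo = 0, thetaHi = 1, length = 1))
  ll <- .ag_loglik(ev, s@n)
  q <- ll$q; L <- ll$L
  ## upper convex hull, left to right (Andrew's monotone chain)
  hull <- integer(0)
  for (i in seq_along(q)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      ## drop b if it lies on or below chord a--i
      if ((L[b] - L[a]) * (q[i] - q[a]) <= (L[i] - L[a]) * (q[b] - q[a]))
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  hq <- q[hull]; hL <- L[hull]
  ## slopes between consecutive hull vertices; only segments with positive
  ## slope are reachable with theta > 0 (L never optimal above the max)
  slopes <- diff(hL) / diff(hq)
  keep <- which(slopes > 0)
  if (!length(keep))
    return(data.frame(q = integer(0), thetaLo = numeric(0),
                      thetaHi = numeric(0), length = numeric(0)))
  ## vertices reachable for theta > 0: hull points up to the last positive
  ## slope; vertex j is optimal for theta in (slope_out(j), slope_in(j)]
  top <- max(keep) + 1L              # vertex index with the largest reachable q
  vq <- hq[seq_len(top)]
  vs <- slopes[seq_len(top - 1L)]    # slope into each vertex from its left
  steps <- data.frame(
    q = vq[-1],                      # exclude q = 0 (= vq[1] = hull base)
    thetaLo = c(vs[-1], 0),          # slope out of each vertex; 0 for the top
    thetaHi = vs)                    # slope into each vertex from the left
  steps <- steps[steps$q >= 1, , drop = FALSE]
  steps <- steps[order(-steps$q), , drop = FALSE]
  steps$length <- steps$thetaHi - steps$thetaLo
  rownames(steps) <- NULL
  steps
}

#' Look up the step function at given prior rates
#'
#' @param steps step data.frame from [auerGervini()].
#' @param theta numeric vector of prior rates (> 0).
#' @return integer MAP dimension per theta: the step whose interval
#'   `(thetaLo, thetaHi]` contains it, 0 beyond the last breakpoint.
#' @export
stepAt <- function(steps, theta) {
  vapply(theta, function(th) {
    hit <- steps$q[steps$thetaLo < th & th <= steps$thetaHi]
    if (length(hit)) as.integer(hit[1]) else 0L
  }, integer(1))
}

#' MAP dimension at given prior rates (reference evaluation)
#'
#' Direct argmax of the penalized profile likelihood on a theta grid; used
#' as the independent check of the hull construction and exported for
#' plotting.
#'
#' @param s an [EigenSpectrum-class].
#' @param theta numeric vector of prior rates (> 0).
#' @return integer vector of MAP dimensions, one per theta. Ties are broken
#'   toward the smaller dimension (the prior prefers parsimony).
#' @export
mapDimension <- function(s, theta) {
  ll <- .ag_loglik(s@eigenvalues, s@n)
  vapply(theta, function(th) {
    obj <- ll$L - th * ll$q
    ll$q[which.max(obj)]   # first max = smallest q on ties
  }, integer(1))
}

#' Select the number of components
#'
#' Long-step candidates are steps (q >= 1) whose theta-interval length
#' exceeds twice the mean step length. The default criterion picks the
#' smallest such candidate -- the most parsimonious dimension that stays
#' optimal over a wide prior range -- falling back to the single longest
#' step when no step passes the twice-mean bar; `"broken-stick"` defers to
#' the broken-stick rule and `"manual"` pins q explicitly (as one does to
#' reproduce a published choice).
#'
#' @param steps step data.frame from [auerGervini()].
#' @param s the [EigenSpectrum-class] the steps came from.
#' @param criterion `"twice-mean"` (default), `"longest-step"`,
#'   `"broken-stick"`, or `"manual"`.
#' @param manualQ dimension to pin when `criterion = "manual"`.
#' @return a [DimensionEstimate-class].
#' @export
selectDimension <- function(steps, s,
                            criterion = c("twice-mean", "longest-step",
                                          "broken-stick", "manual"),
                            manualQ = NULL) {
  criterion <- match.arg(criterion)
  bs <- brokenStick(s)
  cand <- integer(0)
  if (nrow(steps)) {
    long <- steps$length > 2 * mean(steps$length)
    cand <- sort(as.integer(steps$q[long]))
  }
  longest <- if (nrow(steps))
    as.integer(steps$q[which.max(steps$length)]) else 1L
  chosen <- switch(criterion,
    "twice-mean" = if (length(cand)) min(cand) else longest,
    "longest-step" = longest,
    "broken-stick" = max(bs, 1L),
    "manual" = {
      d <- length(s@eigenvalues)
      if (is.null(manualQ) || manualQ < 1 || manualQ > d - 1)
        stop("manualQ must lie in 1..", d - 1)
      as.integer(manualQ)
    })
  if (criterion == "twice-mean" && !length(cand)) criterion <- "longest-step"
  new("DimensionEstimate", steps = steps, brokenStickQ = bs,
      candidates = cand, chosenQ = chosen, criterion = criterion)
}

#' Full dimension estimate for a matrix
#'
#' Convenience wrapper: spectrum, Auer-Gervini steps, selection.
#'
#' @inheritParams eigenSpectrum
#' @inheritParams selectDimension
#' @return a [DimensionEstimate-class].
#' @export
estimateDimension <- function(m, criterion = "twice-mean", manualQ = NULL,
                              standardize = FALSE) {
  s <- eigenSpectrum(m, standardize = standardize)
  selectDimension(auerGervini(s), s, criterion = criterion, manualQ = manualQ)
}

#' Thresher-style outlier feature filter
#'
#' Features are scored by the length of their loading vector on the top q
#' principal components of the feature-standardized matrix: feature j gets
#' `sqrt(sum_k l_k v_jk^2)` over the retained eigenpairs `(l_k, v_k)`.
#' Under correlation-mode PCA this length lies in `[0, 1]` and features
#' below `delta` contribute little to the retained structure; they are
#' removed as uninformative outliers.
#'
#' @param m a [BinaryMatrix-class].
#' @param delta loading-length cutoff in (0, 1), default 0.3.
#' @param q number of components for the loadings; default (`NULL`) selects
#'   it with [estimateDimension()] on the standardized matrix.
#' @param standardize use correlation-mode PCA (default `TRUE`).
#' @return list with `kept` (a [BinaryMatrix-class]), `dropped` (character
#'   vector of removed feature headers), `lengths` (named loading lengths),
#'   and `q` (the dimension used).
#' @export
thresherFilter <- function(m, delta = 0.3, q = NULL, standardize = TRUE) {
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)")
  x <- binValues(m)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sds <- apply(xc, 2, stats::sd)
  zero_var <- sds == 0
  if (standardize) {
    sds[zero_var] <- 1
    xc <- sweep(xc, 2, sds, "/")
  }
  sv <- svd(xc)
  ev <- sv$d^2 / (nrow(x) - 1)
  ev[ev < 1e-12 * ev[1]] <- 0
  if (is.null(q)) {
    spec <- new("EigenSpectrum",
                eigenvalues = c(ev, numeric(max(0L, ncol(x) - length(ev)))),
                n = nrow(x))
    q <- selectDimension(auerGervini(spec), spec)@chosenQ
  }
  q <- min(q, sum(ev > 0))
  load2 <- sv$v[, seq_len(q), drop = FALSE]^2 %*% ev[seq_len(q)]
  lengths <- stats::setNames(sqrt(drop(load2)), colnames(x))
  lengths[zero_var] <- 0   # constant features carry no structure
  keep <- lengths >= delta
  if (!any(keep))
    stop("all features fall below delta = ", delta,
         "; use a lower cutoff")
  list(kept = BinaryMatrix(x[, keep, drop = FALSE],
                           labels = diseaseLabels(m)),
       dropped = colnames(x)[!keep],
       lengths = lengths, q = as.integer(q))
}
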