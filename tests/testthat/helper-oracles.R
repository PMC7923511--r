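# Independent oracles: literal per-position transcriptions of the metric
# formulas, exhaustive searches, and small fixture builders. These must
# stay independent of the package implementation paths they check.

# literal per-position recount of each metric formula
oracle_metric <- function(u, v, metric) {
  n11 <- sum(u == 1 & v == 1); n10 <- sum(u == 1 & v == 0)
  n01 <- sum(u == 0 & v == 1); n00 <- sum(u == 0 & v == 0)
  n <- length(u)
  switch(metric,
    jaccard = , binary =
      if (n11 + n10 + n01 == 0) 0 else 1 - n11 / (n11 + n10 + n01),
    sokalMichener = 1 - (n11 + n00) / n,
    hamming = (n10 + n01) / n,
    russellRao = 1 - n11 / n,
    pearson = {
      den <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
      if (den == 0) { if (n10 + n01 == 0) 0 else 1 }
      else (1 - (n11 * n00 - n10 * n01) / sqrt(den)) / 2
    },
    goodmanKruskal = {
      sig <- max(n11, n10) + max(n01, n00) + max(n11, n01) + max(n10, n00)
      sigp <- max(n11 + n01, n10 + n00) + max(n11 + n10, n01 + n00)
      if (2 * n == sigp) 0 else 1 - (sig - sigp) / (2 * n - sigp)
    },
    manhattan = sum(abs(u - v)),
    canberra = sum(ifelse(u + v == 0, 0, abs(u - v) / (u + v))),
    euclidean = sqrt(sum((u - v)^2)),
    stop("oracle: unknown metric ", metric))
}

rand_binary <- function(n, p = 0.4) as.integer(runif(n) < p)

# small labeled BinaryMatrix from a plain 0/1 matrix
toy_matrix <- function(vals, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(vals)))
  if (is.null(features))
    features <- sprintf("%dq%d.L", seq_len(ncol(vals)), seq_len(ncol(vals)))
  dimnames(vals) <- list(samples, features)
  BinaryMatrix(vals)
}

# exhaustive PAM optimum: best medoid set over all size-K subsets
oracle_pam_cost <- function(d, K) {
  n <- nrow(d)
  sets <- utils::combn(n, K)
  best <- Inf
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# exhaustive assignment: best injective mapping other -> ref by overlap
oracle_best_overlap <- function(tab) {
  kr <- nrow(tab); ko <- ncol(tab)
  if (kr >= ko) {
    perms <- gtools_perm(kr, ko)
    best <- -Inf
    for (i in seq_len(nrow(perms)))
      best <- max(best, sum(tab[cbind(perms[i, ], seq_len(ko))]))
  } else {
    perms <- gtools_perm(ko, kr)
    best <- -Inf
    for (i in seq_len(nrow(perms)))
      best <- max(best, sum(tab[cbind(seq_len(kr), perms[i, ])]))
  }
  best
}

# all ordered selections of k from n (small n only)
gtools_perm <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- gtools_perm(n, k - 1)
    sub <- sub[apply(sub != i, 1, all), , drop = FALSE]
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

# four points forming two well-separated pairs (within 0.1, across 0.9)
two_pair_instance <- function() {
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  d
}

# distance matrix of points in Euclidean space
euclid_dist <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("e", seq_len(nrow(d))),
                      paste0("e", seq_len(nrow(d))))
  d
}
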