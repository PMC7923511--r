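## Redundant-feature reduction.
##
## Whole-chromosome and whole-arm events set many cytoband features to the
## same 0/1 column; collapsing identical columns before any distance or
## dimension computation removes this redundancy while a DedupMap keeps the
## provenance so reports can expand representatives back to full band lists.

#' Drop all-zero feature columns
#'
#' All-zero features carry no pattern information and would only inflate
#' 0-0 counts for metrics that use them.
#'
#' @param m a [BinaryMatrix-class].
#' @return a [BinaryMatrix-class] whose every column has at least one 1.
#' @export
dropEmpty <- function(m) {
  vals <- binValues(m)
  keep <- colSums(vals) > 0L
  if (!any(keep)) stop("all features are empty; nothing to analyze")
  if (any(!keep))
    message("dropEmpty: removed ", sum(!keep), " empty feature(s)")
  BinaryMatrix(vals[, keep, drop = FALSE], labels = diseaseLabels(m))
}

#' Collapse duplicate feature columns
#'
#' Features whose 0/1 columns are identical across all samples are collapsed
#' to a single representative (the first member in original column order).
#' The returned [DedupMap-class] records the members of each representative.
#'
#' @param m a [BinaryMatrix-class].
#' @return list with elements `reduced` (the collapsed [BinaryMatrix-class])
#'   and `map` (a [DedupMap-class]).
#' @examples
#' vals <- cbind("1p1.L" = c(1L, 0L), "1p2.L" = c(1L, 0L), "2q1.G" = c(0L, 1L))
#' rownames(vals) <- c("s1", "s2")
#' red <- collapseDuplicates(BinaryMatrix(vals))
#' representatives(red$map)
#' @export
collapseDuplicates <- function(m) {
  vals <- binValues(m)
  key <- apply(vals, 2, paste, collapse = "")
  first <- !duplicated(key)
  reps <- colnames(vals)[first]
  grp <- match(key, key[first])
  members <- split(colnames(vals), grp)
  names(members) <- reps
  reduced <- BinaryMatrix(vals[, first, drop = FALSE],
                          labels = diseaseLabels(m))
  list(reduced = reduced, map = new("DedupMap", members = members))
}

#' Expand representatives back to original features
#'
#' @param map a [DedupMap-class].
#' @param reps character vector of representative headers (subset of
#'   `representatives(map)`).
#' @return character vector: the union of the member lists of `reps`.
#' @export
expandEvents <- function(map, reps) {
  if (length(reps) == 0L) return(character(0))
  unknown <- setdiff(reps, representatives(map))
  if (length(unknown))
    stop("unknown representative(s): ", paste(unknown, collapse = ", "))
  unname(unlist(map@members[reps]))
}

#' Display name of a representative with its multiplicity
#'
#' Reports label a representative with a `".x<multiplicity>"` suffix when it
#' stands for more than one original band feature, so collapsed whole-arm
#' events remain visible as such.
#'
#' @param map a [DedupMap-class].
#' @param reps representative headers (default: all).
#' @return named character vector of display names.
#' @export
reportNames <- function(map, reps = representatives(map)) {
  mult <- multiplicity(map)[reps]
  stats::setNames(ifelse(mult > 1L, paste0(reps, ".x", mult), reps), reps)
}

#' Serialize / deserialize a DedupMap as two-column TSV
#'
#' @param map a [DedupMap-class].
#' @param path output path.
#' @return `path` invisibly; `readDedupMap` returns the [DedupMap-class].
#' @export
writeDedupMap <- function(map, path) {
  tab <- data.frame(
    representative = rep(representatives(map), multiplicity(map)),
    member = unlist(map@members, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDedupMap
#' @export
readDedupMap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  members <- split(tab$member, factor(tab$representative,
                                      levels = unique(tab$representative)))
  new("DedupMap", members = members)
}
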