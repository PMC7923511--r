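## I/O and feature-name parsing for binary LGF matrices.
##
## The canonical feature-header dialect is "<band>.<L|G|F>" (e.g. "8q24.F");
## upstream callers (such as CytoGPS exports) that use a different naming
## scheme can supply their own regular expression with named-style capture
## groups for band and event type.

.default_feature_pattern <- "^([0-9]+|X|Y)([pq](?:[0-9]+(?:\\.[0-9]+)?)?)\\.([LGF])$"

.etype_codes <- c(L = "Loss", G = "Gain", F = "Fusion")

#' Construct a BinaryMatrix
#'
#' @param values matrix (or data.frame) coercible to an integer 0/1 matrix,
#'   rows = samples, columns = LGF features. Must carry row and column names.
#' @param labels optional named character vector of disease labels keyed by
#'   sample id.
#' @return a validated [BinaryMatrix-class] object.
#' @examples
#' m <- BinaryMatrix(matrix(c(1L, 0L, 1L, 1L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("8q24.F", "13q14.L"))))
#' dim(m)
#' @export
BinaryMatrix <- function(values, labels = character(0)) {
  values <- as.matrix(values)
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "non-binary value %s at sample '%s', feature '%s'",
      format(values[bad[1]]), rownames(values)[rc[1]], colnames(values)[rc[2]]))
  }
  storage.mode(values) <- "integer"
  if (is.null(labels)) labels <- character(0)
  new("BinaryMatrix", binmat = values, labels = labels)
}

#' Parse LGF feature headers into cytoband and event type
#'
#' Splits headers such as `"8q24.F"` into the cytoband (`"8q24"`), its
#' chromosome (`"8"`), arm, and the event type (`Loss`, `Gain`, `Fusion`).
#' Chromosomes are validated against 1-22, X, Y.
#'
#' @param raw character vector of feature headers.
#' @param pattern regular expression with three capture groups (chromosome,
#'   arm+digits, single-letter event code L/G/F). The default implements the
#'   `"<band>.<L|G|F>"` dialect.
#' @param strict if `TRUE` (default) unparseable headers are an error; if
#'   `FALSE` they pass through with `etype = "Unknown"` and a warning.
#' @return data.frame with columns `raw`, `band`, `chromosome`, `arm`,
#'   `etype`.
#' @examples
#' parseFeatureNames(c("8q24.F", "13q14.L"))
#' @export
parseFeatureNames <- function(raw, pattern = .default_feature_pattern,
                              strict = TRUE) {
  m <- regmatches(raw, regexec(pattern, raw))
  ok <- lengths(m) == 4L
  if (any(!ok)) {
    offenders <- raw[!ok]
    ## distinguish a bad chromosome token from a generally malformed header
    loose <- regmatches(offenders,
                        regexec("^(chr)?([0-9]+|[A-Za-z])([pq].*)\\.([LGF])$",
                                offenders))
    chrom_msg <- vapply(loose, function(g)
      if (length(g) == 5L) sprintf(" (invalid chromosome '%s')", g[3]) else "",
      character(1))
    msg <- sprintf("unparseable feature header '%s'%s", offenders, chrom_msg)
    if (strict) stop(paste(msg, collapse = "; "))
    warning("passing through with etype=Unknown: ",
            paste(offenders, collapse = ", "))
  }
  chrom <- ifelse(ok, vapply(m, function(g) g[2][1], character(1)), NA_character_)
  arm <- ifelse(ok, vapply(m, function(g) g[3][1], character(1)), NA_character_)
  code <- ifelse(ok, vapply(m, function(g) g[4][1], character(1)), NA_character_)
  data.frame(
    raw = raw,
    band = ifelse(ok, paste0(chrom, arm), raw),
    chromosome = chrom,
    arm = arm,
    etype = ifelse(ok, .etype_codes[code], "Unknown"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a binary LGF matrix
#'
#' Two plain-text dialects are supported. `"dense"` is a TSV/CSV with a
#' header row; the first column holds sample ids and the remaining columns
#' 0/1 values under feature headers. `"triplet"` is a sparse TSV listing
#' `(sample_id, feature, value)` rows for the 1 cells, preceded by manifest
#' comment lines `#samples:` and `#features:` so all-zero karyotypes (and
#' features) survive round trips.
#'
#' @param path input file path.
#' @param format `"dense"` or `"triplet"`.
#' @param sep field separator for the dense dialect (default tab).
#' @param labels optional path to a two-column TSV (sample_id, disease).
#' @param transpose set `TRUE` if a dense file stores features as rows.
#' @return a validated [BinaryMatrix-class].
#' @seealso [writeBinaryMatrix()]
#' @export
readBinaryMatrix <- function(path, format = c("dense", "triplet"),
                             sep = "\t", labels = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, colClasses = "character")
    ids <- tab[[1]]
    if (anyDuplicated(ids))
      stop("duplicate sample id: ", ids[duplicated(ids)][1])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals)) {
      rc <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[rc[1]], colnames(vals)[rc[2]]))
    }
    rownames(vals) <- ids
    if (transpose) vals <- t(vals)
  } else {
    lines <- readLines(path)
    man <- lines[startsWith(lines, "#")]
    sm <- sub("^#samples:\\s*", "", man[startsWith(man, "#samples:")])
    fm <- sub("^#features:\\s*", "", man[startsWith(man, "#features:")])
    if (!length(sm) || !length(fm))
      stop("triplet file lacks #samples:/#features: manifest lines")
    ids <- strsplit(sm, ",", fixed = TRUE)[[1]]
    feats <- strsplit(fm, ",", fixed = TRUE)[[1]]
    if (anyDuplicated(ids))
      stop("duplicate sample id: ", ids[duplicated(ids)][1])
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    vals <- matrix(0, length(ids), length(feats),
                   dimnames = list(ids, feats))
    if (length(body) > 1L) {   # first body line is the column header
      trip <- utils::read.table(text = body, header = TRUE, sep = "\t",
                                colClasses = "character")
      v <- suppressWarnings(as.numeric(trip[[3]]))
      bad <- which(is.na(v) | !(v %in% c(0, 1)))
      if (length(bad))
        stop(sprintf("non-binary value '%s' at sample '%s', feature '%s'",
                     trip[[3]][bad[1]], trip[[1]][bad[1]], trip[[2]][bad[1]]))
      if (!all(trip[[1]] %in% ids))
        stop("triplet sample not in manifest: ",
             trip[[1]][!trip[[1]] %in% ids][1])
      if (!all(trip[[2]] %in% feats))
        stop("triplet feature not in manifest: ",
             trip[[2]][!trip[[2]] %in% feats][1])
      vals[cbind(trip[[1]], trip[[2]])] <- v
    }
  }
  lab <- character(0)
  if (!is.null(labels)) lab <- readDiseaseLabels(labels)
  BinaryMatrix(vals, labels = lab)
}

#' Read a sample-to-disease label table
#'
#' @param path two-column TSV with header (sample_id, disease).
#' @return named character vector keyed by sample id.
#' @export
readDiseaseLabels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write a binary LGF matrix
#'
#' Inverse of [readBinaryMatrix()]: `readBinaryMatrix(writeBinaryMatrix(m))`
#' reproduces `m` bit-exactly in both dialects. Disease labels, when present,
#' are written alongside as `<path>.labels.tsv`.
#'
#' @param m a [BinaryMatrix-class].
#' @param path output file path.
#' @param format `"dense"` or `"triplet"`.
#' @param sep field separator for the dense dialect.
#' @return `path`, invisibly.
#' @export
writeBinaryMatrix <- function(m, path, format = c("dense", "triplet"),
                              sep = "\t") {
  format <- match.arg(format)
  vals <- binValues(m)
  if (format == "dense") {
    tab <- data.frame(sample = rownames(vals), vals, check.names = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("#samples: ", paste(rownames(vals), collapse = ",")),
                 paste0("#features: ", paste(colnames(vals), collapse = ",")),
                 "sample_id\tfeature\tvalue"), con)
    idx <- which(vals == 1L, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      writeLines(paste(rownames(vals)[idx[, 1]], colnames(vals)[idx[, 2]],
                       "1", sep = "\t"), con)
    }
  }
  if (length(diseaseLabels(m))) {
    lab <- diseaseLabels(m)
    utils::write.table(
      data.frame(sample_id = names(lab), disease = unname(lab)),
      paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}
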