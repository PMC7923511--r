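## Base-graphics views. The heavy lifting (coordinates, trees, palettes)
## happens in graph_view; these helpers just draw.

#' Scree plot of an eigen spectrum
#'
#' @param s an [EigenSpectrum-class].
#' @param nmax show at most this many leading components.
#' @return invisibly, the plotted variance proportions.
#' @export
plotScree <- function(s, nmax = 50L) {
  ev <- s@eigenvalues
  prop <- 100 * ev / sum(ev)
  k <- min(nmax, length(prop))
  graphics::barplot(prop[seq_len(k)], names.arg = seq_len(k),
                    xlab = "component", ylab = "% variance explained",
                    border = NA, col = "grey40")
  invisible(prop)
}

#' Plot the Auer-Gervini step function
#'
#' MAP component count against the prior rate theta; long-step candidates
#' and the chosen dimension are marked.
#'
#' @param est a [DimensionEstimate-class].
#' @return invisibly, the step table.
#' @export
plotStepFunction <- function(est) {
  st <- est@steps
  if (!nrow(st)) { graphics::plot.new(); return(invisible(st)) }
  graphics::plot(NA, xlim = c(0, max(st$thetaHi)),
                 ylim = c(0, max(st$q)), xlab = expression(theta),
                 ylab = "MAP number of components")
  graphics::segments(st$thetaLo, st$q, st$thetaHi, st$q, lwd = 2)
  if (length(est@candidates))
    graphics::abline(h = est@candidates, col = "orange", lty = 3)
  graphics::abline(h = est@chosenQ, col = "purple", lty = 2)
  invisible(st)
}

#' Scatter plot of 2-D embedding coordinates with cluster colors
#'
#' @param coords n x 2 matrix from [classicalMDS()] or [embedCoords()].
#' @param partition optional [Partition-class] for coloring.
#' @param palette optional palette; defaults to [makePalette()] of the
#'   partition.
#' @return invisibly, `coords`.
#' @export
plotEmbedding <- function(coords, partition = NULL, palette = NULL) {
  col <- "grey30"
  if (!is.null(partition)) {
    if (is.null(palette)) palette <- makePalette(partition)
    col <- unname(palette[as.character(partition@labels[rownames(coords)])])
  }
  graphics::plot(coords[, 1], coords[, 2], pch = 19, cex = 0.6, col = col,
                 xlab = colnames(coords)[1], ylab = colnames(coords)[2])
  invisible(coords)
}
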