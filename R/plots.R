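#' Scatter plot of PC scores in true colors
#'
#' Draws samples at their (PC1, PC2) coordinates, colored by their true RGB
#' population mean — the ground-truth legend of the whole framework: the
#' point color shows where the sample really lives in feature space, its
#' position shows where PCA put it.
#'
#' @param model a [PCAModel-class] fitted on `data`.
#' @param data the matching [ColorDataset-class].
#' @param specs optional list of [ColorSpec-class] supplying true colors;
#'   otherwise colors default to the per-population centroid of the first
#'   three features (clamped to [0, 1]).
#' @param pcs which two components to draw.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data.frame of plotted coordinates.
#' @export
plotScores <- function(model, data, specs = NULL, pcs = c(1L, 2L), ...) {
  stopifnot(is(model, "PCAModel"))
  labels <- populationLabels(data)
  S <- model@scores[, pcs, drop = FALSE]
  if (!is.null(specs)) {
    cmap <- vapply(specs, function(s)
      grDevices::rgb(s@mean[1], s@mean[2], s@mean[3]), character(1))
    names(cmap) <- vapply(specs, slot, character(1), "name")
  } else {
    X <- sampleMatrix(data)[, seq_len(min(3L, length(model@center))),
                            drop = FALSE]
    pops <- unique(labels)
    cmap <- vapply(pops, function(g) {
      m <- pmin(pmax(colMeans(X[labels == g, , drop = FALSE]), 0), 1)
      m <- c(m, rep(0, 3 - length(m)))
      grDevices::rgb(m[1], m[2], m[3])
    }, character(1))
  }
  ev <- 100 * model@explained_fraction[pcs]
  graphics::plot(S[, 1L], S[, 2L], col = cmap[labels], pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1L], ev[1L]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2L], ev[2L]), ...)
  invisible(data.frame(S, population = labels))
}

#' Distance-distortion scatter (x = y diagnostic)
#'
#' Plots reduced-space against true-space distances; undistorted pairs sit
#' on the dotted x = y line. Population pairs are drawn as filled symbols
#' over any individual-pair cloud.
#'
#' @param report a [DistanceReport-class] (normalize first to mirror the
#'   0-1 layout).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted pairs.
#' @export
plotDistanceReport <- function(report, ...) {
  stopifnot(is(report, "DistanceReport"))
  p <- report@pairs
  x <- if (report@normalized) p$true_norm else p$true_distance
  y <- if (report@normalized) p$pc_norm else p$pc_distance
  pop <- p$kind == "population"
  graphics::plot(x, y, pch = ifelse(pop, 17, 1),
                 col = ifelse(pop, "black", "grey60"),
                 xlab = if (report@normalized) "true distance (normalized)"
                        else "true distance",
                 ylab = sprintf("top-%d PC distance%s", report@k,
                                if (report@normalized) " (normalized)"
                                else ""), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(p)
}
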