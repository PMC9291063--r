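#' Render a phasor plot
#'
#' Draws the unit circle and a 2D histogram of the valid-pixel phasor
#' coordinates, optionally with cursors. The displayed Y axis is inverted so
#' that a red shift of the emission spectrum moves phasors clockwise — the
#' conventional orientation of spectral phasor plots. The stored (X, Y)
#' values follow the printed transform verbatim (counterclockwise-positive
#' angles in math axes); only the rendering flips.
#'
#' @param pim A [phasor_image()], or a list of `phasor` objects.
#' @param cursors Optional list of [cursor()]s to overlay.
#' @param bins Histogram bins per axis.
#' @param main Plot title.
#' @export
plot_phasor <- function(pim, cursors = NULL, bins = 128L,
                        main = "spectral phasor plot") {
  if (inherits(pim, "phasor_image")) {
    X <- pim$X[pim$valid]; Y <- pim$Y[pim$valid]
  } else {
    stopifnot(is.list(pim), all(vapply(pim, inherits, logical(1), "phasor")))
    X <- vapply(pim, function(p) p$X, numeric(1))
    Y <- vapply(pim, function(p) p$Y, numeric(1))
  }
  graphics::plot(NA, xlim = c(-1.05, 1.05), ylim = c(1.05, -1.05),
                 asp = 1, xlab = "X", ylab = "Y", main = main)
  tt <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(tt), sin(tt), col = "grey40")
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  if (length(X)) {
    br <- seq(-1, 1, length.out = bins + 1L)
    xi <- findInterval(X, br, rightmost.closed = TRUE)
    yi <- findInterval(Y, br, rightmost.closed = TRUE)
    counts <- table(factor(xi, seq_len(bins)), factor(yi, seq_len(bins)))
    mids <- (br[-1] + br[-(bins + 1L)]) / 2
    nz <- which(counts > 0, arr.ind = TRUE)
    dens <- log1p(as.numeric(counts[nz]))
    cols <- grDevices::hcl.colors(64, "viridis")[
      pmax(1, ceiling(64 * dens / max(dens)))]
    graphics::points(mids[nz[, 1]], mids[nz[, 2]], pch = 15,
                     cex = 0.4, col = cols)
  }
  if (!is.null(cursors)) for (cu in cursors) {
    graphics::lines(cu$center[1] + cu$radius * cos(tt),
                    cu$center[2] + cu$radius * sin(tt), col = cu$color,
                    lwd = 2)
    graphics::text(cu$center[1], cu$center[2] - 1.3 * cu$radius, cu$label,
                   col = cu$color, cex = 0.8)
  }
  invisible(NULL)
}

#' Save a phasor plot to PNG
#' @inheritParams plot_phasor
#' @param path Output PNG path.
#' @param size Image size in pixels (square).
#' @export
save_phasor_plot <- function(pim, path, cursors = NULL, bins = 128L,
                             size = 800L) {
  grDevices::png(path, width = size, height = size)
  on.exit(grDevices::dev.off())
  plot_phasor(pim, cursors = cursors, bins = bins)
  invisible(path)
}
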