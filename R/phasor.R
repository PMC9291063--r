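#' Spectral phasor of an emission spectrum
#'
#' The spectral phasor maps a spectrum to the normalized real and imaginary
#' parts of its first Fourier harmonic:
#'
#' \deqn{X = \frac{\sum_\lambda I(\lambda) \cos(2\pi n \lambda / L)}
#'                {\sum_\lambda I(\lambda)}, \qquad
#'       Y = \frac{\sum_\lambda I(\lambda) \sin(2\pi n \lambda / L)}
#'                {\sum_\lambda I(\lambda)}}
#'
#' with harmonic `n = 1` and `lambda` taken as the channel offset from the
#' axis start, so the first channel has phase 0 and the coordinates do not
#' depend on the absolute wavelength origin. `L` is the amplitude of the
#' spectral range, by default the axis span `(count - 1) * step` (320 nm for
#' a 420-740 nm axis at 2.5 nm steps).
#'
#' X and Y always lie in \[-1, 1\] and, for nonnegative spectra, the phasor
#' lies inside the unit circle: it is an intensity-weighted mean of unit
#' vectors. The phasor angle encodes the spectral center of mass (red shift
#' = increasing angle in these math axes, rendered clockwise by
#' [plot_phasor()]); the modulus is inversely related to the spectral
#' bandwidth. The transform is invariant to overall intensity scaling.
#'
#' @param s An [emission_spectrum()]; must be non-empty.
#' @param n Harmonic, a positive integer. The method is defined and
#'   validated for `n = 1`; higher harmonics are accepted but experimental.
#' @param L Period of the phase term in nm; default the axis span.
#' @return An object of class `phasor`: list with `X`, `Y` and `weight`
#'   (total intensity). Use [phasor_angle()] and [phasor_modulus()] for the
#'   polar view.
#' @examples
#' ax <- wavelength_axis(420, 2.5, 129)
#' lam <- axis_wavelengths(ax)
#' p <- compute_phasor(emission_spectrum(dnorm(lam, 550, 20), ax))
#' c(p$X, p$Y, phasor_modulus(p))
#' @export
compute_phasor <- function(s, n = 1L, L = NULL) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("harmonic n must be a positive integer", call. = FALSE)
  stop_if_empty(s, "phasor transform")
  if (is.null(L)) L <- axis_span(s$axis)
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  phase <- 2 * pi * n * axis_offsets(s$axis) / L
  w <- sum(s$intensities)
  new_phasor(sum(s$intensities * cos(phase)) / w,
             sum(s$intensities * sin(phase)) / w, w)
}

new_phasor <- function(X, Y, weight) {
  structure(list(X = X, Y = Y, weight = weight), class = "phasor")
}

#' @export
print.phasor <- function(x, ...) {
  cat(sprintf("<phasor> X = %.4f, Y = %.4f (angle %.4f rad, modulus %.4f), weight %g\n",
              x$X, x$Y, phasor_angle(x), phasor_modulus(x), x$weight))
  invisible(x)
}

#' Polar coordinates of a phasor
#'
#' `phasor_angle()` is `atan2(Y, X)` in radians, counterclockwise-positive
#' in standard math axes; `phasor_modulus()` is `sqrt(X^2 + Y^2)`.
#' @param p A `phasor`.
#' @export
phasor_angle <- function(p) atan2(p$Y, p$X)

#' @rdname phasor_angle
#' @export
phasor_modulus <- function(p) sqrt(p$X^2 + p$Y^2)

#' Unwrap a sequence of angles
#'
#' Removes 2*pi jumps so that consecutive differences are at most pi in
#' magnitude; used to check angle monotonicity along a red-shifting family
#' of spectra.
#' @param theta Numeric vector of angles, radians.
#' @return Unwrapped angles; first element unchanged.
#' @export
unwrap_angles <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

#' Combine phasors by intensity-weighted vector addition
#'
#' Phasors obey vector algebra: the phasor of a sum of spectra is the
#' intensity-weighted centroid of the component phasors. This is exact, not
#' approximate, because the transform is a ratio of linear functionals.
#'
#' @param parts List of `phasor` objects (at least one).
#' @return A `phasor` with `weight` the total weight.
#' @export
combine_phasors <- function(parts) {
  if (inherits(parts, "phasor")) parts <- list(parts)
  stopifnot(is.list(parts), length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "phasor")))
  w <- vapply(parts, function(p) p$weight, numeric(1))
  W <- sum(w)
  if (W <= 0)
    stop("empty spectrum (total intensity 0): combined phasor is undefined",
         call. = FALSE)
  new_phasor(sum(w * vapply(parts, function(p) p$X, numeric(1))) / W,
             sum(w * vapply(parts, function(p) p$Y, numeric(1))) / W, W)
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance on a histogram; used as the default
#' background criterion for [phasor_image()] since dark (background) and
#' stained (particle) pixels form well-separated intensity modes.
#'
#' @param x Numeric vector of intensities.
#' @param nbins Histogram bins.
#' @return Threshold value; pixels strictly above it count as foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || diff(range(x)) == 0) return(max(x, 0))
  breaks <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Per-pixel phasor transform of a lambda stack
#'
#' Applies [compute_phasor()] to every pixel whose total intensity exceeds
#' the background threshold; other pixels are masked invalid (their X/Y are
#' `NA`, never a silent NaN). The default threshold is Otsu's method
#' computed on `log1p` of the total-intensity image and mapped back to
#' intensity units: fluorescence fields are sparse bright foreground over a
#' tight dark background, and on that distribution linear-domain Otsu
#' systematically lands inside the broad foreground mode (discarding dim
#' particles) while log-domain Otsu falls in the gap between the modes.
#' Pass a number for an absolute cutoff, or 0 to keep every pixel with any
#' signal.
#'
#' @param img A [spectral_image()].
#' @param n Harmonic (default 1).
#' @param background_threshold `"otsu"` (log-domain, the default),
#'   `"otsu-linear"`, or a nonnegative number. Pixels with total intensity
#'   strictly greater than the threshold are valid.
#' @param L Optional period override, see [compute_phasor()].
#' @return An object of class `phasor_image`: matrices `X`, `Y`, `weight`
#'   (all `[height, width]`), logical `valid` mask, the `axis` and
#'   `pixel_size` carried over, and the resolved `threshold`.
#' @export
phasor_image <- function(img, n = 1L, background_threshold = "otsu",
                         L = NULL) {
  stopifnot(inherits(img, "spectral_image"))
  if (is.null(L)) L <- axis_span(img$axis)
  d <- dim(img$voxels)
  npix <- d[1] * d[2]
  M <- matrix(img$voxels, nrow = npix, ncol = d[3])
  w <- rowSums(M)
  thr <- if (identical(background_threshold, "otsu")) {
    expm1(otsu_threshold(log1p(w)))
  } else if (identical(background_threshold, "otsu-linear")) {
    otsu_threshold(w)
  } else {
    stopifnot(is.numeric(background_threshold),
              length(background_threshold) == 1L,
              background_threshold >= 0)
    background_threshold
  }
  valid <- w > thr
  if (!any(valid))
    warning("all pixels fall below the background threshold; phasor image has no valid pixels",
            call. = FALSE)
  phase <- 2 * pi * n * axis_offsets(img$axis) / L
  X <- Y <- rep(NA_real_, npix)
  if (any(valid)) {
    X[valid] <- (M[valid, , drop = FALSE] %*% cos(phase)) / w[valid]
    Y[valid] <- (M[valid, , drop = FALSE] %*% sin(phase)) / w[valid]
  }
  structure(list(X = matrix(X, d[1], d[2]), Y = matrix(Y, d[1], d[2]),
                 weight = matrix(w, d[1], d[2]),
                 valid = matrix(valid, d[1], d[2]),
                 axis = img$axis, pixel_size = img$pixel_size,
                 harmonic = as.integer(n), L = L, threshold = thr),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("<phasor_image> %d x %d pixels, %d valid (threshold %.3g), harmonic %d\n",
              ncol(x$X), nrow(x$X), sum(x$valid), x$threshold, x$harmonic))
  invisible(x)
}

#' @export
dim.phasor_image <- function(x) dim(x$X)

#' Export valid phasor pixels as CSV
#'
#' Columns `x,y,X,Y,weight` (1-based pixel coordinates), one row per valid
#' pixel.
#' @param pim A [phasor_image()].
#' @param path Output CSV path.
#' @export
write_phasor_csv <- function(pim, path) {
  stopifnot(inherits(pim, "phasor_image"))
  idx <- which(pim$valid, arr.ind = TRUE)
  df <- data.frame(x = idx[, 2], y = idx[, 1],
                   X = pim$X[idx], Y = pim$Y[idx], weight = pim$weight[idx])
  df <- df[order(df$y, df$x), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a phasor image as a 3-page float TIFF (X, Y, weight)
#'
#' Invalid pixels carry 0 in all three pages.
#' @param pim A [phasor_image()].
#' @param path Output TIFF path.
#' @export
write_phasor_tiff <- function(pim, path) {
  stopifnot(inherits(pim, "phasor_image"))
  X <- pim$X; Y <- pim$Y
  X[!pim$valid] <- 0; Y[!pim$valid] <- 0
  write_tiff(array(c(X, Y, pim$weight), dim = c(dim(X), 3)), path,
             dtype = "float64")
  invisible(path)
}
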