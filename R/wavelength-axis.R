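#' Uniform wavelength axis of a lambda stack
#'
#' A lambda stack samples emission on a uniform wavelength grid. The axis is
#' fully described by the wavelength of the first channel, the channel step
#' and the channel count; channel `k` (1-based) sits at
#' `start + (k - 1) * step` nm. Non-uniform grids are rejected throughout the
#' package: the phasor transform assumes fixed steps.
#'
#' @param start Wavelength of the first channel, nm.
#' @param step Channel spacing, nm; must be positive.
#' @param count Number of channels; at least 2.
#' @return An object of class `wavelength_axis`.
#' @examples
#' ax <- wavelength_axis(420, 3, 107) # 420-738 nm acquisition grid
#' axis_span(ax)
#' @export
wavelength_axis <- function(start, step, count) {
  stopifnot(is.numeric(start), length(start) == 1L, is.finite(start))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("wavelength axis `step` must be a single positive number", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 2L)
    stop("wavelength axis `count` must be an integer >= 2", call. = FALSE)
  structure(list(start = as.numeric(start), step = as.numeric(step),
                 count = count),
            class = "wavelength_axis")
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf("<wavelength_axis> %g-%g nm, step %g nm, %d channels (L = %g nm)\n",
              x$start, axis_end(x), x$step, x$count, axis_span(x)))
  invisible(x)
}

#' Wavelengths of every channel
#' @param axis A [wavelength_axis()].
#' @return Numeric vector of length `axis$count`, nm.
#' @export
axis_wavelengths <- function(axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  axis$start + (seq_len(axis$count) - 1) * axis$step
}

#' Channel offsets from the axis start
#'
#' These offsets (0, step, 2 step, ...) are what enters the phasor phase
#' term, making phasor coordinates independent of the absolute wavelength
#' origin.
#' @inheritParams axis_wavelengths
#' @return Numeric vector, nm.
#' @export
axis_offsets <- function(axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  (seq_len(axis$count) - 1) * axis$step
}

#' Span (amplitude L) of a wavelength axis
#'
#' Defined as `(count - 1) * step`, the distance between the first and last
#' channel. For a 420-740 nm axis with 2.5 nm steps this is 320 nm. The
#' phasor transform uses this as its default period `L` but accepts an
#' override.
#' @inheritParams axis_wavelengths
#' @return Span in nm.
#' @export
axis_span <- function(axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  (axis$count - 1) * axis$step
}

axis_end <- function(axis) axis$start + (axis$count - 1) * axis$step

#' @export
format.wavelength_axis <- function(x, ...) {
  sprintf("axis(%g, %g, %d)", x$start, x$step, x$count)
}
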