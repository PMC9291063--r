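#' Emission spectrum on a uniform wavelength grid
#'
#' Intensities are arbitrary units, nonnegative, one value per channel of the
#' axis. A spectrum whose total intensity is zero is "empty": it carries no
#' spectral information and the phasor transform refuses it.
#'
#' @param intensities Nonnegative numeric vector, length `axis$count`.
#' @param axis A [wavelength_axis()].
#' @return An object of class `emission_spectrum`.
#' @examples
#' ax <- wavelength_axis(420, 2.5, 129)
#' s <- emission_spectrum(exp(-((axis_wavelengths(ax) - 550) / 20)^2 / 2), ax)
#' spectral_center_of_mass(s)
#' @export
emission_spectrum <- function(intensities, axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != axis$count)
    stop(sprintf("spectrum has %d intensities but axis has %d channels",
                 length(intensities), axis$count), call. = FALSE)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("spectrum intensities must be finite", call. = FALSE)
  if (any(intensities < 0))
    stop("spectrum intensities must be nonnegative", call. = FALSE)
  structure(list(intensities = intensities, axis = axis),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d channels on %s, total intensity %g%s\n",
              x$axis$count, format(x$axis), sum(x$intensities),
              if (is_empty_spectrum(x)) " [empty]" else ""))
  invisible(x)
}

#' Is a spectrum empty (zero total intensity)?
#' @param s An [emission_spectrum()].
#' @export
is_empty_spectrum <- function(s) {
  stopifnot(inherits(s, "emission_spectrum"))
  sum(s$intensities) == 0
}

stop_if_empty <- function(s, what = "operation") {
  if (is_empty_spectrum(s))
    stop(sprintf("empty spectrum (total intensity 0): %s is undefined", what),
         call. = FALSE)
  invisible(s)
}

#' Normalize an emission spectrum
#'
#' `mode = "max"` rescales so the peak value is 1 (the convention used when
#' overlaying bulk emission spectra of differently bright samples);
#' `mode = "area"` rescales so the intensities sum to 1. Either way the
#' spectral shape (all intensity ratios) is preserved and the operation is
#' idempotent.
#'
#' @param s An [emission_spectrum()]; must be non-empty.
#' @param mode `"max"` or `"area"`.
#' @return A normalized `emission_spectrum`.
#' @export
normalize_spectrum <- function(s, mode = c("max", "area")) {
  stopifnot(inherits(s, "emission_spectrum"))
  mode <- match.arg(mode)
  stop_if_empty(s, "normalization")
  denom <- switch(mode, max = max(s$intensities), area = sum(s$intensities))
  emission_spectrum(s$intensities / denom, s$axis)
}

#' Spectral center of mass
#'
#' The intensity-weighted mean emission wavelength,
#' sum(lambda * I(lambda)) / sum(I(lambda)). In phasor space this quantity is
#' encoded by the angular position of the phasor.
#'
#' @param s An [emission_spectrum()]; must be non-empty.
#' @return Wavelength in nm, guaranteed within the axis range.
#' @export
spectral_center_of_mass <- function(s) {
  stopifnot(inherits(s, "emission_spectrum"))
  stop_if_empty(s, "center of mass")
  lam <- axis_wavelengths(s$axis)
  sum(lam * s$intensities) / sum(s$intensities)
}

#' Read a bulk emission spectrum from a two-column CSV
#'
#' Expects header `wavelength_nm,intensity` and a uniform wavelength grid
#' (constant step); this is the interchange format for spectra measured on a
#' bench spectrofluorimeter.
#'
#' @param path CSV file path.
#' @param tol Relative tolerance on step uniformity.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path, tol = 1e-6) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("spectrum CSV must have columns wavelength_nm,intensity", call. = FALSE)
  lam <- df$wavelength_nm
  if (length(lam) < 2) stop("spectrum CSV needs at least 2 rows", call. = FALSE)
  steps <- diff(lam)
  if (any(steps <= 0) || diff(range(steps)) > tol * abs(mean(steps)))
    stop("spectrum CSV wavelengths must form a uniform increasing grid",
         call. = FALSE)
  emission_spectrum(df$intensity,
                    wavelength_axis(lam[1], mean(steps), length(lam)))
}

#' Write a bulk emission spectrum to CSV
#' @param s An [emission_spectrum()].
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "emission_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = axis_wavelengths(s$axis),
               intensity = s$intensities),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
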