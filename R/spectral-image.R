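#' Lambda stack: an image whose every pixel holds an emission spectrum
#'
#' Voxels are stored as a numeric array `[y, x, channel]` of nonnegative
#' intensities (float, regardless of the integer type of the source file, so
#' the pipeline is photon-count agnostic). `pixel_size`, when known, is the
#' lateral sampling in micrometers per pixel and propagates into particle
#' areas and diameters.
#'
#' @param voxels Numeric array `[height, width, channels]`, nonnegative.
#' @param axis A [wavelength_axis()] with `count == dim(voxels)[3]`.
#' @param pixel_size Optional micrometers per pixel, > 0.
#' @return An object of class `spectral_image`.
#' @export
spectral_image <- function(voxels, axis, pixel_size = NULL) {
  stopifnot(inherits(axis, "wavelength_axis"))
  if (length(dim(voxels)) != 3)
    stop("voxels must be a 3-d array [y, x, channel]", call. = FALSE)
  if (dim(voxels)[3] != axis$count)
    stop(sprintf("stack has %d channels but axis declares %d",
                 dim(voxels)[3], axis$count), call. = FALSE)
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxels must be finite", call. = FALSE)
  if (any(voxels < 0))
    stop("voxels must be nonnegative (clamp on load)", call. = FALSE)
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L)
    if (!is.finite(pixel_size) || pixel_size <= 0)
      stop("pixel_size must be > 0 (micrometers per pixel)", call. = FALSE)
    pixel_size <- as.numeric(pixel_size)
  }
  structure(list(voxels = voxels * 1.0, axis = axis, pixel_size = pixel_size),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<spectral_image> %d x %d pixels, %d channels on %s%s\n",
              d[2], d[1], d[3], format(x$axis),
              if (is.null(x$pixel_size)) ""
              else sprintf(", %g um/pixel", x$pixel_size)))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$voxels)

#' Extract the emission spectrum of one pixel
#' @param img A [spectral_image()].
#' @param x,y Pixel coordinates, 1-based (`x` = column, `y` = row).
#' @return An [emission_spectrum()].
#' @export
pixel_spectrum <- function(img, x, y) {
  stopifnot(inherits(img, "spectral_image"))
  emission_spectrum(img$voxels[y, x, ], img$axis)
}

#' Per-pixel total intensity image
#' @param img A [spectral_image()].
#' @return Matrix `[height, width]` of channel sums.
#' @export
total_intensity <- function(img) {
  stopifnot(inherits(img, "spectral_image"))
  rowSums(img$voxels, dims = 2)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Load a lambda stack from a multi-page TIFF
#'
#' One TIFF page per wavelength channel. The wavelength axis comes either
#' from `axis` or from a YAML sidecar next to the TIFF
#' (`<stem>.yaml`, keys `start_nm`, `step_nm`, `count`, optional
#' `pixel_size_um`). A page-count/axis mismatch is a format error; negative
#' input pixels are clamped to zero with a warning stating how many.
#'
#' @param path Multi-page TIFF path.
#' @param axis Optional [wavelength_axis()]; overrides any sidecar.
#' @param pixel_size Optional micrometers per pixel; overrides any sidecar.
#' @param quiet Suppress the dimension log line.
#' @return A [spectral_image()].
#' @export
load_spectral_image <- function(path, axis = NULL, pixel_size = NULL,
                                quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(axis) || is.null(pixel_size)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- yaml::read_yaml(sc)
      if (is.null(axis) && all(c("start_nm", "step_nm", "count") %in% names(meta)))
        axis <- wavelength_axis(meta$start_nm, meta$step_nm, meta$count)
      if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    }
  }
  if (is.null(axis))
    stop("no wavelength axis: pass `axis` or provide a YAML sidecar ",
         sidecar_path(path), call. = FALSE)
  voxels <- read_tiff(path)
  if (dim(voxels)[3] != axis$count)
    stop(sprintf(
      "page count / axis mismatch: TIFF %s has %d pages but axis declares %d channels",
      path, dim(voxels)[3], axis$count), call. = FALSE)
  nneg <- sum(voxels < 0)
  if (nneg > 0) {
    warning(sprintf("%d negative input pixel values clamped to 0", nneg),
            call. = FALSE)
    voxels[voxels < 0] <- 0
  }
  img <- spectral_image(voxels, axis, pixel_size)
  if (!quiet)
    message(sprintf("loaded %s: %d x %d pixels, %d channels (%s)",
                    path, dim(voxels)[2], dim(voxels)[1], dim(voxels)[3],
                    format(axis)))
  img
}

#' Save a lambda stack as a multi-page float TIFF plus YAML sidecar
#'
#' Defaults to float64 pages so arbitrary intensities round-trip
#' bit-for-bit with [load_spectral_image()]; use `dtype = "float32"` for
#' half-size files when photon-count precision suffices.
#'
#' @param img A [spectral_image()].
#' @param path Output TIFF path; the sidecar goes to `<stem>.yaml`.
#' @param dtype TIFF sample type, see [write_tiff()].
#' @export
save_spectral_image <- function(img, path, dtype = "float64") {
  stopifnot(inherits(img, "spectral_image"))
  write_tiff(img$voxels, path, dtype = dtype)
  meta <- list(start_nm = img$axis$start, step_nm = img$axis$step,
               count = img$axis$count)
  if (!is.null(img$pixel_size)) meta$pixel_size_um <- img$pixel_size
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}
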