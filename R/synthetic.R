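#' Default acquisition axis for synthetic scenes
#'
#' 420-740 nm in 3 nm steps (107 channels), the spectral detection window
#' and step of the confocal acquisitions the generator emulates.
#' @return A [wavelength_axis()].
#' @export
default_axis <- function() wavelength_axis(420, 3, 107)

#' Reference emission model of one polymer class
#'
#' Emission of the solvatochromic dye bound to a polymer is modeled as a sum
#' of Gaussian bands. Nonpolar polyolefins (PP, LDPE, HDPE) show two blue
#' bands between 450 and 520 nm; polar polymers show a single broad band
#' above 520 nm, reddest and broadest for PET. The *numeric* band
#' parameters shipped as defaults are synthetic stand-ins chosen to respect
#' that qualitative ordering — no published per-polymer emission maxima
#' exist for this dye — and live in an editable YAML file
#' (`system.file("extdata", "polymer_references_synthetic.yaml",
#' package = "phasorMP")`).
#'
#' @param name Class name.
#' @param peaks Data frame with columns `center` (nm), `sigma` (nm),
#'   `amplitude` (relative); all positive.
#' @param dielectric_range Length-2 numeric, the material's dielectric
#'   constant range (orders the classes by polarity).
#' @param display_color Display color.
#' @return An object of class `polymer_reference`.
#' @export
polymer_reference <- function(name, peaks, dielectric_range,
                              display_color = "grey") {
  stopifnot(is.character(name), length(name) == 1L)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "sigma", "amplitude") %in% names(peaks)),
            nrow(peaks) >= 1)
  if (any(peaks$sigma <= 0) || any(peaks$amplitude <= 0))
    stop("peak sigmas and amplitudes must be positive", call. = FALSE)
  dielectric_range <- as.numeric(dielectric_range)
  stopifnot(length(dielectric_range) == 2, dielectric_range[1] <= dielectric_range[2])
  structure(list(name = name, peaks = peaks,
                 dielectric_range = dielectric_range,
                 display_color = display_color),
            class = "polymer_reference")
}

#' Built-in five-polymer reference set
#'
#' Loads the synthetic reference library shipped with the package: PP,
#' LDPE, HDPE, PS, PET with display colors blue, cyan, green, yellow, red
#' and dielectric-constant ranges PP 2.2-2.5, HDPE 2.3-2.4, LDPE 2.2-2.35,
#' PS 2.4-3.1, PET 3-4. LDPE and HDPE band positions differ by only ~2 nm:
#' enough for bulk spectra to register minor differences, little enough
#' that their image phasor clouds superimpose.
#'
#' @param path Optional alternative YAML reference file.
#' @return List of [polymer_reference()] objects, in order of increasing
#'   polarity (PP, LDPE, HDPE, PS, PET).
#' @export
default_polymer_references <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "polymer_references_synthetic.yaml",
                        package = "phasorMP")
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r)
    polymer_reference(r$name, do.call(rbind, lapply(r$peaks, as.data.frame)),
                      unlist(r$dielectric_range), r$display_color))
}

#' Evaluate a polymer reference as an emission spectrum on an axis
#'
#' Sum of the reference's Gaussian bands, max-normalized. Every band center
#' must lie within the axis range.
#'
#' @param ref A [polymer_reference()].
#' @param axis A [wavelength_axis()].
#' @return A max-normalized [emission_spectrum()].
#' @export
make_reference_spectrum <- function(ref, axis) {
  stopifnot(inherits(ref, "polymer_reference"),
            inherits(axis, "wavelength_axis"))
  lam <- axis_wavelengths(axis)
  if (any(ref$peaks$center < min(lam) | ref$peaks$center > max(lam)))
    stop(sprintf("reference %s has a peak center outside the axis %g-%g nm",
                 ref$name, min(lam), max(lam)), call. = FALSE)
  I <- rep(0, length(lam))
  for (i in seq_len(nrow(ref$peaks)))
    I <- I + ref$peaks$amplitude[i] *
      exp(-(lam - ref$peaks$center[i])^2 / (2 * ref$peaks$sigma[i]^2))
  normalize_spectrum(emission_spectrum(I, axis), "max")
}

#' Specification of a synthetic stained-sample scene
#'
#' Describes a field of dispersed plastic fragments on a dark aqueous
#' background, imaged as a lambda stack in photon-counting mode. Defaults
#' emulate the acquisitions the pipeline targets: 256 x 256 pixels,
#' 420-740 nm in 3 nm steps, roughly equal amounts of the five polymers,
#' particle radii 3-12 pixels, peak signal ~120 counts/channel, flat
#' background of 1 count/channel, Poisson (shot) noise.
#'
#' @param width,height Scene size in pixels.
#' @param axis A [wavelength_axis()].
#' @param n_particles Number of fragments to place.
#' @param class_mix Named target fractions (by particle count) summing to 1.
#' @param size_range Particle equivalent-radius range, pixels.
#' @param peak_counts Expected peak intensity, counts per channel, before
#'   the per-particle brightness factor.
#' @param brightness_range Per-particle multiplicative brightness factor
#'   range (fragments are unevenly stained and unevenly thick).
#' @param background_level Background counts per channel.
#' @param noise `"poisson"` (photon counting), `"none"`, or a positive
#'   number for additive Gaussian noise of that standard deviation.
#' @param pixel_size Micrometers per pixel (default ~5, a 1272 um field of
#'   view over 256 pixels).
#' @param seed Integer seed; a fixed seed makes [generate_scene()] output
#'   bit-identical.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256L, height = 256L, axis = default_axis(),
                       n_particles = 40L,
                       class_mix = c(PP = 0.2, LDPE = 0.2, HDPE = 0.2,
                                     PS = 0.2, PET = 0.2),
                       size_range = c(3, 12), peak_counts = 120,
                       brightness_range = c(0.6, 1.4),
                       background_level = 1, noise = "poisson",
                       pixel_size = 1272 / 256, seed = 1L) {
  stopifnot(width >= 8, height >= 8, inherits(axis, "wavelength_axis"),
            n_particles >= 1, length(size_range) == 2,
            size_range[1] >= 1, size_range[1] <= size_range[2],
            peak_counts > 0, background_level >= 0)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix fractions must sum to 1", call. = FALSE)
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    stop("class_mix must be a named vector of fractions", call. = FALSE)
  if (!(identical(noise, "poisson") || identical(noise, "none") ||
        (is.numeric(noise) && length(noise) == 1 && noise > 0)))
    stop('noise must be "poisson", "none", or a positive Gaussian sd',
         call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 axis = axis, n_particles = as.integer(n_particles),
                 class_mix = class_mix, size_range = size_range,
                 peak_counts = peak_counts,
                 brightness_range = brightness_range,
                 background_level = background_level, noise = noise,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "scene_spec")
}

## ellipse footprint as logical matrix over the whole scene
ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic lambda stack with ground truth
#'
#' Places elliptical fragments (random eccentricity and orientation, sizes
#' from `size_range`) without overlap by rejection sampling, assigns each a
#' polymer class so realized counts track `class_mix`, paints every particle
#' pixel with its class reference spectrum scaled by `peak_counts` and a
#' per-particle brightness factor, adds the flat background, and applies the
#' chosen noise. Identical seeds give bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @param refs List of [polymer_reference()]s covering every class in
#'   `spec$class_mix`.
#' @param max_tries Rejection-sampling budget per particle.
#' @return List with `image` ([spectral_image()]), `truth` (ground-truth
#'   label map, class order = `names(spec$class_mix)`), `particles`
#'   (ground-truth `particle_table`), and `class_mix_realized` (realized
#'   pixel-area fractions).
#' @export
generate_scene <- function(spec, refs = default_polymer_references(),
                           max_tries = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  ref_names <- vapply(refs, function(r) r$name, character(1))
  classes <- names(spec$class_mix)
  missing <- setdiff(classes, ref_names)
  if (length(missing))
    stop("classes missing from reference set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  spectra <- lapply(refs[match(classes, ref_names)], function(r)
    make_reference_spectrum(r, spec$axis)$intensities)
  names(spectra) <- classes

  # deterministic class sequence tracking the target mix
  n <- spec$n_particles
  counts <- floor(spec$class_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(spec$class_mix * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  class_seq <- sample(rep(classes, counts))

  h <- spec$height; w <- spec$width
  occupied <- matrix(FALSE, h, w) # particles plus a 1-px separation margin
  labels <- matrix(0L, h, w)
  rows <- list()
  stack <- array(spec$background_level,
                 dim = c(h, w, spec$axis$count))
  placed <- 0L
  for (i in seq_len(n)) {
    cls <- class_seq[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r_eq <- stats::runif(1, spec$size_range[1], spec$size_range[2])
      ecc <- stats::runif(1, 0.5, 1) # b/a ratio
      a <- r_eq / sqrt(ecc); b <- r_eq * sqrt(ecc)
      theta <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, 1 + a, h - a)
      cx <- stats::runif(1, 1 + a, w - a)
      m <- ellipse_mask(h, w, cy, cx, a, b, theta)
      if (!any(m)) next
      grown <- m | ellipse_mask(h, w, cy, cx, a + 1.5, b + 1.5, theta)
      if (any(grown & occupied)) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("particle placement failed: placed %d of %d requested before exhausting %d tries",
                   placed, n, max_tries), call. = FALSE)
    occupied <- occupied | grown
    ci <- match(cls, classes)
    labels[m] <- ci
    bright <- stats::runif(1, spec$brightness_range[1],
                           spec$brightness_range[2])
    sp <- spectra[[cls]] * spec$peak_counts * bright
    idx <- which(m)
    for (ch in seq_len(spec$axis$count))
      stack[idx + (ch - 1) * h * w] <- stack[idx + (ch - 1) * h * w] + sp[ch]
    pxs <- which(m, arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      class = cls, area_px = nrow(pxs),
      area_um2 = nrow(pxs) * spec$pixel_size^2,
      centroid_x = mean(pxs[, 2]), centroid_y = mean(pxs[, 1]),
      eq_diameter_px = sqrt(4 * nrow(pxs) / pi),
      eq_diameter_um = sqrt(4 * nrow(pxs) / pi) * spec$pixel_size,
      tile = 1L)
    placed <- placed + 1L
  }
  if (identical(spec$noise, "poisson")) {
    stack[] <- stats::rpois(length(stack), stack)
  } else if (is.numeric(spec$noise)) {
    stack[] <- pmax(stack + stats::rnorm(length(stack), 0, spec$noise), 0)
  }
  img <- spectral_image(stack, spec$axis, spec$pixel_size)
  pt <- do.call(rbind, rows)
  pt <- cbind(particle_id = seq_len(nrow(pt)), pt)
  attr(pt, "pixel_size") <- spec$pixel_size
  class(pt) <- c("particle_table", "data.frame")
  areas <- tapply(pt$area_px, pt$class, sum)
  mix <- as.numeric(areas) / sum(areas)
  names(mix) <- names(areas)
  list(image = img,
       truth = new_label_map(labels, classes,
                             vapply(refs[match(classes, ref_names)],
                                    function(r) r$display_color, character(1)),
                             spec$pixel_size),
       particles = pt,
       class_mix_realized = mix)
}

## approximate wavelength (nm) to linear-RGB weights, piecewise linear
wavelength_to_rgb <- function(lam) {
  r <- g <- b <- numeric(length(lam))
  for (i in seq_along(lam)) {
    x <- lam[i]
    if (x >= 380 && x < 440) { r[i] <- (440 - x) / 60; b[i] <- 1 }
    else if (x < 490) { g[i] <- (x - 440) / 50; b[i] <- 1 }
    else if (x < 510) { g[i] <- 1; b[i] <- (510 - x) / 20 }
    else if (x < 580) { r[i] <- (x - 510) / 70; g[i] <- 1 }
    else if (x < 645) { r[i] <- 1; g[i] <- (645 - x) / 65 }
    else if (x <= 780) { r[i] <- 1 }
  }
  cbind(r, g, b)
}

#' Approximate true-color rendering of a lambda stack
#'
#' Maps each pixel's spectrum to RGB through a fixed wavelength-to-color
#' lookup weighted by intensity — roughly what the stained sample looks like
#' under UV illumination. Deterministic; a zero image renders black.
#'
#' @param img A [spectral_image()].
#' @param gamma Display gamma applied after normalization.
#' @return Numeric array `[height, width, 3]` in \[0, 1\].
#' @export
render_rgb_preview <- function(img, gamma = 1 / 2.2) {
  stopifnot(inherits(img, "spectral_image"))
  d <- dim(img$voxels)
  M <- matrix(img$voxels, d[1] * d[2], d[3])
  lut <- wavelength_to_rgb(axis_wavelengths(img$axis))
  rgb <- M %*% lut
  mx <- max(rgb)
  if (mx > 0) rgb <- (rgb / mx)^gamma
  array(rgb, dim = c(d[1], d[2], 3))
}

#' Write a scene specification to YAML / read it back
#' @param spec A [scene_spec()].
#' @param path YAML path.
#' @export
write_scene_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(list(
    width = spec$width, height = spec$height,
    axis = list(start_nm = spec$axis$start, step_nm = spec$axis$step,
                count = spec$axis$count),
    n_particles = spec$n_particles,
    class_mix = as.list(spec$class_mix),
    size_range = spec$size_range, peak_counts = spec$peak_counts,
    brightness_range = spec$brightness_range,
    background_level = spec$background_level,
    noise = spec$noise, pixel_size = spec$pixel_size, seed = spec$seed),
    path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  r <- yaml::read_yaml(path)
  scene_spec(width = r$width, height = r$height,
             axis = wavelength_axis(r$axis$start_nm, r$axis$step_nm,
                                    r$axis$count),
             n_particles = r$n_particles,
             class_mix = unlist(r$class_mix),
             size_range = unlist(r$size_range),
             peak_counts = r$peak_counts,
             brightness_range = unlist(r$brightness_range),
             background_level = r$background_level,
             noise = if (is.character(r$noise)) r$noise else as.numeric(r$noise),
             pixel_size = r$pixel_size, seed = r$seed)
}
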