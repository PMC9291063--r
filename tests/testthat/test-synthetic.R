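count_local_maxima <- function(y) {
  n <- length(y)
  sum(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] > y[-(1:2)])
}

test_that("default reference spectra honor the polymer shape constraints", {
  ax <- default_axis()
  refs <- default_polymer_references()
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  lam <- axis_wavelengths(ax)
  for (nm in c("PP", "LDPE", "HDPE")) {
    s <- make_reference_spectrum(refs[[nm]], ax)
    expect_lt(lam[which.max(s$intensities)], 520)
    expect_equal(count_local_maxima(s$intensities), 2) # dual blue-green bands
    peaks <- lam[which(diff(sign(diff(s$intensities))) == -2) + 1]
    expect_true(all(peaks >= 450 & peaks <= 520))
  }
  for (nm in c("PS", "PET")) {
    s <- make_reference_spectrum(refs[[nm]], ax)
    expect_equal(count_local_maxima(s$intensities), 1) # single polar band
    expect_gt(lam[which.max(s$intensities)], 520)
  }
  # PET redder and broader than PS
  com <- vapply(refs, function(r)
    spectral_center_of_mass(make_reference_spectrum(r, ax)), numeric(1))
  expect_gt(com[["PET"]], com[["PS"]])
  mods <- vapply(refs, function(r)
    phasor_modulus(compute_phasor(make_reference_spectrum(r, ax))),
    numeric(1))
  expect_lt(mods[["PET"]], mods[["PS"]])
  # max-normalized
  for (r in refs)
    expect_equal(max(make_reference_spectrum(r, ax)$intensities), 1)
})

test_that("reference phasor angles follow the polarity ordering", {
  ax <- default_axis()
  refs <- default_polymer_references()
  ang <- unwrap_angles(vapply(refs, function(r)
    phasor_angle(compute_phasor(make_reference_spectrum(r, ax))),
    numeric(1)))
  names(ang) <- vapply(refs, function(r) r$name, character(1))
  expect_true(ang[["PP"]] < ang[["LDPE"]])
  expect_true(ang[["LDPE"]] <= ang[["HDPE"]])
  expect_true(ang[["HDPE"]] < ang[["PS"]])
  expect_true(ang[["PS"]] < ang[["PET"]])
})

test_that("a single-band reference peaks at the nearest grid point", {
  ax <- default_axis()
  ref <- polymer_reference("X", data.frame(center = 560, sigma = 25,
                                           amplitude = 1), c(2, 3))
  s <- make_reference_spectrum(ref, ax)
  lam <- axis_wavelengths(ax)
  expect_equal(lam[which.max(s$intensities)],
               lam[which.min(abs(lam - 560))])
  expect_error(make_reference_spectrum(
    polymer_reference("X", data.frame(center = 900, sigma = 10,
                                      amplitude = 1), c(2, 3)), ax),
    "outside")
  expect_error(polymer_reference("X", data.frame(center = 500, sigma = -1,
                                                 amplitude = 1), c(2, 3)),
               "positive")
})

test_that("generate_scene bookkeeping is exact without noise", {
  spec <- tiny_scene(seed = 5, n_particles = 10)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$particles), 10)
  # ground truth areas match the label map exactly
  by_class <- tapply(sc$particles$area_px, sc$particles$class, sum)
  for (cl in names(by_class))
    expect_equal(sum(sc$truth$labels == match(cl, sc$truth$class_labels)),
                 unname(by_class[[cl]]))
  expect_equal(sum(sc$class_mix_realized), 1, tolerance = 1e-12)
  # no overlap: particle areas sum to labeled-pixel count
  expect_equal(sum(sc$particles$area_px), sum(sc$truth$labels > 0))
})

test_that("every particle pixel carries exactly its class phasor when noiseless", {
  spec <- tiny_scene(seed = 3, n_particles = 6)
  spec$background_level <- 0
  sc <- generate_scene(spec)
  pim <- phasor_image(sc$image, background_threshold = 0)
  refs <- default_polymer_references()
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  for (ci in seq_along(sc$truth$class_labels)) {
    idx <- which(sc$truth$labels == ci)
    if (!length(idx)) next
    p <- compute_phasor(make_reference_spectrum(
      refs[[sc$truth$class_labels[ci]]], spec$axis))
    expect_equal(max(abs(pim$X[idx] - p$X)), 0, tolerance = 1e-9)
    expect_equal(max(abs(pim$Y[idx] - p$Y)), 0, tolerance = 1e-9)
  }
})

test_that("scene generation is seed-deterministic", {
  a <- generate_scene(tiny_scene(seed = 17, noise = "poisson"))
  b <- generate_scene(tiny_scene(seed = 17, noise = "poisson"))
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$particles, b$particles)
  c_ <- generate_scene(tiny_scene(seed = 18, noise = "poisson"))
  expect_false(identical(a$truth$labels, c_$truth$labels))
})

test_that("placement failure reports achieved vs requested counts", {
  spec <- scene_spec(width = 24, height = 24, n_particles = 200,
                     size_range = c(3, 6), noise = "none", seed = 1)
  expect_error(generate_scene(spec, max_tries = 30), "of 200 requested")
})

test_that("scene spec validates and round-trips through YAML", {
  expect_error(scene_spec(class_mix = c(PP = 0.5, PET = 0.4)), "sum to 1")
  expect_error(scene_spec(noise = "salt"), "poisson")
  spec <- tiny_scene(seed = 9, noise = "poisson")
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scene_yaml(spec, p)
  back <- read_scene_yaml(p)
  expect_equal(back, spec)
  expect_identical(generate_scene(back)$image$voxels,
                   generate_scene(spec)$image$voxels)
})

test_that("rgb preview shows class-typical hues and renders zero as black", {
  ax <- default_axis()
  refs <- default_polymer_references()
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  mono_image <- function(nm) {
    s <- make_reference_spectrum(refs[[nm]], ax)$intensities
    spectral_image(array(rep(s, each = 16), dim = c(4, 4, ax$count)), ax)
  }
  pp <- render_rgb_preview(mono_image("PP"))
  expect_true(mean(pp[, , 3]) > mean(pp[, , 1])) # PP: blue over red
  pet <- render_rgb_preview(mono_image("PET"))
  expect_true(mean(pet[, , 1]) > mean(pet[, , 3])) # PET: red over blue
  zero <- spectral_image(array(0, dim = c(4, 4, ax$count)), ax)
  expect_equal(max(render_rgb_preview(zero)), 0)
})
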