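# build a small phasor image directly from chosen (X, Y) points
fake_phasor_image <- function(X, Y, weight = NULL, valid = NULL) {
  stopifnot(identical(dim(X), dim(Y)))
  structure(list(X = X, Y = Y,
                 weight = weight %||% (X * 0 + 1),
                 valid = valid %||% (X * 0 == 0),
                 axis = axis107(), pixel_size = NULL,
                 harmonic = 1L, L = 318, threshold = 0),
            class = "phasor_image")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cursor construction validates geometry and labels", {
  expect_error(cursor("PP", c(0, 0), radius = 0), "> 0")
  expect_error(cursor("PP", c(1.5, 0)), "within")
  expect_error(phasorMP:::check_cursor_set(list(cursor("A", c(0, 0)),
                                                cursor("A", c(0.5, 0)))),
               "duplicate")
})

test_that("classify_pixels: containment, nearest-center overlap, tie-break", {
  X <- matrix(c(0.30, 0.90, 0.50, 0.415), 2, 2)
  Y <- matrix(c(0.00, 0.00, 0.00, 0.000), 2, 2)
  curs <- list(cursor("A", c(0.30, 0), 0.12), cursor("B", c(0.53, 0), 0.12))
  lm <- classify_pixels(fake_phasor_image(X, Y), curs)
  expect_equal(lm$labels[1, 1], 1L)          # at A's center
  expect_equal(lm$labels[2, 1], 0L)          # modulus 0.9, outside all
  expect_equal(lm$labels[1, 2], 2L)          # inside both, nearer B
  expect_equal(lm$labels[2, 2], 1L)          # equidistant: first cursor wins
  # invalid pixels never get labels
  lm2 <- classify_pixels(fake_phasor_image(X, Y,
                           valid = matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)),
                         curs)
  expect_equal(sum(lm2$labels > 0), 1L)
  expect_error(classify_pixels(fake_phasor_image(X, Y),
                               list(cursor("A", c(0, 0)),
                                    cursor("A", c(0.1, 0)))), "duplicate")
})

test_that("back-mapping consistency: labeled pixels lie inside their cursor", {
  set.seed(31)
  X <- matrix(runif(400, -1, 1), 20, 20)
  Y <- matrix(runif(400, -1, 1), 20, 20)
  curs <- list(cursor("A", c(-0.3, 0.2), 0.3), cursor("B", c(0.4, -0.1), 0.25))
  lm <- classify_pixels(fake_phasor_image(X, Y), curs)
  for (ci in 1:2) {
    idx <- which(lm$labels == ci)
    if (length(idx)) {
      d <- sqrt((X[idx] - curs[[ci]]$center[1])^2 +
                (Y[idx] - curs[[ci]]$center[2])^2)
      expect_true(all(d <= curs[[ci]]$radius + 1e-12))
    }
  }
})

test_that("auto_cursors recovers well-separated classes and is deterministic", {
  set.seed(1)
  n <- 400
  X <- matrix(c(rnorm(n, 0.6, 0.02), rnorm(n, -0.2, 0.02)), 40, 20)
  Y <- matrix(c(rnorm(n, 0.3, 0.02), rnorm(n, 0.6, 0.02)), 40, 20)
  pim <- fake_phasor_image(X, Y)
  curs <- auto_cursors(pim, k = 2, radius = 0.1, seed = 4)
  curs2 <- auto_cursors(pim, k = 2, radius = 0.1, seed = 4)
  expect_identical(curs, curs2)
  centers <- t(vapply(curs, function(cu) cu$center, numeric(2)))
  # one center near each cluster
  expect_lt(min(sqrt((centers[, 1] - 0.6)^2 + (centers[, 2] - 0.3)^2)), 0.02)
  expect_lt(min(sqrt((centers[, 1] + 0.2)^2 + (centers[, 2] - 0.6)^2)), 0.02)
  # each cursor captures >99% of its own cluster
  lm <- classify_pixels(pim, curs)
  # column-major fill: the first 400 values occupy columns 1-10
  first_cluster <- matrix(FALSE, 40, 20); first_cluster[, 1:10] <- TRUE
  lab1 <- lm$labels[first_cluster]; lab2 <- lm$labels[!first_cluster]
  expect_gt(mean(lab1 == as.integer(names(which.max(table(lab1))))), 0.99)
  expect_gt(mean(lab2 == as.integer(names(which.max(table(lab2))))), 0.99)
  expect_error(auto_cursors(pim, k = 2000), "2000")
})

test_that("auto_cursors with k = 1 returns the weighted centroid", {
  set.seed(2)
  X <- matrix(runif(100, 0.2, 0.4), 10, 10)
  Y <- matrix(runif(100, -0.1, 0.1), 10, 10)
  w <- matrix(runif(100, 1, 5), 10, 10)
  cu <- auto_cursors(fake_phasor_image(X, Y, weight = w), k = 1, seed = 9)[[1]]
  expect_equal(cu$center, c(sum(X * w) / sum(w), sum(Y * w) / sum(w)),
               tolerance = 1e-9)
})

test_that("cursor sets round-trip through YAML", {
  curs <- list(cursor("PP", c(0.55, 0.45), 0.08, "blue"),
               cursor("PET", c(-0.5, -0.2), 0.1, "red"))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_cursors_yaml(curs, p)
  back <- read_cursors_yaml(p)
  expect_equal(back, curs)
})

test_that("label_components honors connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE # diagonal touch
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  # two disjoint blobs
  m2 <- matrix(FALSE, 8, 8)
  m2[1:2, 1:2] <- TRUE; m2[6:8, 6:7] <- TRUE
  lab <- label_components(m2, 8)
  expect_equal(max(lab), 2)
  expect_equal(sort(as.integer(table(lab[lab > 0]))), c(4L, 6L))
  expect_error(label_components(m2, 6), "4 or 8")
})

test_that("extract_particles: sizes, filtering, connectivity, units", {
  lab <- matrix(0L, 12, 12)
  lab[2:3, 2:6] <- 1L              # 10-px blob, class 1
  lab[8:9, 2:6] <- 1L              # second 10-px blob, class 1
  lab[5, 9:11] <- 2L               # 3-px blob, class 2
  lm <- phasorMP:::new_label_map(lab, c("A", "B"), pixel_size = 2)
  pt <- extract_particles(lm, min_particle_size = 4)
  expect_equal(nrow(pt), 2)
  expect_equal(pt$area_px, c(10, 10))
  expect_equal(pt$class, c("A", "A")) # 3-px blob dropped below min size
  expect_equal(pt$area_um2, c(40, 40))
  expect_equal(pt$eq_diameter_px, rep(sqrt(40 / pi), 2))
  pt2 <- extract_particles(lm, min_particle_size = 1)
  expect_equal(nrow(pt2), 3)
  expect_true(anyDuplicated(pt2$particle_id) == 0)
  # diagonal-touching blobs of one class: 1 particle at 8-conn, 2 at 4-conn
  lab3 <- matrix(0L, 6, 6)
  lab3[2:3, 2:3] <- 1L; lab3[4:5, 4:5] <- 1L
  lm3 <- phasorMP:::new_label_map(lab3, "A")
  expect_equal(nrow(extract_particles(lm3, 1, connectivity = 8)), 1)
  expect_equal(nrow(extract_particles(lm3, 1, connectivity = 4)), 2)
  # empty map -> empty table, no error
  pt0 <- extract_particles(phasorMP:::new_label_map(matrix(0L, 4, 4), "A"))
  expect_equal(nrow(pt0), 0)
})

test_that("composition_fractions: both bases, sums to 1, empty warning", {
  lab <- matrix(0L, 20, 20)
  lab[1:15, 1:20] <- 1L   # 300 px of class A
  lab[18:19, 1:10] <- 2L  # 20 px of class B
  lm <- phasorMP:::new_label_map(lab, c("A", "B"))
  pt <- extract_particles(lm, 1)
  fr <- composition_fractions(pt, "pixel_area")
  expect_equal(unname(fr[c("A", "B")]), c(0.9375, 0.0625)) # 300 vs 20
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  frc <- composition_fractions(pt, "particle_count")
  expect_equal(sum(frc), 1, tolerance = 1e-12)
  expect_equal(attr(frc, "basis"), "particle_count")
  one <- pt[pt$class == "A", ]
  class(one) <- class(pt)
  expect_equal(as.numeric(composition_fractions(one)), 1)
  empty <- pt[0, ]; class(empty) <- class(pt)
  expect_warning(fr0 <- composition_fractions(empty), "empty")
  expect_length(fr0, 0)
})

test_that("mosaic_aggregate pools tiles, re-keys ids, rejects mixed units", {
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L; lab[7:9, 7:8] <- 2L
  lm <- phasorMP:::new_label_map(lab, c("A", "B"), pixel_size = 3)
  t1 <- extract_particles(lm, 1)
  lab2 <- lab; lab2[7:9, 7:8] <- 0L
  t2 <- extract_particles(phasorMP:::new_label_map(lab2, c("A", "B"),
                                                   pixel_size = 3), 1)
  pooled <- mosaic_aggregate(list(t1, t2))
  expect_equal(nrow(pooled), nrow(t1) + nrow(t2))
  expect_equal(pooled$particle_id, seq_len(nrow(pooled)))
  expect_equal(sort(unique(pooled$tile)), c(1L, 2L))
  # identical tiles double areas, fractions unchanged
  twice <- mosaic_aggregate(list(t1, t1))
  expect_equal(tapply(twice$area_px, twice$class, sum),
               2 * tapply(t1$area_px, t1$class, sum))
  expect_equal(composition_fractions(twice), composition_fractions(t1))
  # fractions over the aggregate equal pooled per-tile areas
  fr <- composition_fractions(pooled, "pixel_area")
  areas <- tapply(pooled$area_px, pooled$class, sum)
  expect_equal(unname(fr[names(areas)]), as.numeric(areas / sum(areas)))
  expect_equal(nrow(mosaic_aggregate(list())), 0)
  tbad <- t2; attr(tbad, "pixel_size") <- 5
  expect_error(mosaic_aggregate(list(t1, tbad)), "mixed pixel size")
})

test_that("label maps export as PNG with a JSON legend", {
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L; lab[5, 5:6] <- 2L
  lm <- phasorMP:::new_label_map(lab, c("PP", "PET"), c("blue", "red"))
  p <- withr::local_tempfile(fileext = ".png")
  write_labelmap_png(lm, p)
  img <- png::readPNG(p)
  expect_equal(img[2, 2, ], c(0, 0, 1)) # PP pixel is blue
  expect_equal(img[5, 5, ], c(1, 0, 0)) # PET pixel is red
  expect_equal(img[1, 1, ], c(0, 0, 0)) # background black
  legend <- jsonlite::read_json(sub("\\.png$", ".json", p))
  expect_equal(names(legend), c("PP", "PET"))
})
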