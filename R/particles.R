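#' Connected-component labeling of a binary mask
#'
#' Iterative minimum-label propagation over 4- or 8-neighborhoods,
#' vectorized over whole-image shifts; converges in a number of sweeps
#' bounded by the geodesic radius of the largest component, which is small
#' for particle-scale blobs.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edges + diagonals).
#' @return Integer matrix: 0 for background, components numbered 1..n in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  lab[!mask] <- NA_integer_
  shift <- function(m, dy, dx) {
    out <- matrix(NA_integer_, h, w)
    ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
    okY <- ys >= 1 & ys <= h; okX <- xs >= 1 & xs <= w
    out[okY, okX] <- m[ys[okY], xs[okX]]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    nb <- lab
    for (o in offs) nb <- pmin(nb, shift(lab, o[1], o[2]), na.rm = TRUE)
    nb[!mask] <- NA_integer_
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab[!mask] <- 0L
  # renumber in raster order of first occurrence
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], sort(ids))
  lab
}

#' Extract particles from a class label map
#'
#' Connected components are computed independently per class; components
#' smaller than `min_particle_size` are dropped (they are below anything one
#' would call a particle and are typically noise speckle). Areas, centroids
#' and equivalent-circle diameters are reported in pixels, and additionally
#' in micrometers when the pixel size is known.
#'
#' @param lm A [classify_pixels()] label map.
#' @param min_particle_size Minimum component area in pixels (default 4).
#' @param connectivity 4 or 8 (default 8).
#' @return A `particle_table`: data frame with columns `particle_id`,
#'   `class`, `area_px`, `area_um2`, `centroid_x`, `centroid_y`,
#'   `eq_diameter_px`, `eq_diameter_um`, `tile`; attribute `pixel_size`.
#' @export
extract_particles <- function(lm, min_particle_size = 4L, connectivity = 8L) {
  stopifnot(inherits(lm, "label_map"))
  px <- lm$pixel_size
  rows <- list()
  for (ci in seq_along(lm$class_labels)) {
    comp <- label_components(lm$labels == ci, connectivity)
    if (!any(comp > 0)) next
    for (id in seq_len(max(comp))) {
      idx <- which(comp == id, arr.ind = TRUE)
      area <- nrow(idx)
      if (area < min_particle_size) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = lm$class_labels[ci],
        area_px = area,
        area_um2 = if (is.null(px)) NA_real_ else area * px^2,
        centroid_x = mean(idx[, 2]),
        centroid_y = mean(idx[, 1]),
        eq_diameter_px = sqrt(4 * area / pi),
        eq_diameter_um = if (is.null(px)) NA_real_ else sqrt(4 * area / pi) * px,
        tile = 1L)
    }
  }
  pt <- if (length(rows)) do.call(rbind, rows) else empty_particle_table()
  if (nrow(pt)) pt <- cbind(particle_id = seq_len(nrow(pt)), pt)
  attr(pt, "pixel_size") <- px
  class(pt) <- c("particle_table", "data.frame")
  pt
}

empty_particle_table <- function() {
  data.frame(class = character(), area_px = numeric(), area_um2 = numeric(),
             centroid_x = numeric(), centroid_y = numeric(),
             eq_diameter_px = numeric(), eq_diameter_um = numeric(),
             tile = integer())
}

#' Per-class composition fractions of a particle table
#'
#' The relative amount of each detected polymer class with respect to the
#' total detected plastic, either by summed pixel area (default; robust to
#' fragmentation of one physical particle into several components) or by
#' particle count. Fractions are nonnegative and sum to 1 over detected
#' classes; an empty table yields all zeros with a warning.
#'
#' @param pt A `particle_table`.
#' @param basis `"pixel_area"` or `"particle_count"`.
#' @return Named numeric vector of fractions with attribute `basis`.
#' @export
composition_fractions <- function(pt, basis = c("pixel_area",
                                                "particle_count")) {
  basis <- match.arg(basis)
  stopifnot(inherits(pt, "particle_table") || is.data.frame(pt))
  classes <- unique(pt$class)
  if (nrow(pt) == 0) {
    warning("empty particle table: composition fractions are all zero",
            call. = FALSE)
    out <- numeric(0)
    attr(out, "basis") <- basis
    return(out)
  }
  val <- switch(basis,
                pixel_area = tapply(pt$area_px, pt$class, sum),
                particle_count = tapply(rep(1, nrow(pt)), pt$class, sum))
  out <- as.numeric(val) / sum(val)
  names(out) <- names(val)
  attr(out, "basis") <- basis
  out
}

#' Pool particle tables from a mosaic of tiles
#'
#' Tiles of a mosaic (acquired to enlarge the field of view) are pooled by
#' concatenating their particle tables with fresh unique particle ids and a
#' `tile` provenance column, so composition fractions over the aggregate
#' equal pooling of per-tile areas/counts. Tiles must agree on pixel size
#' (or all lack it).
#'
#' @param tables List of `particle_table`s.
#' @return A pooled `particle_table` (empty for an empty list).
#' @export
mosaic_aggregate <- function(tables) {
  stopifnot(is.list(tables))
  if (length(tables) == 0) {
    pt <- cbind(particle_id = integer(), empty_particle_table())
    class(pt) <- c("particle_table", "data.frame")
    return(pt)
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "particle_table")))
  ps <- lapply(tables, attr, "pixel_size")
  ps_chr <- vapply(ps, function(p) if (is.null(p)) "none" else format(p),
                   character(1))
  if (length(unique(ps_chr)) > 1)
    stop("tiles have mixed pixel sizes (", paste(unique(ps_chr), collapse = ", "),
         "); cannot aggregate in consistent units", call. = FALSE)
  pooled <- do.call(rbind, lapply(seq_along(tables), function(i) {
    ti <- as.data.frame(tables[[i]])
    if (nrow(ti)) ti$tile <- i
    ti
  }))
  pooled$particle_id <- seq_len(nrow(pooled))
  attr(pooled, "pixel_size") <- ps[[1]]
  class(pooled) <- c("particle_table", "data.frame")
  pooled
}

#' Write a particle table to CSV
#' @param pt A `particle_table`.
#' @param path Output path.
#' @export
write_particles_csv <- function(pt, path) {
  utils::write.csv(as.data.frame(pt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a label map as an indexed-color PNG plus JSON legend
#'
#' Background is black; classes use their cursor colors. The legend
#' (`<stem>.json`) maps class labels to hex colors.
#' @param lm A label map.
#' @param path Output PNG path.
#' @export
write_labelmap_png <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  cols <- grDevices::col2rgb(lm$colors) / 255
  h <- nrow(lm$labels); w <- ncol(lm$labels)
  img <- array(0, dim = c(h, w, 3))
  for (ci in seq_along(lm$class_labels)) {
    m <- lm$labels == ci
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[m] <- cols[ch, ci]; img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  legend <- as.list(grDevices::rgb(t(grDevices::col2rgb(lm$colors) / 255)))
  names(legend) <- lm$class_labels
  jsonlite::write_json(legend, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
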