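#' Circular cursor in phasor space
#'
#' A cursor is a labeled circle drawn on the phasor plot; pixels whose
#' phasor falls inside are assigned the cursor's class. Default radius 0.08
#' (dimensionless phasor units) — phasor clouds of distinct polymer classes
#' separate by several times that, while photon noise scatters a cloud by
#' far less at typical photon-counting intensities.
#'
#' @param label Class name; unique within a cursor set.
#' @param center Numeric length-2, (X, Y) within \[-1, 1\]^2.
#' @param radius Positive radius, dimensionless.
#' @param color Display color (any R color spec).
#' @return An object of class `cursor`.
#' @export
cursor <- function(label, center, radius = 0.08, color = "grey") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  center <- as.numeric(center)
  if (length(center) != 2 || anyNA(center) || any(abs(center) > 1))
    stop("cursor center must be (X, Y) within [-1, 1]^2", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("cursor radius must be > 0", call. = FALSE)
  structure(list(label = label, center = center, radius = as.numeric(radius),
                 color = color), class = "cursor")
}

#' @export
print.cursor <- function(x, ...) {
  cat(sprintf("<cursor> %s: center (%.3f, %.3f), radius %.3f, color %s\n",
              x$label, x$center[1], x$center[2], x$radius, x$color))
  invisible(x)
}

check_cursor_set <- function(cursors) {
  stopifnot(is.list(cursors), length(cursors) >= 1,
            all(vapply(cursors, inherits, logical(1), "cursor")))
  labels <- vapply(cursors, function(cu) cu$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate cursor labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  labels
}

#' Read / write a cursor set as YAML
#'
#' The file is a YAML list of `{label, center: [X, Y], radius, color}`.
#' @param path YAML file path.
#' @export
read_cursors_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cursors <- lapply(raw, function(r)
    cursor(r$label, unlist(r$center), r$radius %||% 0.08,
           r$color %||% "grey"))
  check_cursor_set(cursors)
  cursors
}

#' @rdname read_cursors_yaml
#' @param cursors List of [cursor()] objects.
#' @export
write_cursors_yaml <- function(cursors, path) {
  check_cursor_set(cursors)
  yaml::write_yaml(lapply(cursors, function(cu)
    list(label = cu$label, center = as.list(cu$center), radius = cu$radius,
         color = cu$color)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Back-map phasor-space cursors to a per-pixel label map
#'
#' Each valid pixel whose (X, Y) falls inside at least one cursor receives a
#' label; a pixel inside several cursors goes to the nearest cursor center,
#' with exact ties broken by cursor list order. Pixels outside all cursors,
#' and invalid (background) pixels, are labeled 0.
#'
#' @param pim A [phasor_image()].
#' @param cursors List of [cursor()] objects with unique labels.
#' @return An object of class `label_map`: integer matrix `labels`
#'   (`[height, width]`, 0 = unclassified), the class `labels` in cursor
#'   order, cursor `colors`, and `pixel_size` carried over.
#' @export
classify_pixels <- function(pim, cursors) {
  stopifnot(inherits(pim, "phasor_image"))
  labels <- check_cursor_set(cursors)
  idx <- which(pim$valid)
  lab <- integer(length(pim$X))
  if (length(idx)) {
    X <- pim$X[idx]; Y <- pim$Y[idx]
    k <- length(cursors)
    d2 <- matrix(Inf, length(idx), k)
    for (j in seq_len(k)) {
      cu <- cursors[[j]]
      dj <- (X - cu$center[1])^2 + (Y - cu$center[2])^2
      d2[, j] <- ifelse(dj <= cu$radius^2, dj, Inf)
    }
    # which.max on a logical picks the first TRUE: ties go to list order
    best <- max.col(-d2, ties.method = "first")
    inside <- is.finite(d2[cbind(seq_along(idx), best)])
    lab[idx[inside]] <- best[inside]
  }
  new_label_map(matrix(lab, nrow(pim$X), ncol(pim$X)), labels,
                vapply(cursors, function(cu) cu$color, character(1)),
                pim$pixel_size)
}

new_label_map <- function(labels, class_labels, colors = NULL,
                          pixel_size = NULL) {
  structure(list(labels = labels, class_labels = class_labels,
                 colors = colors %||% rep("grey", length(class_labels)),
                 pixel_size = pixel_size),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0], length(x$class_labels))
  cat(sprintf("<label_map> %d x %d pixels; %s; unclassified %d\n",
              ncol(x$labels), nrow(x$labels),
              paste(sprintf("%s: %d", x$class_labels, counts), collapse = ", "),
              sum(x$labels == 0)))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' Automatic cursor placement by weighted k-means in phasor space
#'
#' Automates the manual drawing of circles around phasor clouds: runs
#' Lloyd's k-means on the valid (X, Y) points, weighted by pixel total
#' intensity, from a seeded k-means++ initialization, and returns one cursor
#' per centroid. Deterministic for a fixed seed.
#'
#' @param pim A [phasor_image()] with at least `k` valid pixels.
#' @param k Number of cursors.
#' @param radius Radius given to every returned cursor.
#' @param seed Integer seed for the initialization.
#' @param max_iter Lloyd iteration cap.
#' @return List of [cursor()] objects labeled `"class_1"` ... `"class_k"`,
#'   ordered by increasing phasor angle (blue to red).
#' @export
auto_cursors <- function(pim, k, radius = 0.08, seed = 1L, max_iter = 100L) {
  stopifnot(inherits(pim, "phasor_image"), k >= 1)
  idx <- which(pim$valid)
  if (length(idx) < k)
    stop(sprintf("need at least k = %d valid pixels but phasor image has %d",
                 k, length(idx)), call. = FALSE)
  pts <- cbind(pim$X[idx], pim$Y[idx])
  w <- pim$weight[idx]
  centers <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    kmeanspp_init(pts, w, k)
  })
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(pts^2), rowSums(centers^2), "+") -
      2 * pts %*% t(centers)
    assign_to <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      m <- assign_to == j
      if (any(m))
        new_centers[j, ] <- colSums(pts[m, , drop = FALSE] * w[m]) / sum(w[m])
    }
    if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
    centers <- new_centers
  }
  ord <- order(unwrap_angles(atan2(centers[, 2], centers[, 1])))
  centers <- centers[ord, , drop = FALSE]
  lapply(seq_len(k), function(j)
    cursor(sprintf("class_%d", j), pmin(pmax(centers[j, ], -1), 1), radius))
}

kmeanspp_init <- function(pts, w, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, 2)
  centers[1, ] <- pts[sample.int(n, 1, prob = w), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(centers[seq_len(j - 1), , drop = FALSE], 1, function(cc)
      (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2)
    mind2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    p <- mind2 * w
    centers[j, ] <- if (sum(p) > 0) pts[sample.int(n, 1, prob = p), ]
                    else pts[sample.int(n, 1, prob = w), ]
  }
  centers
}

#' Default cursor set centered on reference-polymer phasors
#'
#' Places one cursor at the phasor of each reference spectrum. With
#' `merge_pe = TRUE` (the default) LDPE and HDPE share a single
#' `"LDPE/HDPE"` cursor at the midpoint of their phasors — in images their
#' clouds superimpose and cannot be separated; the strict mode
#' (`merge_pe = FALSE`) keeps them apart for bulk-spectrum work, where minor
#' but significant differences are resolvable.
#'
#' @param refs List of [polymer_reference()] objects (default the built-in
#'   five-polymer set).
#' @param axis [wavelength_axis()] on which to evaluate reference spectra.
#' @param radius Cursor radius.
#' @param merge_pe Merge LDPE and HDPE into one cursor.
#' @return List of [cursor()] objects.
#' @export
reference_cursors <- function(refs = default_polymer_references(),
                              axis = default_axis(), radius = 0.08,
                              merge_pe = TRUE) {
  phs <- lapply(refs, function(r)
    compute_phasor(make_reference_spectrum(r, axis)))
  names(phs) <- vapply(refs, function(r) r$name, character(1))
  cols <- vapply(refs, function(r) r$display_color, character(1))
  names(cols) <- names(phs)
  pe <- intersect(c("LDPE", "HDPE"), names(phs))
  if (merge_pe && length(pe) == 2) {
    keep <- setdiff(names(phs), pe)
    merged <- combine_phasors(lapply(phs[pe], function(p)
      new_phasor(p$X, p$Y, 1))) # unweighted midpoint of the two clouds
    out <- lapply(keep, function(nm)
      cursor(nm, c(phs[[nm]]$X, phs[[nm]]$Y), radius, cols[[nm]]))
    c(out, list(cursor("LDPE/HDPE", c(merged$X, merged$Y), radius,
                       cols[[pe[1]]])))
  } else {
    lapply(names(phs), function(nm)
      cursor(nm, c(phs[[nm]]$X, phs[[nm]]$Y), radius, cols[[nm]]))
  }
}
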