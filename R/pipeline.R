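#' Pipeline configuration
#'
#' Collects every knob of the lambda-stack analysis in one serializable
#' object. The resolved configuration is written alongside the outputs of
#' [run_pipeline()] so any result can be reproduced from its output
#' directory alone.
#'
#' @param axis Optional [wavelength_axis()]; when `NULL` each input's YAML
#'   sidecar must provide it.
#' @param harmonic Phasor harmonic (default 1).
#' @param threshold Background threshold: `"otsu"` or a nonnegative number.
#' @param cursors Cursor source: `"reference"` (cursors at the built-in
#'   reference-polymer phasors, LDPE/HDPE merged), a path to a cursor YAML,
#'   or `"auto"` for weighted k-means placement on the first tile.
#' @param auto_k Number of cursors when `cursors = "auto"`.
#' @param cursor_radius Cursor radius (phasor units).
#' @param min_particle_size Minimum particle area, pixels.
#' @param connectivity 4 or 8.
#' @param basis Composition basis, `"pixel_area"` or `"particle_count"`.
#' @param seed Seed for any seeded stage (auto-cursor initialization).
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(axis = NULL, harmonic = 1L, threshold = "otsu",
                            cursors = "reference", auto_k = 4L,
                            cursor_radius = 0.08, min_particle_size = 4L,
                            connectivity = 8L,
                            basis = c("pixel_area", "particle_count"),
                            seed = 1L, out_dir = "phasorMP-out") {
  basis <- match.arg(basis)
  stopifnot(connectivity %in% c(4L, 8L), min_particle_size >= 1,
            cursor_radius > 0, auto_k >= 1, harmonic >= 1)
  structure(list(axis = axis, harmonic = as.integer(harmonic),
                 threshold = threshold, cursors = cursors,
                 auto_k = as.integer(auto_k), cursor_radius = cursor_radius,
                 min_particle_size = as.integer(min_particle_size),
                 connectivity = as.integer(connectivity), basis = basis,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$axis))
    out$axis <- list(start_nm = out$axis$start, step_nm = out$axis$step,
                     count = out$axis$count)
  out
}

resolve_cursors <- function(config, first_pim, refs) {
  if (identical(config$cursors, "reference")) {
    reference_cursors(refs, first_pim$axis, radius = config$cursor_radius,
                      merge_pe = TRUE)
  } else if (identical(config$cursors, "auto")) {
    auto_cursors(first_pim, config$auto_k, radius = config$cursor_radius,
                 seed = config$seed)
  } else if (is.character(config$cursors) && file.exists(config$cursors)) {
    read_cursors_yaml(config$cursors)
  } else if (is.list(config$cursors)) {
    check_cursor_set(config$cursors)
    config$cursors
  } else {
    stop("cursors must be \"reference\", \"auto\", a cursor YAML path, or a cursor list",
         call. = FALSE)
  }
}

#' Run the full analysis pipeline over one or more lambda stacks
#'
#' For every input tile: load, per-pixel phasor transform, cursor
#' classification, particle extraction. Tiles are then pooled as a mosaic
#' and composition fractions computed on both bases. Per-tile phasor maps
#' (3-page TIFF), label maps (PNG + legend) and particle tables (CSV) are
#' written to `config$out_dir` together with `report.json`, `report.md` and
#' the resolved `config.yaml`.
#'
#' @param config A [pipeline_config()].
#' @param inputs Character vector of lambda-stack TIFF paths; non-empty.
#' @param refs Polymer references used when `config$cursors = "reference"`.
#' @param quiet Suppress progress messages.
#' @return The report, invisibly: list with per-tile summaries, the pooled
#'   particle table, and composition fractions on both bases.
#' @export
run_pipeline <- function(config, inputs,
                         refs = default_polymer_references(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.character(inputs) || length(inputs) == 0)
    stop("no inputs: supply at least one lambda-stack TIFF path",
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  cursors <- NULL
  tiles <- list()
  for (i in seq_along(inputs)) {
    say("[tile %d/%d] loading %s", i, length(inputs), inputs[i])
    img <- load_spectral_image(inputs[i], axis = config$axis, quiet = quiet)
    pim <- phasor_image(img, n = config$harmonic,
                        background_threshold = config$threshold)
    if (is.null(cursors)) cursors <- resolve_cursors(config, pim, refs)
    lm <- classify_pixels(pim, cursors)
    pt <- extract_particles(lm, config$min_particle_size,
                            config$connectivity)
    stem <- file.path(config$out_dir, sprintf("tile%02d", i))
    write_phasor_tiff(pim, paste0(stem, "_phasor.tif"))
    write_labelmap_png(lm, paste0(stem, "_labels.png"))
    write_particles_csv(pt, paste0(stem, "_particles.csv"))
    tiles[[i]] <- list(input = inputs[i], n_valid = sum(pim$valid),
                       threshold = pim$threshold, particles = pt)
  }
  write_cursors_yaml(cursors, file.path(config$out_dir, "cursors.yaml"))
  pooled <- mosaic_aggregate(lapply(tiles, `[[`, "particles"))
  write_particles_csv(pooled, file.path(config$out_dir, "particles_all.csv"))
  frac_area <- composition_fractions(pooled, "pixel_area")
  frac_count <- composition_fractions(pooled, "particle_count")
  report <- list(
    n_tiles = length(inputs),
    tiles = lapply(tiles, function(t)
      list(input = t$input, n_valid_pixels = t$n_valid,
           background_threshold = t$threshold,
           n_particles = nrow(t$particles))),
    n_particles_total = nrow(pooled),
    class_area_px = as.list(tapply(pooled$area_px, pooled$class, sum)),
    fractions_by_area = as.list(frac_area),
    fractions_by_count = as.list(frac_count),
    basis_default = config$basis)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  yaml::write_yaml(config_as_list(config),
                   file.path(config$out_dir, "config.yaml"))
  writeLines(report_markdown(report), file.path(config$out_dir, "report.md"))
  say("wrote report to %s", config$out_dir)
  invisible(report)
}

report_markdown <- function(report) {
  fr <- report$fractions_by_area
  lines <- c("# Microplastic composition report", "",
             sprintf("Tiles analyzed: %d", report$n_tiles),
             sprintf("Particles detected: %d", report$n_particles_total), "",
             "| class | area (px) | fraction by area | fraction by count |",
             "|---|---|---|---|")
  for (cl in names(fr))
    lines <- c(lines, sprintf("| %s | %d | %.4f | %.4f |", cl,
                              report$class_area_px[[cl]], fr[[cl]],
                              report$fractions_by_count[[cl]]))
  lines
}

merge_pe_labels <- function(x) ifelse(x %in% c("LDPE", "HDPE"), "LDPE/HDPE", x)

#' Benchmark the pipeline on seeded synthetic scenes
#'
#' Generates `replicates` scenes (seeds `seed`, `seed + 1`, ...), runs
#' phasor + cursor classification with cursors at the reference phasors, and
#' scores against the generator's ground truth: overall pixel accuracy
#' (LDPE/HDPE merged, since their phasor clouds superimpose in images),
#' per-class composition-fraction error, and confusion matrices both merged
#' and unmerged.
#'
#' @param spec A [scene_spec()]; its `seed` field is overridden per
#'   replicate.
#' @param refs Polymer references.
#' @param replicates Number of replicates (>= 1).
#' @param seed First replicate's seed.
#' @param cursor_radius Cursor radius.
#' @return List with `per_replicate` (data frame: seed, pixel_accuracy,
#'   max_fraction_error, per-class fraction errors), `confusion_merged`,
#'   `confusion_unmerged` (summed over replicates), and `aggregate`
#'   (mean and sd of accuracy and fraction errors).
#' @export
run_synthetic_benchmark <- function(spec, refs = default_polymer_references(),
                                    replicates = 5L, seed = 1L,
                                    cursor_radius = 0.08) {
  stopifnot(inherits(spec, "scene_spec"), replicates >= 1)
  cursors_m <- reference_cursors(refs, spec$axis, cursor_radius, merge_pe = TRUE)
  cursors_u <- reference_cursors(refs, spec$axis, cursor_radius, merge_pe = FALSE)
  lab_m <- vapply(cursors_m, function(cu) cu$label, character(1))
  lab_u <- vapply(cursors_u, function(cu) cu$label, character(1))
  conf_m <- matrix(0, length(lab_m) + 1, length(lab_m) + 1,
                   dimnames = list(truth = c("background", lab_m),
                                   predicted = c("background", lab_m)))
  conf_u <- matrix(0, length(lab_u) + 1, length(lab_u) + 1,
                   dimnames = list(truth = c("background", lab_u),
                                   predicted = c("background", lab_u)))
  rows <- list()
  for (r in seq_len(replicates)) {
    sp <- spec; sp$seed <- as.integer(seed + r - 1)
    scene <- generate_scene(sp, refs)
    pim <- phasor_image(scene$image)
    truth_named <- c("background",
                     scene$truth$class_labels)[scene$truth$labels + 1L]
    lm_m <- classify_pixels(pim, cursors_m)
    pred_m <- c("background", lab_m)[lm_m$labels + 1L]
    truth_m <- merge_pe_labels(truth_named)
    acc <- mean(pred_m == truth_m)
    conf_m <- conf_m + table(factor(truth_m, c("background", lab_m)),
                             factor(pred_m, c("background", lab_m)))
    lm_u <- classify_pixels(pim, cursors_u)
    pred_u <- c("background", lab_u)[lm_u$labels + 1L]
    conf_u <- conf_u + table(factor(truth_named, c("background", lab_u)),
                             factor(pred_u, c("background", lab_u)))
    pt <- extract_particles(lm_m)
    fr <- composition_fractions(pt, "pixel_area")
    truth_fr <- tapply(scene$particles$area_px,
                       merge_pe_labels(scene$particles$class), sum)
    truth_fr <- truth_fr / sum(truth_fr)
    err <- vapply(lab_m, function(cl) {
      f <- if (cl %in% names(fr)) fr[[cl]] else 0
      tf <- if (cl %in% names(truth_fr)) truth_fr[[cl]] else 0
      abs(f - tf)
    }, numeric(1))
    rows[[r]] <- data.frame(seed = sp$seed, pixel_accuracy = acc,
                            max_fraction_error = max(err),
                            t(err))
  }
  per <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("pixel_accuracy", "max_fraction_error"),
    mean = c(mean(per$pixel_accuracy), mean(per$max_fraction_error)),
    sd = c(stats::sd(per$pixel_accuracy), stats::sd(per$max_fraction_error)))
  list(per_replicate = per, confusion_merged = conf_m,
       confusion_unmerged = conf_u, aggregate = agg)
}
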