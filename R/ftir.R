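#' Characteristic ATR-FTIR absorption peaks of the model polymers
#'
#' The built-in table lists, per polymer class, the characteristic infrared
#' absorption peaks (wavenumber, cm-1) used for identification:
#' PP 2915/1455/1377/997/982; LDPE 2915/2845/1462/717; HDPE identical to
#' LDPE (both are polyethylene, differing only in branching); PS
#' 3024/2847/1492/1451/694; PET 1713/1241/1094/720. Shipped as an editable
#' CSV (`class,peaks` with semicolon-separated wavenumbers).
#'
#' @param path Optional alternative reference CSV.
#' @return List of `ftir_reference` objects (fields `name`, `peaks`).
#' @export
ftir_reference_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ftir_reference_peaks.csv",
                        package = "phasorMP")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "peaks") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    structure(list(name = df$class[i],
                   peaks = as.numeric(strsplit(df$peaks[i], ";")[[1]])),
              class = "ftir_reference"))
}

#' Score observed FTIR peaks against reference polymer peak lists
#'
#' For each reference class, observed peaks are matched to reference peaks
#' by greedy nearest-first one-to-one assignment within `tolerance`: the
#' globally closest (observed, reference) pair is matched first and both
#' members are consumed, so one broad observed band cannot satisfy several
#' reference peaks. The score is matched / total reference peaks. Classes
#' are ranked by descending score, then matched count; exact score ties are
#' reported as a tie set (LDPE and HDPE, whose reference rows are identical,
#' always tie on polyethylene input). If no class matches any peak the
#' ranking is flagged inconclusive.
#'
#' @param observed Numeric vector of observed peak wavenumbers, cm-1;
#'   non-empty.
#' @param refs Reference list from [ftir_reference_table()].
#' @param tolerance Match tolerance in cm-1 (> 0). Default 5: the
#'   acquisition resolution is 2 cm-1 and 5 absorbs peak-picking jitter.
#' @return Data frame `class, matched, total, score, rank, tied` sorted by
#'   rank, with attributes `inconclusive` (logical) and `unmatched_observed`
#'   (observed peaks not consumed by the top-ranked class).
#' @export
match_peaks <- function(observed, refs = ftir_reference_table(),
                        tolerance = 5) {
  observed <- as.numeric(observed)
  if (length(observed) == 0 || anyNA(observed))
    stop("no peaks supplied", call. = FALSE)
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L, tolerance > 0)
  score_one <- function(ref) {
    obs <- observed
    rp <- ref$peaks
    matched <- 0L
    while (length(obs) && length(rp)) {
      d <- abs(outer(obs, rp, "-"))
      m <- which(d == min(d), arr.ind = TRUE)[1, ]
      if (d[m[1], m[2]] > tolerance) break
      matched <- matched + 1L
      obs <- obs[-m[1]]; rp <- rp[-m[2]]
    }
    c(matched = matched, total = length(ref$peaks), leftover = length(obs))
  }
  sc <- t(vapply(refs, score_one, numeric(3)))
  out <- data.frame(class = vapply(refs, function(r) r$name, character(1)),
                    matched = as.integer(sc[, "matched"]),
                    total = as.integer(sc[, "total"]),
                    score = sc[, "matched"] / sc[, "total"])
  out <- out[order(-out$score, -out$matched, seq_len(nrow(out))), ]
  out$rank <- rank(-out$score, ties.method = "min")
  key <- sprintf("%.12f", out$score)
  out$tied <- key %in% key[duplicated(key)]
  rownames(out) <- NULL
  attr(out, "inconclusive") <- all(out$matched == 0)
  # observed peaks the best class leaves unexplained (purity reporting)
  best <- refs[[match(out$class[1], vapply(refs, function(r) r$name,
                                           character(1)))]]
  used <- logical(length(observed))
  obs <- observed; rp <- best$peaks; keep <- seq_along(observed)
  while (length(obs) && length(rp)) {
    d <- abs(outer(obs, rp, "-"))
    m <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[m[1], m[2]] > tolerance) break
    used[keep[m[1]]] <- TRUE
    obs <- obs[-m[1]]; keep <- keep[-m[1]]; rp <- rp[-m[2]]
  }
  attr(out, "unmatched_observed") <- observed[!used]
  out
}

#' Detect peaks in a raw absorbance spectrum
#'
#' Finds local maxima and keeps those whose topographic prominence (height
#' above the higher of the two bounding saddles) exceeds `prominence` times
#' the spectrum's full intensity range. Feeds [match_peaks()] from raw ATR
#' curves.
#'
#' @param spectrum Data frame or 2-column matrix: wavenumber (cm-1),
#'   intensity; at least 3 points.
#' @param prominence Relative prominence threshold in (0, 1].
#' @return Numeric vector of peak wavenumbers, sorted by descending peak
#'   intensity; empty for a flat spectrum.
#' @export
detect_peaks <- function(spectrum, prominence = 0.05) {
  spectrum <- as.data.frame(spectrum)
  stopifnot(ncol(spectrum) >= 2)
  if (nrow(spectrum) < 3)
    stop("spectrum must have at least 3 points", call. = FALSE)
  if (!is.numeric(prominence) || prominence <= 0 || prominence > 1)
    stop("prominence must be in (0, 1]", call. = FALSE)
  x <- spectrum[[1]]; y <- spectrum[[2]]
  o <- order(x); x <- x[o]; y <- y[o]
  rng <- diff(range(y))
  if (rng == 0) return(numeric(0))
  n <- length(y)
  is_max <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-(1:2)]) + 1L
  if (!length(is_max)) return(numeric(0))
  prom <- vapply(is_max, function(i) {
    left <- if (any(y[seq_len(i - 1)] > y[i])) {
      j <- max(which(y[seq_len(i - 1)] > y[i]))
      min(y[j:i])
    } else min(y[1:i])
    right <- if (any(y[(i + 1):n] > y[i])) {
      j <- i + min(which(y[(i + 1):n] > y[i]))
      min(y[i:j])
    } else min(y[i:n])
    y[i] - max(left, right)
  }, numeric(1))
  keep <- is_max[prom >= prominence * rng]
  keep[order(y[keep], decreasing = TRUE)]
  x[keep[order(y[keep], decreasing = TRUE)]]
}
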