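# Single-cell Raman spectra: containers, IO, band integration, %CD scoring,
# activity thresholds and group comparison.

#' Wavenumber window
#'
#' A half-open description of a spectral band, `lo < hi`, in cm^-1.
#'
#' @param lo,hi Window bounds in cm^-1.
#' @return A `band_window` object (list with `lo`, `hi`).
#' @export
#' @examples
#' band_window(2040, 2300)
band_window <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L || length(hi) != 1L ||
      !is.finite(lo) || !is.finite(hi)) {
    stop("band_window: 'lo' and 'hi' must be finite scalars")
  }
  if (lo >= hi) stop("band_window: 'lo' must be < 'hi'")
  structure(list(lo = lo, hi = hi), class = "band_window")
}

as_band_window <- function(x) {
  if (inherits(x, "band_window")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(band_window(x[1L], x[2L]))
  stop("expected a band_window or a numeric length-2 vector")
}

# Canonical windows used throughout: C-D and C-H stretching bands for %CD,
# the phenylalanine/amide protein region for the cell index Pc, and the
# silent-region reference band for the labeling index PL denominator.

#' Default spectral windows
#'
#' @return A named list of `band_window`s: `cd` (2040-2300 cm^-1, C-D
#'   stretching), `ch` (2800-3100, C-H stretching), `pc` (1620-1670, protein
#'   region used to detect a captured cell), `pl_den` (1850-1900, the silent
#'   region that normalizes the labeling index).
#' @export
default_windows <- function() {
  list(
    cd     = band_window(2040, 2300),
    ch     = band_window(2800, 3100),
    pc     = band_window(1620, 1670),
    pl_den = band_window(1850, 1900)
  )
}

#' Construct a single-cell Raman spectrum
#'
#' @param wavenumbers Numeric vector, cm^-1, strictly increasing after
#'   sorting; duplicates are an error.
#' @param intensities Numeric vector of detector counts, same length.
#' @param cell_id Identifier string.
#' @param sample_meta Named list of sample-level metadata (donor, treatment,
#'   timepoint_h, replicate, ...). Free-form.
#' @return A `raman_spectrum` object.
#' @export
raman_spectrum <- function(wavenumbers, intensities, cell_id = "cell",
                           sample_meta = list()) {
  w <- as.numeric(wavenumbers)
  y <- as.numeric(intensities)
  if (length(w) != length(y)) {
    stop("raman_spectrum: wavenumbers and intensities differ in length")
  }
  if (length(w) < 2L) stop("raman_spectrum: need at least 2 points")
  if (anyNA(w) || anyNA(y) || !all(is.finite(w)) || !all(is.finite(y))) {
    stop("raman_spectrum: non-finite values")
  }
  if (is.unsorted(w, strictly = FALSE)) {
    o <- order(w)
    w <- w[o]
    y <- y[o]
  }
  if (anyDuplicated(w)) stop("raman_spectrum: duplicate wavenumbers")
  structure(
    list(wavenumbers = w, intensities = y,
         cell_id = as.character(cell_id), sample_meta = sample_meta),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum '%s': %d points, %.0f-%.0f cm^-1>\n",
              x$cell_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Read a spectrum from two-column delimited text
#'
#' The expected format is what confocal Raman instruments export: one row per
#' point, wavenumber then intensity, separated by whitespace, a comma, or a
#' tab. Lines starting with `#` (and blank lines) are skipped. Rows are
#' sorted by wavenumber on load.
#'
#' @param path File path.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @param sample_meta Optional metadata list attached to the spectrum.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, cell_id = NULL, sample_meta = list()) {
  if (!file.exists(path)) stop(sprintf("read_spectrum: no such file '%s'", path))
  if (is.null(cell_id)) {
    cell_id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L) stop(sprintf("read_spectrum: '%s' has fewer than 2 data rows", path))
  w <- numeric(length(idx))
  y <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[,\t ]+")[[1L]]
    if (length(fields) != 2L) {
      stop(sprintf("read_spectrum: line %d of '%s' is not two columns", idx[k], path))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("read_spectrum: non-numeric field on line %d of '%s'", idx[k], path))
    }
    w[k] <- vals[1L]
    y[k] <- vals[2L]
  }
  if (anyDuplicated(w)) {
    dup <- which(duplicated(w))[1L]
    stop(sprintf("read_spectrum: duplicate wavenumber on line %d of '%s'",
                 idx[dup], path))
  }
  raman_spectrum(w, y, cell_id = cell_id, sample_meta = sample_meta)
}

#' Write a spectrum as two-column text
#'
#' Full double precision is preserved so that a read/write round trip is
#' exact.
#'
#' @param spec A `raman_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "raman_spectrum"))
  lines <- c(sprintf("# cell_id: %s", spec$cell_id),
             sprintf("%.17g %.17g", spec$wavenumbers, spec$intensities))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a regular grid
#'
#' Linear interpolation onto a 1 cm^-1 grid over the (sub)range covered by
#' the spectrum; used to put spectra from different instruments on a common
#' support before pointwise arithmetic.
#'
#' @param spec A `raman_spectrum`.
#' @param grid Target grid; default `seq(ceiling(min), floor(max), by = 1)`.
#' @return A `raman_spectrum` on `grid`.
#' @export
resample_spectrum <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "raman_spectrum"))
  if (is.null(grid)) {
    grid <- seq(ceiling(min(spec$wavenumbers)), floor(max(spec$wavenumbers)), by = 1)
  }
  if (min(grid) < min(spec$wavenumbers) || max(grid) > max(spec$wavenumbers)) {
    stop("resample_spectrum: grid extends beyond the spectrum span")
  }
  y <- stats::approx(spec$wavenumbers, spec$intensities, xout = grid)$y
  raman_spectrum(grid, y, cell_id = spec$cell_id, sample_meta = spec$sample_meta)
}

# Trapezoidal integral of (w, y) restricted to [lo, hi]; endpoints are
# linearly interpolated when they fall between grid points.
.trapz_window <- function(w, y, lo, hi) {
  inside <- w > lo & w < hi
  xs <- c(lo, w[inside], hi)
  ys <- c(stats::approx(w, y, xout = lo)$y,
          y[inside],
          stats::approx(w, y, xout = hi)$y)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Integrate a spectral band
#'
#' Trapezoidal integration of intensity over a wavenumber window. In
#' `"raw"` mode the intensity is integrated as measured. In
#' `"local_linear"` mode a straight baseline is first subtracted: the line
#' through the median intensity of two 5 cm^-1 shoulder regions immediately
#' outside the window (anchored at the shoulder midpoints). The corrected
#' area can be negative; callers that need a physical peak area clamp at 0
#' (as [percent_cd()] does).
#'
#' @param spec A `raman_spectrum` covering the window (and, in
#'   `local_linear` mode, the shoulders).
#' @param window A `band_window` or numeric `c(lo, hi)`.
#' @param baseline_mode `"raw"` or `"local_linear"`.
#' @param shoulder Shoulder width in cm^-1 (local_linear mode only).
#' @return Integrated area, intensity * cm^-1.
#' @export
integrate_band <- function(spec, window, baseline_mode = c("raw", "local_linear"),
                           shoulder = 5) {
  stopifnot(inherits(spec, "raman_spectrum"))
  window <- as_band_window(window)
  baseline_mode <- match.arg(baseline_mode)
  w <- spec$wavenumbers
  y <- spec$intensities
  if (window$lo < min(w) || window$hi > max(w)) {
    stop(sprintf("integrate_band: window [%g, %g] outside spectrum span [%g, %g]",
                 window$lo, window$hi, min(w), max(w)))
  }
  if (baseline_mode == "raw") {
    return(.trapz_window(w, y, window$lo, window$hi))
  }
  # local_linear: shoulders [lo - s, lo) and (hi, hi + s]
  if (window$lo - shoulder < min(w) || window$hi + shoulder > max(w)) {
    stop("integrate_band: spectrum does not cover the baseline shoulders")
  }
  left <- w >= window$lo - shoulder & w < window$lo
  right <- w > window$hi & w <= window$hi + shoulder
  if (!any(left) || !any(right)) {
    stop("integrate_band: no data points in a baseline shoulder")
  }
  xl <- window$lo - shoulder / 2
  xr <- window$hi + shoulder / 2
  ml <- stats::median(y[left])
  mr <- stats::median(y[right])
  slope <- (mr - ml) / (xr - xl)
  base <- ml + slope * (w - xl)
  .trapz_window(w, y - base, window$lo, window$hi)
}

#' Per-cell deuterium substitution score (%CD)
#'
#' The degree of deuterium substitution is the C-D stretching band area as a
#' percentage of the total C-D + C-H area,
#' `100 * A_CD / (A_CD + A_CH)`, with both areas baseline-corrected
#' (local linear) and clamped at 0 before forming the ratio. A cell with no
#' signal in either band scores 0.
#'
#' @param spec A `raman_spectrum` covering both bands and their shoulders.
#' @param cd_window,ch_window Band windows; defaults 2040-2300 and
#'   2800-3100 cm^-1.
#' @return Numeric %CD in \[0, 100\].
#' @export
percent_cd <- function(spec, cd_window = default_windows()$cd,
                       ch_window = default_windows()$ch) {
  a_cd <- max(integrate_band(spec, cd_window, "local_linear"), 0)
  a_ch <- max(integrate_band(spec, ch_window, "local_linear"), 0)
  if (a_cd + a_ch == 0) return(0)
  100 * a_cd / (a_cd + a_ch)
}

#' Score a set of spectra into a %CD table
#'
#' @param spectra List of `raman_spectrum` objects.
#' @param ... Passed to [percent_cd()].
#' @return data.frame with columns `cell_id`, `donor`, `treatment`,
#'   `percent_cd`, `labeled` (NA until classified).
#' @export
cd_score_table <- function(spectra, ...) {
  meta_field <- function(s, f) {
    v <- s$sample_meta[[f]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  data.frame(
    cell_id = vapply(spectra, function(s) s$cell_id, character(1L)),
    donor = vapply(spectra, meta_field, character(1L), f = "donor"),
    treatment = vapply(spectra, meta_field, character(1L), f = "treatment"),
    percent_cd = vapply(spectra, percent_cd, numeric(1L), ...),
    labeled = NA,
    stringsAsFactors = FALSE
  )
}

#' Calibrate the activity threshold from control cells
#'
#' Threshold = mean + 3 * sample standard deviation (n - 1 denominator) of
#' %CD values measured on cells from a control incubation without labeling
#' substrate. Cells scoring above it are called metabolically active.
#'
#' @param control_scores Numeric vector of control %CD values, length >= 2.
#' @return An `activity_threshold` object: `value`, `control_mean`,
#'   `control_sd`, `n_control`.
#' @export
calibrate_threshold <- function(control_scores) {
  x <- as.numeric(control_scores)
  if (length(x) < 2L) {
    stop("calibrate_threshold: need at least 2 control values")
  }
  if (anyNA(x) || !all(is.finite(x))) stop("calibrate_threshold: non-finite values")
  m <- mean(x)
  s <- stats::sd(x)
  structure(
    list(value = m + 3 * s, control_mean = m, control_sd = s,
         n_control = length(x)),
    class = "activity_threshold"
  )
}

#' @export
print.activity_threshold <- function(x, ...) {
  cat(sprintf("<activity_threshold: %.4g%% (mean %.4g + 3 x SD %.4g, n = %d)>\n",
              x$value, x$control_mean, x$control_sd, x$n_control))
  invisible(x)
}

#' Classify cells as labeled/unlabeled
#'
#' A cell is labeled iff its %CD strictly exceeds the threshold; ties are
#' conservative (unlabeled).
#'
#' @param scores A data.frame with a `percent_cd` column (e.g. from
#'   [cd_score_table()]) or a numeric vector.
#' @param thr An `activity_threshold` or a numeric cutoff.
#' @return Same shape as `scores` with `labeled` filled in (for a numeric
#'   vector, a logical vector).
#' @export
classify_cells <- function(scores, thr) {
  cutoff <- if (inherits(thr, "activity_threshold")) thr$value else as.numeric(thr)
  if (is.numeric(scores)) return(scores > cutoff)
  stopifnot(is.data.frame(scores), "percent_cd" %in% names(scores))
  scores$labeled <- scores$percent_cd > cutoff
  scores
}

#' One-way ANOVA of %CD between condition groups
#'
#' Fixed-effects one-way analysis of variance on per-cell scores: F from the
#' between/within mean squares, p from the F distribution.
#'
#' @param groups Named list of numeric vectors (one per group), each of
#'   length >= 2; or a numeric vector plus `g` a grouping factor.
#' @param g Optional grouping factor when `groups` is a plain vector.
#' @return List: `F`, `p`, `n`, `df` (numerator, denominator).
#' @export
compare_groups <- function(groups, g = NULL) {
  if (is.numeric(groups) && !is.null(g)) {
    groups <- split(as.numeric(groups), g)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("compare_groups: need at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("compare_groups: every group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), sizes))
  n <- length(values)
  k <- length(groups)
  grand <- mean(values)
  ss_between <- sum(sizes * (vapply(groups, mean, numeric(1L)) - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
  df1 <- k - 1L
  df2 <- n - k
  msw <- ss_within / df2
  f <- if (msw == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df1) / msw
  }
  p <- if (f == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p = p, n = n, df = c(df1, df2))
}

#' Write a %CD score table
#'
#' Tab-separated with header `cell_id, donor, treatment, percent_cd,
#' labeled`.
#'
#' @param scores data.frame from [cd_score_table()] / [classify_cells()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cd_scores <- function(scores, path) {
  utils::write.table(scores[, c("cell_id", "donor", "treatment",
                                "percent_cd", "labeled")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
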