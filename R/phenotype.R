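# Isolate physiology: growth-curve areas and growth boost, HPAEC linear
# calibration and substrate degradation, coculture log2 fold change.

#' Construct a growth curve
#'
#' @param times Hours, strictly increasing, >= 0.
#' @param od600 Optical density readings, same length, finite.
#' @param strain,medium Labels (e.g. medium `"YCFA-lactulose"`,
#'   `"YCFA-NA"`).
#' @param replicate Replicate index.
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(times, od600, strain = "strain", medium = "medium",
                         replicate = 1L) {
  t <- as.numeric(times)
  y <- as.numeric(od600)
  if (length(t) != length(y)) stop("growth_curve: lengths differ")
  if (anyNA(t) || anyNA(y) || !all(is.finite(c(t, y)))) {
    stop("growth_curve: non-finite values")
  }
  if (any(t < 0)) stop("growth_curve: times must be >= 0")
  if (is.unsorted(t, strictly = TRUE)) stop("growth_curve: times must be strictly increasing")
  structure(list(times = t, od600 = y, strain = as.character(strain),
                 medium = as.character(medium), replicate = replicate),
            class = "growth_curve")
}

as_growth_curve <- function(x) {
  if (inherits(x, "growth_curve")) return(x)
  if (is.data.frame(x) && all(c("time_h", "od600") %in% names(x))) {
    return(growth_curve(x$time_h, x$od600))
  }
  stop("expected a growth_curve or a data.frame with time_h/od600")
}

#' Area under a growth curve
#'
#' Trapezoidal integral of the blank-corrected optical density
#' `max(od600 - blank, 0)` over the full time span, in OD x h.
#'
#' @param curve A `growth_curve` (or data.frame with `time_h`, `od600`).
#' @param blank Blank OD subtracted before integration; `"first"` uses the
#'   curve's first reading (the default behaviour of [growth_boost()] is
#'   blank = 0; blanking choices are the caller's).
#' @return Area, OD x h.
#' @export
growth_auc <- function(curve, blank = 0) {
  curve <- as_growth_curve(curve)
  if (length(curve$times) < 2L) stop("growth_auc: need at least 2 time points")
  b <- if (identical(blank, "first")) curve$od600[1L] else as.numeric(blank)
  y <- pmax(curve$od600 - b, 0)
  t <- curve$times
  sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)
}

#' Growth boost
#'
#' Area under the growth curve in the amended medium relative to the
#' no-amendment control: `boost = AUC_treatment / AUC_control`.
#'
#' @param treatment,control `growth_curve`s (or data.frames).
#' @param blank Passed to [growth_auc()] for both curves.
#' @return List: `auc_treatment`, `auc_control`, `boost`.
#' @export
growth_boost <- function(treatment, control, blank = 0) {
  a_t <- growth_auc(treatment, blank)
  a_c <- growth_auc(control, blank)
  if (a_c <= 0) stop("growth_boost: control AUC must be > 0")
  list(auc_treatment = a_t, auc_control = a_c, boost = a_t / a_c)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares `signal = slope * concentration + intercept` on
#' chromatography standards (or any linear quantitation standard, e.g. a
#' qPCR dilution series already on a common scale).
#'
#' @param concentration Standard concentrations (mg/ml), >= 2 distinct.
#' @param signal Measured signals.
#' @param analyte Label.
#' @return A `calibration_curve`: `slope`, `intercept`, `r2`, `n`,
#'   `analyte`.
#' @export
fit_calibration <- function(concentration, signal, analyte = "analyte") {
  x <- as.numeric(concentration)
  y <- as.numeric(signal)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("fit_calibration: need >= 2 paired standards")
  }
  if (length(unique(x)) < 2L) {
    stop("fit_calibration: all concentrations equal, design is rank deficient")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, n = length(x), analyte = as.character(analyte)),
            class = "calibration_curve")
}

#' Concentration from signal via a calibration curve
#'
#' @param cal A `calibration_curve`.
#' @param signal Measured signal(s).
#' @return Concentration(s), `(signal - intercept) / slope`.
#' @export
concentration_from_signal <- function(cal, signal) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$slope == 0) stop("concentration_from_signal: zero slope")
  (as.numeric(signal) - cal$intercept) / cal$slope
}

#' Substrate degradation percentage
#'
#' `100 * (c0 - ct) / c0`, clamped to \[0, 100\]; measurements where the
#' final concentration exceeds the initial one clamp to 0 with a warning.
#'
#' @param c0 Initial concentration (mg/ml), > 0.
#' @param ct Final concentration (mg/ml), >= 0.
#' @return List: `c0`, `ct`, `percent_degraded`.
#' @export
degradation_percent <- function(c0, ct) {
  if (!is.finite(c0) || c0 <= 0) stop("degradation_percent: c0 must be > 0")
  if (!is.finite(ct) || ct < 0) stop("degradation_percent: ct must be >= 0")
  if (ct > c0) {
    warning("degradation_percent: ct > c0; clamping to 0% degraded")
  }
  pct <- min(max(100 * (c0 - ct) / c0, 0), 100)
  list(c0 = c0, ct = ct, percent_degraded = pct)
}

#' Coculture log2 fold change
#'
#' Fold change in abundance of a strain between monoculture and coculture:
#' `l2fc = log2(mean(co) / mean(mono))`, with significance from a plain
#' (equal-variance) Student's t-test on the log2-transformed quantities.
#' Identical constant replicate sets give `l2fc = 0, p = 1` by convention.
#'
#' @param mono,co Positive abundance quantities (e.g. qPCR copy numbers),
#'   >= 2 replicates each.
#' @return List: `l2fc`, `t`, `p`, `df`.
#' @export
coculture_l2fc <- function(mono, co) {
  mono <- as.numeric(mono)
  co <- as.numeric(co)
  if (length(mono) < 2L || length(co) < 2L) {
    stop("coculture_l2fc: need >= 2 replicates per condition")
  }
  if (any(mono <= 0) || any(co <= 0)) {
    stop("coculture_l2fc: quantities must be > 0")
  }
  l2fc <- log2(mean(co) / mean(mono))
  lm_ <- log2(mono)
  lc_ <- log2(co)
  n1 <- length(lm_)
  n2 <- length(lc_)
  sp2 <- (sum((lm_ - mean(lm_))^2) + sum((lc_ - mean(lc_))^2)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    delta <- mean(lc_) - mean(lm_)
    return(list(l2fc = l2fc, t = if (delta == 0) 0 else sign(delta) * Inf,
                p = if (delta == 0) 1 else 0, df = df))
  }
  tstat <- (mean(lc_) - mean(lm_)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(l2fc = l2fc, t = tstat,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE), df = df)
}
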