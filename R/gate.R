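# Raman-activated cell sorting: the Pc (cell capture) and PL (labeling)
# indices, the collect/waste gate, and an in-silico sorter.

#' Sorting gate configuration
#'
#' The gate uses two raw (not baseline-subtracted) band-integral ratios:
#' the cell index Pc, the 1620-1670 cm^-1 integral of the trapped object
#' relative to the carrier fluid (a captured cell raises it above 1), and
#' the labeling index PL, the deuterium band integral (2040-2300) over the
#' silent-region integral (1850-1900). A cell is collected only when both
#' indices exceed their thresholds. The default PL threshold of 5.7 is the
#' deployed calibration value; note it sits just above 5.2, the value a
#' featureless flat spectrum yields (the 260/50 window-width ratio), so it
#' is only meaningful on raw integrals. No Pc threshold is published; the
#' 1.2 default is this package's declared choice and is configurable.
#'
#' @param pc_window,pl_num_window,pl_den_window Band windows (cm^-1).
#' @param pc_threshold,pl_threshold Positive gate thresholds.
#' @return A `gate_config` object.
#' @export
gate_config <- function(pc_window = default_windows()$pc,
                        pl_num_window = default_windows()$cd,
                        pl_den_window = default_windows()$pl_den,
                        pc_threshold = 1.2,
                        pl_threshold = 5.7) {
  pc_window <- as_band_window(pc_window)
  pl_num_window <- as_band_window(pl_num_window)
  pl_den_window <- as_band_window(pl_den_window)
  if (pc_threshold <= 0 || pl_threshold <= 0) {
    stop("gate_config: thresholds must be > 0")
  }
  if (pl_den_window$hi > pl_num_window$lo) {
    stop("gate_config: PL denominator window must lie below the numerator window")
  }
  structure(
    list(pc_window = pc_window, pl_num_window = pl_num_window,
         pl_den_window = pl_den_window,
         pc_threshold = pc_threshold, pl_threshold = pl_threshold),
    class = "gate_config"
  )
}

#' Cell index Pc
#'
#' Raw integrated intensity of the trapped object over the protein window
#' divided by the carrier-fluid integral over the same window. Each spectrum
#' is integrated on its own grid; no baseline subtraction.
#'
#' @param spec Object `raman_spectrum`.
#' @param fluid Carrier-fluid reference `raman_spectrum`.
#' @param cfg A `gate_config`.
#' @return Pc ratio.
#' @export
cell_index <- function(spec, fluid, cfg = gate_config()) {
  denom <- integrate_band(fluid, cfg$pc_window, "raw")
  if (denom <= 0) {
    stop("cell_index: fluid reference integral is not positive")
  }
  integrate_band(spec, cfg$pc_window, "raw") / denom
}

#' Labeling index PL
#'
#' Raw integrated intensity over the deuterium band (2040-2300 cm^-1)
#' divided by the raw integral over the silent reference region
#' (1850-1900 cm^-1). Scale-invariant in the overall spectrum intensity.
#'
#' @param spec A `raman_spectrum` covering both windows.
#' @param cfg A `gate_config`.
#' @return PL ratio.
#' @export
labeling_index <- function(spec, cfg = gate_config()) {
  denom <- integrate_band(spec, cfg$pl_den_window, "raw")
  if (denom <= 0) {
    stop("labeling_index: reference-band integral is not positive")
  }
  integrate_band(spec, cfg$pl_num_window, "raw") / denom
}

#' Gate decision
#'
#' Collect iff `pc > pc_threshold` AND `pl > pl_threshold`; ties go to
#' waste. Vectorized over `pc`/`pl`.
#'
#' @param pc,pl Index values.
#' @param cfg A `gate_config`.
#' @return Character vector, `"collect"` or `"waste"`.
#' @export
gate_decision <- function(pc, pl, cfg = gate_config()) {
  ifelse(pc > cfg$pc_threshold & pl > cfg$pl_threshold, "collect", "waste")
}

#' Simulate a sorting run
#'
#' Applies both indices and the gate to a stream of spectra, acting as a
#' pure classifier (no fluidics, dwell times or throughput are modeled).
#' When ground-truth labels are supplied, sensitivity (collected fraction of
#' truly labeled cells) and specificity (wasted fraction of truly unlabeled
#' cells) are reported.
#'
#' @param stream List of `raman_spectrum` objects.
#' @param fluid Carrier-fluid reference spectrum.
#' @param cfg A `gate_config`.
#' @param truth Optional logical vector of ground-truth labeled status.
#' @return List with `events` (data.frame: cell_id, pc, pl, decision,
#'   truth_labeled) and `summary` (n_events, n_collected, n_waste,
#'   sensitivity, specificity).
#' @export
simulate_sort <- function(stream, fluid, cfg = gate_config(), truth = NULL) {
  n <- length(stream)
  if (!is.null(truth) && length(truth) != n) {
    stop("simulate_sort: truth length must match the stream")
  }
  if (n == 0L) {
    events <- data.frame(cell_id = character(0), pc = numeric(0),
                         pl = numeric(0), decision = character(0),
                         truth_labeled = logical(0), stringsAsFactors = FALSE)
    return(list(events = events,
                summary = list(n_events = 0L, n_collected = 0L, n_waste = 0L,
                               sensitivity = NA_real_, specificity = NA_real_)))
  }
  pc <- vapply(stream, cell_index, numeric(1L), fluid = fluid, cfg = cfg)
  pl <- vapply(stream, labeling_index, numeric(1L), cfg = cfg)
  decision <- gate_decision(pc, pl, cfg)
  events <- data.frame(
    cell_id = vapply(stream, function(s) s$cell_id, character(1L)),
    pc = pc, pl = pl, decision = decision,
    truth_labeled = if (is.null(truth)) NA else as.logical(truth),
    stringsAsFactors = FALSE
  )
  sens <- spec_ <- NA_real_
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    if (any(truth)) sens <- mean(decision[truth] == "collect")
    if (any(!truth)) spec_ <- mean(decision[!truth] == "waste")
  }
  list(events = events,
       summary = list(n_events = n,
                      n_collected = sum(decision == "collect"),
                      n_waste = sum(decision == "waste"),
                      sensitivity = sens, specificity = spec_))
}
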