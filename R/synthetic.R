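# Synthetic data with recorded ground truth: Raman spectra with controlled
# %CD, fluid backgrounds, sorter streams with targeted PL, Dirichlet-
# multinomial donor-structured count tables, and logistic growth curves.
# Every generator is reproducible given (spec, seed).

#' Specification of a synthetic single-cell Raman spectrum
#'
#' The generated spectrum is a tilted baseline plus Gaussian C-D and C-H
#' stretching bands plus i.i.d. Gaussian noise on a 400-3200 cm^-1 grid at
#' 1 cm^-1. The C-D band area is chosen so that the baseline-corrected,
#' clamped area ratio equals `percent_cd_true`:
#' `A_CD = percent_cd_true / (100 - percent_cd_true) * ch_area`.
#' Band widths default to sigma 25/30 cm^-1, narrow enough that the
#' Gaussian mass outside the integration windows is negligible (< 0.1%).
#' Defaults emulate moderate single-cell signal-to-noise: a C-H band of
#' area 400 over an offset-10 baseline with noise SD 0.05.
#'
#' @param percent_cd_true Target %CD in \[0, 100\); 100 is infeasible
#'   whenever `ch_area > 0`.
#' @param ch_area C-H band area (intensity x cm^-1), >= 0.
#' @param peak_width_cd,peak_width_ch Gaussian sigmas (cm^-1).
#' @param baseline_offset,baseline_slope Baseline intercept and tilt.
#' @param noise_sd Gaussian noise SD, >= 0.
#' @param grid Wavenumber grid.
#' @param cd_center,ch_center Band centers (must lie inside the C-D /
#'   C-H windows).
#' @return A `spectrum_spec` list.
#' @export
spectrum_spec <- function(percent_cd_true = 0, ch_area = 400,
                          peak_width_cd = 25, peak_width_ch = 30,
                          baseline_offset = 10, baseline_slope = 0.005,
                          noise_sd = 0.05, grid = seq(400, 3200, by = 1),
                          cd_center = 2170, ch_center = 2950) {
  if (percent_cd_true < 0 || percent_cd_true > 100) {
    stop("spectrum_spec: percent_cd_true must be in [0, 100]")
  }
  if (percent_cd_true == 100 && ch_area > 0) {
    stop("spectrum_spec: percent_cd_true = 100 is infeasible with ch_area > 0")
  }
  if (ch_area < 0 || noise_sd < 0) stop("spectrum_spec: areas and noise_sd must be >= 0")
  if (cd_center < 2040 || cd_center > 2300) stop("spectrum_spec: cd_center outside 2040-2300")
  if (ch_center < 2800 || ch_center > 3100) stop("spectrum_spec: ch_center outside 2800-3100")
  structure(list(percent_cd_true = percent_cd_true, ch_area = ch_area,
                 peak_width_cd = peak_width_cd, peak_width_ch = peak_width_ch,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 grid = grid, cd_center = cd_center, ch_center = ch_center),
            class = "spectrum_spec")
}

# Deterministic band + baseline shape; cd_area in raw band-area units.
.spectrum_shape <- function(spec, cd_area) {
  w <- spec$grid
  spec$baseline_offset + spec$baseline_slope * (w - min(w)) +
    cd_area * stats::dnorm(w, spec$cd_center, spec$peak_width_cd) +
    spec$ch_area * stats::dnorm(w, spec$ch_center, spec$peak_width_ch)
}

#' Generate one synthetic Raman spectrum
#'
#' @param spec A `spectrum_spec`.
#' @param seed Optional RNG seed (bit-reproducible output for a fixed
#'   seed).
#' @param cell_id,sample_meta Identity metadata for the spectrum.
#' @return A `raman_spectrum`.
#' @export
generate_spectrum <- function(spec = spectrum_spec(), seed = NULL,
                              cell_id = "synthetic_cell", sample_meta = list()) {
  stopifnot(inherits(spec, "spectrum_spec"))
  p <- spec$percent_cd_true
  cd_area <- if (p >= 100) spec$ch_area else p / (100 - p) * spec$ch_area
  y <- .spectrum_shape(spec, cd_area)
  if (spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
  }
  raman_spectrum(spec$grid, y, cell_id = cell_id, sample_meta = sample_meta)
}

# Truncated-normal draws by inverse-CDF; exact for a fixed seed.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a population of cells with known activity labels
#'
#' Labeled cells draw `percent_cd_true` from the active distribution,
#' unlabeled cells from the null; both are normal distributions truncated
#' to \[0, 100\]. The default population size follows the 30-40 cells per
#' sample typically measured on slides.
#'
#' @param n_cells Number of cells (default 35).
#' @param labeled_fraction Fraction of truly active cells in \[0, 1\].
#' @param cd_active_mean,cd_active_sd Active %CD distribution.
#' @param cd_null_mean,cd_null_sd Null (unlabeled) %CD distribution.
#' @param seed RNG seed.
#' @param base_spec `spectrum_spec` template (its `percent_cd_true` is
#'   overridden per cell).
#' @param sample_meta Metadata attached to every cell.
#' @return List: `spectra` (list of `raman_spectrum`), `truth` (data.frame
#'   `cell_id`, `labeled`, `percent_cd_true`).
#' @export
generate_cell_population <- function(n_cells = 35, labeled_fraction = 0.5,
                                     cd_active_mean = 30, cd_active_sd = 10,
                                     cd_null_mean = 2, cd_null_sd = 1,
                                     seed = NULL, base_spec = spectrum_spec(),
                                     sample_meta = list()) {
  if (labeled_fraction < 0 || labeled_fraction > 1) {
    stop("generate_cell_population: labeled_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  labeled <- stats::runif(n_cells) < labeled_fraction
  pcd <- numeric(n_cells)
  pcd[labeled] <- rtruncnorm(sum(labeled), cd_active_mean, cd_active_sd, 0, 100)
  pcd[!labeled] <- rtruncnorm(sum(!labeled), cd_null_mean, cd_null_sd, 0, 100)
  # cap just below 100 so the area mapping stays feasible
  pcd <- pmin(pcd, 99.9)
  ids <- sprintf("cell_%04d", seq_len(n_cells))
  spectra <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sp <- base_spec
    sp$percent_cd_true <- pcd[i]
    spectra[[i]] <- generate_spectrum(sp, seed = NULL, cell_id = ids[i],
                                      sample_meta = sample_meta)
  }
  list(spectra = spectra,
       truth = data.frame(cell_id = ids, labeled = labeled,
                          percent_cd_true = pcd, stringsAsFactors = FALSE))
}

#' Generate a carrier-fluid background spectrum
#'
#' A flat low-intensity background (plus optional noise) used as the Pc
#' reference stream: with zero noise its raw integral over any window of
#' width w is exactly `offset * w`.
#'
#' @param grid Wavenumber grid.
#' @param offset Background intensity, > 0.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @return A `raman_spectrum`.
#' @export
generate_fluid_background <- function(grid = seq(400, 3200, by = 1),
                                      offset = 10, noise_sd = 0, seed = NULL) {
  if (offset <= 0) stop("generate_fluid_background: offset must be > 0")
  y <- rep(offset, length(grid))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(grid), 0, noise_sd)
  }
  raman_spectrum(grid, y, cell_id = "fluid")
}

#' Generate a sorter input stream with targeted PL values
#'
#' Builds cells over a flat `offset` background with (i) a protein band at
#' 1650 cm^-1 sized so the cell index hits `pc_target`, and (ii) a C-D band
#' sized so the labeling index hits a PL value drawn from the labeled or
#' unlabeled distribution. On a flat background of any height the PL of a
#' band-free spectrum is 5.2 (the 260/50 window-width ratio), so the C-D
#' band area for a target t is `offset * 50 * (t - 5.2)`; targets below 5.2
#' produce a shallow dip, mimicking measurement spread below the
#' featureless value.
#'
#' @param n Number of cells.
#' @param labeled_fraction Fraction of truly labeled cells.
#' @param pl_active_mean,pl_active_sd Labeled PL distribution (default
#'   9 +/- 1).
#' @param pl_null_mean,pl_null_sd Unlabeled PL distribution (default
#'   5.2 +/- 0.2, centered on the featureless value).
#' @param pc_target Cell index of every generated cell (default 2).
#' @param offset Flat background intensity.
#' @param noise_sd Spectral noise SD.
#' @param seed RNG seed.
#' @return List: `spectra`, `fluid` (matched reference), `truth`
#'   (data.frame `cell_id`, `labeled`, `pl_target`).
#' @export
generate_sort_stream <- function(n = 200, labeled_fraction = 0.5,
                                 pl_active_mean = 9, pl_active_sd = 1,
                                 pl_null_mean = 5.2, pl_null_sd = 0.2,
                                 pc_target = 2, offset = 10, noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(400, 3200, by = 1)
  wins <- default_windows()
  flat_pl <- (wins$cd$hi - wins$cd$lo) / (wins$pl_den$hi - wins$pl_den$lo)
  pc_width <- wins$pc$hi - wins$pc$lo
  den_width <- wins$pl_den$hi - wins$pl_den$lo
  labeled <- stats::runif(n) < labeled_fraction
  pl_t <- numeric(n)
  pl_t[labeled] <- stats::rnorm(sum(labeled), pl_active_mean, pl_active_sd)
  pl_t[!labeled] <- stats::rnorm(sum(!labeled), pl_null_mean, pl_null_sd)
  protein_area <- offset * pc_width * (pc_target - 1)
  ids <- sprintf("sort_%04d", seq_len(n))
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    cd_area <- offset * den_width * (pl_t[i] - flat_pl)
    y <- offset +
      protein_area * stats::dnorm(grid, 1645, 8) +
      cd_area * stats::dnorm(grid, 2170, 25)
    if (noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, noise_sd)
    spectra[[i]] <- raman_spectrum(grid, y, cell_id = ids[i])
  }
  list(spectra = spectra,
       fluid = generate_fluid_background(grid, offset = offset),
       truth = data.frame(cell_id = ids, labeled = labeled, pl_target = pl_t,
                          stringsAsFactors = FALSE))
}

#' Specification of a synthetic donor-structured community experiment
#'
#' Emulates a paired-fraction incubation across ~6 donors: each donor
#' carries a strong individual compositional fingerprint (log-normal
#' multiplicative donor effects), and planted responder genera are
#' multiplied by `exp(effect)` in the treatment samples. Counts are drawn
#' Dirichlet-multinomial so technical replicates are overdispersed relative
#' to a plain multinomial.
#'
#' The built-in design generates, per donor and replicate: a baseline bulk
#' sample (`treatment = "none"`, `fraction = "bulk"`, 0 h), a treated
#' active-sorted sample (`treatment = "lactulose"`,
#' `fraction = "boncat_pos"`, 6 h) and an untreated reference sorted sample
#' (`treatment = "none"`, `fraction = "dapi_neg"`, 6 h).
#'
#' @param n_donors Number of donors (default 6).
#' @param n_genera Number of genera (default 50).
#' @param reads_per_sample Sequencing depth (default 20000; column sums are
#'   exact).
#' @param donor_effect_sd SD of per-donor log-abundance offsets (default
#'   1.2, calibrated so donor identity dominates Bray-Curtis variance).
#' @param responders Named numeric vector of planted log-fold effects,
#'   names must be genus labels (`"g01"`...).
#' @param dispersion Dirichlet concentration (larger = closer to
#'   multinomial; default 200).
#' @param replicates Technical replicates per donor x condition (default
#'   2).
#' @param base_log_sd SD of the shared genus log-abundance profile.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_donors = 6, n_genera = 50,
                           reads_per_sample = 20000, donor_effect_sd = 1.2,
                           responders = c(), dispersion = 200,
                           replicates = 2, base_log_sd = 1.5) {
  if (reads_per_sample <= 0) stop("community_spec: reads_per_sample must be > 0")
  if (length(responders) && anyNA(responders)) stop("community_spec: effects must be finite")
  genera <- sprintf("g%02d", seq_len(n_genera))
  if (length(responders) && !all(names(responders) %in% genera)) {
    stop("community_spec: responder genus not in the table")
  }
  structure(list(n_donors = n_donors, n_genera = n_genera,
                 reads_per_sample = reads_per_sample,
                 donor_effect_sd = donor_effect_sd, responders = responders,
                 dispersion = dispersion, replicates = replicates,
                 base_log_sd = base_log_sd, genera = genera),
            class = "community_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Generate a donor-structured count table with planted responders
#'
#' @param spec A `community_spec`.
#' @param seed RNG seed.
#' @return List: `table` (a `count_table`), `truth` (data.frame `genus`,
#'   `effect`).
#' @export
generate_count_table <- function(spec = community_spec(), seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (!is.null(seed)) set.seed(seed)
  genera <- spec$genera
  donors <- sprintf("D%d", seq_len(spec$n_donors))
  # genus labels are ordered by expected baseline abundance (g01 most
  # abundant), so planted responders at low indices model dominant taxa --
  # the regime where sorted-fraction EF analyses operate
  base_log <- sort(stats::rnorm(spec$n_genera, 0, spec$base_log_sd),
                   decreasing = TRUE)
  donor_log <- matrix(stats::rnorm(spec$n_genera * spec$n_donors, 0,
                                   spec$donor_effect_sd),
                      spec$n_genera, spec$n_donors)
  effect <- stats::setNames(rep(0, spec$n_genera), genera)
  if (length(spec$responders)) effect[names(spec$responders)] <- spec$responders

  conditions <- data.frame(
    treatment = c("none", "lactulose", "none"),
    fraction = c("bulk", "boncat_pos", "dapi_neg"),
    timepoint_h = c(0, 6, 6),
    treated = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  meta <- do.call(rbind, lapply(seq_along(donors), function(di) {
    do.call(rbind, lapply(seq_len(nrow(conditions)), function(ci) {
      data.frame(
        sample_id = sprintf("%s_%s_%s_t%d_r%d", donors[di],
                            conditions$treatment[ci], conditions$fraction[ci],
                            conditions$timepoint_h[ci], seq_len(spec$replicates)),
        donor = donors[di],
        treatment = conditions$treatment[ci],
        fraction = conditions$fraction[ci],
        timepoint_h = conditions$timepoint_h[ci],
        replicate = seq_len(spec$replicates),
        treated = conditions$treated[ci],
        stringsAsFactors = FALSE
      )
    }))
  }))
  counts <- matrix(0L, spec$n_genera, nrow(meta),
                   dimnames = list(genera, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    di <- match(meta$donor[s], donors)
    loglam <- base_log + donor_log[, di]
    if (meta$treated[s]) loglam <- loglam + effect
    pi_s <- exp(loglam - max(loglam))
    pi_s <- pi_s / sum(pi_s)
    p <- rdirichlet1(spec$dispersion * pi_s)
    counts[, s] <- stats::rmultinom(1L, spec$reads_per_sample, p)[, 1L]
  }
  meta$treated <- NULL
  list(table = count_table(counts, meta),
       truth = data.frame(genus = genera, effect = unname(effect),
                          stringsAsFactors = FALSE))
}

#' Generate paired logistic growth curves
#'
#' Shifted logistic `K / (1 + exp(-r (t - t_mid)))` sampled every `step`
#' hours over `[0, horizon]`, with additive Gaussian noise clamped at 0.
#' The treatment set's carrying capacity is `boost * K`, so with zero noise
#' the AUC ratio equals `boost` exactly.
#'
#' @param K Carrying capacity (OD600), > 0.
#' @param r Growth rate (1/h), > 0.
#' @param t_mid Inflection time (h); plays the role of the lag midpoint.
#' @param noise_sd OD noise SD.
#' @param horizon Total duration (h).
#' @param step Sampling interval (h), default 0.5 (a 30-min plate-reader
#'   cycle).
#' @param boost Treatment/control capacity ratio.
#' @param replicates Curves per condition.
#' @param seed RNG seed.
#' @return List: `treatment`, `control` (lists of `growth_curve`), `truth`
#'   (the parameters).
#' @export
generate_growth_curves <- function(K = 1, r = 0.5, t_mid = 8, noise_sd = 0.01,
                                   horizon = 24, step = 0.5, boost = 1,
                                   replicates = 3, seed = NULL) {
  if (K <= 0 || r <= 0 || step <= 0) {
    stop("generate_growth_curves: K, r and step must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, horizon, by = step)
  one <- function(cap, medium, rep_i) {
    y <- cap / (1 + exp(-r * (t - t_mid)))
    if (noise_sd > 0) y <- pmax(y + stats::rnorm(length(t), 0, noise_sd), 0)
    growth_curve(t, y, strain = "isolate", medium = medium, replicate = rep_i)
  }
  list(
    treatment = lapply(seq_len(replicates), function(i)
      one(boost * K, "YCFA-lactulose", i)),
    control = lapply(seq_len(replicates), function(i) one(K, "YCFA-NA", i)),
    truth = list(K = K, r = r, t_mid = t_mid, boost = boost,
                 noise_sd = noise_sd, horizon = horizon, step = step)
  )
}

#' Closed-form integral of the shifted logistic
#'
#' `Integral_0^T K / (1 + exp(-r (t - t_mid))) dt
#'  = (K / r) * (log(1 + exp(r (T - t_mid))) - log(1 + exp(-r t_mid)))`,
#' used as the analytic oracle for trapezoidal growth-curve areas.
#'
#' @param K,r,t_mid Logistic parameters.
#' @param T_end Upper integration limit (h).
#' @return Exact area, OD x h.
#' @export
logistic_auc <- function(K, r, t_mid, T_end) {
  (K / r) * (log1p(exp(r * (T_end - t_mid))) - log1p(exp(-r * t_mid)))
}
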