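# raman_core: parsing, band integration, %CD, threshold calibration,
# classification and group comparison.

test_that("read_spectrum parses, sorts, and reports malformed input", {
  path <- withr::local_tempfile(fileext = ".txt")

  writeLines(c("400 10", "401 11"), path)
  sp <- read_spectrum(path)
  expect_equal(sp$wavenumbers, c(400, 401))
  expect_equal(sp$intensities, c(10, 11))

  # rows out of order load sorted; comma and tab delimiters accepted
  writeLines(c("# header", "402,12", "400\t10", "401 11"), path)
  sp <- read_spectrum(path)
  expect_equal(sp$wavenumbers, c(400, 401, 402))
  expect_equal(sp$intensities, c(10, 11, 12))

  writeLines(c("400 10", "401 abc"), path)
  expect_error(read_spectrum(path), "line 2")
  writeLines(c("400 10", "400 11"), path)
  expect_error(read_spectrum(path), "duplicate")
  writeLines(c("400 10 3", "401 11"), path)
  expect_error(read_spectrum(path), "two columns")
})

test_that("write/read round-trip preserves arrays to full precision", {
  set.seed(41)
  sp <- raman_spectrum(sort(runif(50, 400, 3200)), rnorm(50, 100, 13),
                       cell_id = "rt")
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path, cell_id = "rt")
  expect_identical(back$wavenumbers, sp$wavenumbers)
  expect_identical(back$intensities, sp$intensities)
})

test_that("raman_spectrum validates its invariants", {
  expect_error(raman_spectrum(1:3, 1:2), "length")
  expect_error(raman_spectrum(400, 1), "2 points")
  expect_error(raman_spectrum(c(400, 400, 401), c(1, 2, 3)), "duplicate")
  expect_error(raman_spectrum(c(400, 401), c(1, NA)), "finite")
})

test_that("integrate_band raw mode: flat cases and window errors", {
  zero <- flat_spectrum(0)
  expect_equal(integrate_band(zero, c(2040, 2300), "raw"), 0)
  k <- 3.5
  expect_equal(integrate_band(flat_spectrum(k), c(2040, 2300), "raw"),
               k * 260)
  # fractional window endpoints are interpolated
  expect_equal(integrate_band(flat_spectrum(k), c(2040.5, 2050.25), "raw"),
               k * 9.75)
  expect_error(integrate_band(flat_spectrum(1), c(3100, 3300), "raw"),
               "outside")
  expect_error(integrate_band(flat_spectrum(1), c(398, 500), "local_linear"),
               "outside|shoulder")
})

test_that("integrate_band raw mode is linear on a shared grid", {
  set.seed(7)
  win <- band_window(1500, 1700)
  for (i in 1:5) {
    y1 <- rnorm(length(default_grid()), 10, 2)
    y2 <- rnorm(length(default_grid()), 5, 1)
    a <- runif(1, -2, 2)
    b <- runif(1, -2, 2)
    s1 <- raman_spectrum(default_grid(), y1)
    s2 <- raman_spectrum(default_grid(), y2)
    s12 <- raman_spectrum(default_grid(), a * y1 + b * y2)
    expect_equal(integrate_band(s12, win, "raw"),
                 a * integrate_band(s1, win, "raw") +
                   b * integrate_band(s2, win, "raw"),
                 tolerance = 1e-10)
  }
})

test_that("local_linear baseline recovers a Gaussian area on a tilted offset", {
  area <- 120
  sp <- gauss_spectrum(area, 2170, 25, offset = 50, slope = 0.02)
  got <- integrate_band(sp, c(2040, 2300), "local_linear")
  expect_lt(abs(got - area) / area, 0.01)
  # and against a naive trapezoid oracle on the band-only arrays
  band_only <- area * dnorm(default_grid(), 2170, 25)
  inside <- default_grid() >= 2040 & default_grid() <= 2300
  expect_equal(got, oracle_trapz(default_grid()[inside], band_only[inside]),
               tolerance = 1e-3)
})

test_that("percent_cd matches constructed area ratios and clamps at zero", {
  g <- default_grid()
  # no C-D band, prominent C-H band -> 0
  ch_only <- gauss_spectrum(300, 2950, 30, offset = 10)
  expect_equal(percent_cd(ch_only), 0)
  # equal areas -> 50
  both <- raman_spectrum(g, 10 + 80 * dnorm(g, 2170, 25) +
                           80 * dnorm(g, 2950, 30))
  expect_equal(percent_cd(both), 50, tolerance = 1e-4)
  # A_CD = 2, A_CH = 6 -> 25
  s26 <- raman_spectrum(g, 5 + 2 * dnorm(g, 2170, 25) +
                          6 * dnorm(g, 2950, 30))
  expect_equal(percent_cd(s26), 25, tolerance = 0.1)
  # coverage error
  short <- raman_spectrum(seq(400, 2500, 1), rep(1, 2101))
  expect_error(percent_cd(short), "outside|shoulder")
})

test_that("percent_cd is bounded and monotone in the C-D amplitude", {
  g <- default_grid()
  set.seed(11)
  for (i in 1:4) {
    ch_area <- runif(1, 50, 400)
    offset <- runif(1, 0, 30)
    prev <- -Inf
    for (cd_area in c(0, 5, 25, 100, 400)) {
      sp <- raman_spectrum(g, offset + cd_area * dnorm(g, 2170, 25) +
                             ch_area * dnorm(g, 2950, 30) +
                             rnorm(length(g), 0, 0.01))
      p <- percent_cd(sp)
      expect_gte(p, 0)
      expect_lte(p, 100)
      expect_gte(p, prev - 0.2)  # tiny slack for the noise
      prev <- p
    }
  }
})

test_that("calibrate_threshold: mean + 3 sample SD, equivariances, errors", {
  expect_equal(calibrate_threshold(rep(4.2, 10))$value, 4.2)
  thr <- calibrate_threshold(c(1, 2, 3))
  expect_equal(thr$control_mean, 2)
  expect_equal(thr$control_sd, 1)
  expect_equal(thr$value, 5)
  expect_equal(thr$n_control, 3L)
  expect_error(calibrate_threshold(7), "2 control")

  set.seed(5)
  x <- rnorm(40, 3, 0.7)
  base <- calibrate_threshold(x)$value
  expect_equal(calibrate_threshold(x + 1.3)$value, base + 1.3,
               tolerance = 1e-12)
  expect_equal(calibrate_threshold(2.5 * x)$value, 2.5 * base,
               tolerance = 1e-12)

  # simulation oracle: N(1, 0.5) -> threshold -> 2.5
  set.seed(19)
  big <- rnorm(1e5, 1, 0.5)
  expect_equal(calibrate_threshold(big)$value, 2.5, tolerance = 0.02)
})

test_that("classify_cells uses a strict cutoff and hits the 3-sigma tail", {
  thr <- calibrate_threshold(c(1, 2, 3))  # value 5
  df <- data.frame(cell_id = c("a", "b", "c"), percent_cd = c(5, 4.99, 5.01),
                   labeled = NA)
  out <- classify_cells(df, thr)
  expect_equal(out$labeled, c(FALSE, FALSE, TRUE))
  expect_false(any(classify_cells(rep(0, 5), thr)))

  # Gaussian null scored against its own mean + 3 SD: upper 3-sigma tail
  set.seed(23)
  x <- rnorm(2e5, 10, 2)
  frac <- mean(classify_cells(x, calibrate_threshold(x)))
  expect_lt(abs(frac - pnorm(3, lower.tail = FALSE)), 5e-4)
})

test_that("compare_groups: hand oracle, degenerate and separated cases", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- compare_groups(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  res <- compare_groups(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(res$F, 1.5)            # SSB 1.5 / (SSW 4 / 4)
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$n, 6L)

  # cross-check against the fixed-effects ANOVA reference implementation
  set.seed(3)
  g <- rep(c("a", "b", "c"), each = 8)
  v <- rnorm(24) + (g == "b") * 0.5
  mine <- compare_groups(v, g)
  ref <- oneway.test(v ~ g, var.equal = TRUE)
  expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-10)

  set.seed(4)
  far <- list(a = rnorm(30, 0, 1), b = rnorm(30, 10, 1))
  expect_lt(compare_groups(far)$p, 1e-6)

  expect_error(compare_groups(list(a = 1, b = c(1, 2))), ">= 2 values")
  expect_error(compare_groups(list(a = c(1, 2))), "2 groups")
})
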