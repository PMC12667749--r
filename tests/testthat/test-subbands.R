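test_that("derivative trimming keeps 400 of 426 points and preserves the grid", {
  g <- default_grid()
  s <- new_spectrum(g, rnorm(426))
  d <- second_derivative(s)
  expect_length(d$absorbance, 400)
  p <- derivative_params()
  expect_equal(d$grid$values,
               g$values[(p$trim_low + 1):(426 - p$trim_high)])
  expect_equal(p$trim_low + p$trim_high, 26)
  # the 966 cm-1 reference band stays on the trimmed support
  expect_lte(d$grid$start, 966 - g$step)
})

test_that("derivative parameter invariants are enforced", {
  expect_error(derivative_params(window_length = 12), "odd")
  expect_error(derivative_params(window_length = 3, poly_order = 2), "poly_order")
  expect_error(derivative_params(trim_low = -1), "non-negative")
  g <- small_grid()
  s <- new_spectrum(g, rnorm(length(g$values)))
  expect_error(second_derivative(s, derivative_params(trim_low = 30, trim_high = 30)),
               "whole spectrum")
})

test_that("the filter reproduces quadratic curvature exactly in physical units", {
  g <- default_grid()
  k <- seq_len(426)
  a <- 0.37
  d <- second_derivative(new_spectrum(g, a * k^2))
  expect_equal(d$absorbance, rep(2 * a / g$step^2, 400), tolerance = 1e-9)
})

test_that("the derivative minimum of a noise-free Gaussian band sits at its center", {
  g <- default_grid()
  wn <- g$values
  for (cc in c(1035, 1238, 1658)) {
    y <- exp(-4 * log(2) * (wn - cc)^2 / 20^2)
    d <- second_derivative(new_spectrum(g, y))
    got <- d$grid$values[which.min(d$absorbance)]
    # oracle: dense finite differences of the analytic band
    dense <- seq(cc - 30, cc + 30, by = 0.01)
    fd <- diff(exp(-4 * log(2) * (dense - cc)^2 / 20^2), differences = 2)
    oracle <- dense[which.min(fd) + 1]
    expect_equal(got, g$values[which.min(abs(g$values - oracle))])
  }
})

test_that("peak detection obeys the 3-sigma contract on constructed inputs", {
  g <- make_grid(1600, 1700, 2)
  zero <- new_spectrum(g, rep(0, length(g$values)))
  expect_equal(nrow(detect_significant_peaks(zero, sigma = 1)), 0)

  sigma <- 1e-4
  dip <- new_spectrum(g, -10 * sigma * exp(-(g$values - 1658)^2 / 50))
  calls <- detect_significant_peaks(dip, sigma)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$center, 1658)
  expect_equal(calls$significance, 10)
  expect_equal(calls$depth, -10 * sigma)

  # a 2.9-sigma dip is not significant
  weak <- new_spectrum(g, -2.9 * sigma * exp(-(g$values - 1658)^2 / 50))
  expect_equal(nrow(detect_significant_peaks(weak, sigma)), 0)

  expect_error(detect_significant_peaks(dip, sigma = 0), "positive")
  expect_error(detect_significant_peaks(dip, sigma = -1), "positive")
})

test_that("detection is scale-consistent: scaling spectrum and sigma preserves calls", {
  set.seed(21)
  g <- default_grid()
  y <- rnorm(426, sd = 0.01) + 0.5 * exp(-4 * log(2) * (g$values - 1400)^2 / 400)
  d <- second_derivative(new_spectrum(g, y))
  sigma <- 2e-4
  base <- detect_significant_peaks(d, sigma)
  for (c_scale in c(1e-3, 7, 1e4)) {
    scaled <- detect_significant_peaks(
      new_spectrum(d$grid, d$absorbance * c_scale), sigma * c_scale)
    expect_equal(scaled$center, base$center)
    expect_equal(scaled$significance, base$significance, tolerance = 1e-9)
  }
})

test_that("mean-spectrum calls on a default synthetic ROI match the generator bands", {
  cfg <- default_config()
  cube <- simulate_cube(cfg, "kidney", "FF", roi_id = "k", seed = 42)
  tm <- tissue_mask(cube)
  bs <- background_stats(cube, tm$mask)
  raw <- sample_pixels(cube, tm$mask, 2000, seed = 1, correct = FALSE)
  m <- rubberband_correct(roi_mean_spectrum(raw))$corrected
  calls <- detect_significant_peaks(second_derivative(m), bs$sigma)
  truth <- sort(cfg$band_tables$kidney_FF$center)
  expect_equal(nrow(calls), 13)
  expect_true(all(abs(calls$center - truth) <= 2))
})

test_that("occurrence counting saturates, rejects bad inputs, respects tolerance", {
  g <- default_grid()
  wn <- g$values
  n <- 30
  mk_set <- function(mat, roi) {
    spectrum_set(g, mat, data.frame(row = seq_len(nrow(mat)), col = 1),
                 roi, "kidney", "FF")
  }
  dipmat <- matrix(rep(0.2 * exp(-4 * log(2) * (wn - 1238)^2 / 400),
                       each = n), n)
  set <- mk_set(dipmat + 1e-6 * matrix(rnorm(n * 426), n), "r1")
  bands <- default_band_table()
  occ <- peak_occurrence(list(set), bands, sigma = 1e-5, n_per_roi = n, seed = 1)
  expect_equal(unname(occ["1238", 1]), n)
  expect_equal(attr(occ, "n_per_roi"), n)

  expect_error(peak_occurrence(list(set), bands, sigma = 1e-5, n_per_roi = n + 1),
               "exceeds")
  expect_error(peak_occurrence(list(set), bands, sigma = 1e-5, n_per_roi = n,
                               tolerance = 1), "grid step")
  off <- data.frame(assignment = "edge", center = 956,
                    window_low = 952, window_high = 960)
  expect_error(peak_occurrence(list(set), off, sigma = 1e-5, n_per_roi = n),
               "trimmed grid")
  expect_error(peak_occurrence(list(set), bands[0, ], sigma = 1e-5,
                               n_per_roi = n), "empty")
})

test_that("a partially expressed band shows binomial occurrence at its presence probability", {
  cfg <- single_band_config(center = 1238, fwhm = 20, amplitude = 0.5,
                            presence = 0.5, noise_sd = 0.02, cv = 0.15,
                            height = 32, width = 32)
  sets <- list(); sig <- numeric(0)
  for (r in 1:6) {
    cube <- simulate_cube(cfg, "kidney", "FFPE", roi_id = r, seed = 100 + r)
    # the generator's own mask: Otsu at the band's wavenumber would select
    # only the pixels expressing the half-present band
    mask <- attr(cube, "tissue_mask")
    bs <- background_stats(cube, mask)
    sets[[r]] <- sample_pixels(cube, mask, 150, seed = r, correct = FALSE)
    sig[r] <- bs$sigma_pixel
  }
  bands <- data.frame(assignment = "test", center = 1238,
                      window_low = 1226, window_high = 1250)
  occ <- peak_occurrence(sets, bands, sig, n_per_roi = 100, seed = 3,
                         correct = TRUE)
  # pooled occurrence across the 6 ROIs inside the 95% binomial band of 0.5
  expect_gte(sum(occ), qbinom(0.025, 600, 0.5))
  expect_lte(sum(occ), qbinom(0.975, 600, 0.5))
})

test_that("consistent-band counting applies the median rule and handles empties", {
  counts <- matrix(c(90, 95, 88,   # clearly consistent
                     50, 50, 49,   # median exactly at threshold
                     10, 60, 20),  # median below threshold
                   nrow = 3, byrow = TRUE)
  occ <- structure(counts, n_per_roi = 100,
                   class = c("occurrence_table", "matrix"))
  expect_equal(count_consistent_bands(occ), 2)
  expect_equal(count_consistent_bands(occ, min_fraction = 0.9), 1)
  expect_equal(count_consistent_bands(occ[0, , drop = FALSE]), 0)
  expect_equal(count_consistent_bands(NULL), 0)
})

test_that("Gaussian sub-band fitting recovers generator parameters", {
  g <- default_grid()
  wn <- g$values
  y1 <- exp(-4 * log(2) * (wn - 1658)^2 / 20^2)
  f1 <- fit_gaussian_subbands(new_spectrum(g, y1), 1658)
  expect_true(f1$converged)
  expect_equal(f1$bands$amplitude, 1, tolerance = 0.01)
  expect_equal(f1$bands$fwhm, 20, tolerance = 0.01)
  expect_equal(f1$bands$center, 1658, tolerance = 0.01)
  expect_lt(f1$residual_rms, 1e-6)

  # two overlapping bands 20 cm-1 apart
  y2 <- 0.8 * exp(-4 * log(2) * (wn - 1530)^2 / 20^2) +
    0.5 * exp(-4 * log(2) * (wn - 1550)^2 / 20^2)
  f2 <- fit_gaussian_subbands(new_spectrum(g, y2), c(1530, 1550))
  expect_true(f2$converged)
  expect_equal(sort(f2$bands$amplitude), c(0.5, 0.8), tolerance = 0.05)

  expect_error(fit_gaussian_subbands(new_spectrum(g, y1), numeric(0)), "empty")
})

test_that("composite Simpson matches analytic integrals and the even-count rule", {
  x <- seq(0, 24, by = 2)  # 13 points
  expect_equal(composite_simpson(x, rep(1, 13)), 24)
  expect_equal(composite_simpson(x, x^2), 24^3 / 3)
  expect_equal(composite_simpson(x, x^3 - 2 * x^2 + 5), 24^4 / 4 - 2 * 24^3 / 3 + 5 * 24)

  # even point count: Simpson over the first n-1 points plus one trapezoid
  x2 <- seq(0, 26, by = 2)  # 14 points
  y2 <- x2^2
  expected <- 24^3 / 3 + (24^2 + 26^2) / 2 * 2  # exact Simpson + trapezoid tail
  expect_equal(composite_simpson(x2, y2), expected)
  expect_equal(composite_simpson(c(0, 2), c(3, 5)), 8)  # pure trapezoid
  expect_error(composite_simpson(c(0, 1, 3), c(1, 1, 1)), "evenly spaced")
})

test_that("band integrals respect windows and reject out-of-grid requests", {
  g <- default_grid()
  s <- new_spectrum(g, rep(1, 426))
  amide <- list(window_low = 1646, window_high = 1670)
  expect_equal(band_integral(s, amide), 24)
  expect_error(band_integral(s, list(window_low = 900, window_high = 1000)),
               "outside")
  gauss <- new_spectrum(g, exp(-4 * log(2) * (g$values - 1400)^2 / 20^2))
  got <- band_integral(gauss, list(window_low = 1340, window_high = 1460))
  expect_equal(got, gaussian_area(1, 20), tolerance = 0.005)
})

test_that("percent reduction is plain arithmetic with a guarded denominator", {
  expect_equal(percent_reduction(3, 1), 100 * 2 / 3)
  expect_equal(percent_reduction(7.7, 7.7), 0)
  expect_equal(percent_reduction(2, 3), -50)
  expect_error(percent_reduction(0, 1), "positive")
  expect_error(percent_reduction(-1, 1), "positive")
})

test_that("second-derivative integration mode integrates the negated derivative", {
  g <- default_grid()
  y <- 0.9 * exp(-4 * log(2) * (g$values - 1400)^2 / 30^2)
  s <- new_spectrum(g, y)
  bands <- data.frame(assignment = "x", center = 1400,
                      window_low = 1388, window_high = 1412)
  ints <- roi_band_integrals(list(s), bands, mode = "second_derivative")
  d <- second_derivative(s)
  expect_equal(unname(ints[1, 1]),
               band_integral(new_spectrum(d$grid, -d$absorbance), bands[1, ]))
  expect_gt(ints[1, 1], 0)
})
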