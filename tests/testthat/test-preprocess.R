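test_that("Otsu threshold separates bimodal data and matches the exhaustive oracle", {
  v <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0)
  expect_lte(thr, 10)
  expect_true(any(v <= thr) && any(v > thr))

  v2 <- c(1, 1, 2, 2, 9, 9, 10, 10)
  thr2 <- otsu_threshold(v2)
  oracle <- brute_force_otsu(v2)
  expect_identical(v2 > thr2, v2 > oracle)

  expect_error(otsu_threshold(rep(3, 10)), "distinct")
})

test_that("Otsu partitions of random images match the exhaustive oracle", {
  set.seed(42)
  for (i in 1:30) {
    v <- c(rnorm(40, mean = 0), rnorm(40, mean = sample(3:8, 1)))
    expect_identical(v > otsu_threshold(v), v > brute_force_otsu(v),
                     label = paste("image", i))
  }
})

test_that("Otsu threshold is translation-equivariant", {
  set.seed(1)
  v <- c(rnorm(100), rnorm(100, 6))
  expect_equal(otsu_threshold(v + 3.7), otsu_threshold(v) + 3.7,
               tolerance = 1e-9)
})

test_that("tissue segmentation recovers the generator mask", {
  # noise-free: exact recovery
  cfg0 <- single_band_config(center = 1608, fwhm = 20, amplitude = 1)
  cube0 <- simulate_cube(cfg0, "kidney", "FF", seed = 2)
  tm0 <- tissue_mask(cube0, mask_band = 1608)
  expect_identical(tm0$mask, matrix(as.vector(attr(cube0, "tissue_mask")),
                                    nrow(tm0$mask)))

  # default SNR: near-exact recovery
  cube <- simulate_cube(tiny_config(), "kidney", "FF", seed = 3)
  tm <- tissue_mask(cube)
  gen <- attr(cube, "tissue_mask")
  jac <- sum(tm$mask & gen) / sum(tm$mask | gen)
  expect_gte(jac, 0.95)
  # mask and background partition the pixel set exactly
  expect_equal(sum(tm$mask) + sum(!tm$mask), length(gen))

  flat <- new_cube(array(1, c(8, 8, length(small_grid()$values))),
                   small_grid(), "kidney", "FF", 1)
  expect_error(tissue_mask(flat, mask_band = 1000), "distinct")
})

test_that("nearest grid point is used for an off-grid mask band, with a message", {
  cube <- simulate_cube(single_band_config(center = 1608, amplitude = 1),
                        "kidney", "FF", seed = 2)
  expect_message(tm <- tissue_mask(cube, mask_band = 1607.3), "nearest")
  expect_equal(tm$mask_band, 1608)
})

test_that("background noise calibration is exact on polynomial backgrounds", {
  g <- default_grid()
  B <- length(g$values)
  k <- seq_len(B)
  # constant background: second derivative is identically zero
  data <- array(rep(2.5, 16 * 16 * B), c(16, 16, B))
  data[1:8, , ] <- 5  # "tissue" half
  cube <- new_cube(data, g, "kidney", "FF", 1)
  mask <- matrix(FALSE, 16, 16); mask[1:8, ] <- TRUE
  bs <- background_stats(cube, mask)
  expect_equal(bs$sigma, 0, tolerance = 1e-12)
  expect_equal(bs$n_background_pixels, 128)
  expect_equal(bs$background_spectrum$absorbance, rep(2.5, B))

  # quadratic background: order-2 Savitzky-Golay reproduces it exactly,
  # so the second derivative is constant and sigma is zero
  quad <- 0.3 + 0.01 * k + 0.002 * k^2
  data2 <- array(rep(quad, each = 16 * 16), c(16, 16, B))
  data2[1:8, , ] <- data2[1:8, , ] + 1
  cube2 <- new_cube(data2, g, "kidney", "FF", 1)
  bs2 <- background_stats(cube2, mask)
  expect_equal(bs2$sigma, 0, tolerance = 1e-9)

  expect_error(background_stats(cube, matrix(TRUE, 16, 16)), "background")
})

test_that("sigma rises strictly with the generator noise level", {
  sig_at <- function(noise, seed) {
    cfg <- tiny_config(noise_sd = noise)
    cube <- simulate_cube(cfg, "kidney", "FF", seed = seed)
    background_stats(cube, attr(cube, "tissue_mask"))$sigma
  }
  for (seed in 1:5) {
    s <- vapply(c(0.01, 0.02, 0.04), sig_at, 0, seed = seed)
    expect_true(all(diff(s) > 0), label = paste("seed", seed))
  }
})

test_that("sigma matches the known additive-noise-only level on synthetic cubes", {
  cfg <- tiny_config()
  ratios <- vapply(1:10, function(seed) {
    cube <- simulate_cube(cfg, "kidney", "FF", seed = seed)
    mask <- attr(cube, "tissue_mask")
    bs <- background_stats(cube, mask)
    # oracle: strip the known deterministic baseline from the background
    # mean, leaving the pure mean-noise spectrum
    wn <- cfg$grid$values
    bl <- cfg$baseline$kidney_FF
    base <- bl$offset + bl$slope * (wn - cfg$grid$start) +
      bl$curvature_amplitude *
        exp(-4 * log(2) * (wn - cfg$baseline_bump_center)^2 /
              cfg$baseline_bump_fwhm^2)
    noise_mean <- bs$background_spectrum$absorbance - base
    d <- mirspec:::sg_second_derivative(matrix(noise_mean, 1), cfg$grid$step)
    bs$sigma / sd(as.vector(d))
  }, 0)
  expect_true(all(ratios > 0.85 & ratios < 1.15))
})

test_that("rubberband correction zeroes affine and convex spectra", {
  g <- small_grid()
  wn <- g$values
  lin <- new_spectrum(g, 0.2 + 0.003 * wn)
  r <- rubberband_correct(lin)
  expect_equal(r$corrected$absorbance, rep(0, length(wn)), tolerance = 1e-9)

  cvx <- new_spectrum(g, exp((wn - 950) / 40))
  r2 <- rubberband_correct(cvx)
  expect_equal(r2$corrected$absorbance, rep(0, length(wn)), tolerance = 1e-9)
})

test_that("rubberband recovers a Gaussian peak on a sloped offset", {
  g <- default_grid()
  wn <- g$values
  y <- exp(-4 * log(2) * (wn - 1400)^2 / 30^2) + 0.5 + 0.001 * wn
  r <- rubberband_correct(new_spectrum(g, y))
  expect_equal(max(r$corrected$absorbance), 1, tolerance = 0.01)
  expect_gte(min(r$corrected$absorbance), -1e-9)
  expect_equal(r$corrected$absorbance[1], 0)
  expect_equal(r$corrected$absorbance[length(wn)], 0)
  expect_equal(r$baseline$absorbance + r$corrected$absorbance, y)
})

test_that("rubberband equals the all-chords hull oracle on random spectra", {
  set.seed(7)
  g <- make_grid(0, 39, 1)
  for (i in 1:40) {
    y <- cumsum(rnorm(40)) + 0.05 * (seq_len(40) - 20)^2 * runif(1)
    got <- rubberband_correct(new_spectrum(g, y))$baseline$absorbance
    expect_equal(got, brute_force_rubberband(g$values, y), tolerance = 1e-9,
                 label = paste("spectrum", i))
  }
})

test_that("rubberband output is invariant to adding any linear function", {
  set.seed(8)
  g <- small_grid()
  for (i in 1:10) {
    y <- abs(rnorm(length(g$values))) + sin(seq_len(length(g$values)) / 3)
    a <- rnorm(1); b <- rnorm(1, sd = 0.01)
    c1 <- rubberband_correct(new_spectrum(g, y))$corrected$absorbance
    c2 <- rubberband_correct(new_spectrum(g, y + a + b * g$values))$corrected$absorbance
    expect_equal(c1, c2, tolerance = 1e-9)
  }
})

test_that("pixel sampling is seeded, exhaustive at full n, and bounded by tissue count", {
  cube <- simulate_cube(tiny_config(), "liver", "FF", seed = 9)
  tm <- tissue_mask(cube)
  n_tissue <- sum(tm$mask)

  s1 <- sample_pixels(cube, tm$mask, 200, seed = 5, correct = FALSE)
  s2 <- sample_pixels(cube, tm$mask, 200, seed = 5, correct = FALSE)
  expect_identical(s1$pixel_ids, s2$pixel_ids)
  expect_identical(s1$matrix, s2$matrix)
  expect_equal(nrow(s1$matrix), 200)

  full <- sample_pixels(cube, tm$mask, n_tissue, seed = 1, correct = FALSE)
  expect_equal(nrow(full$matrix), n_tissue)
  H <- dim(cube$data)[1]
  expect_setequal((full$pixel_ids$col - 1) * H + full$pixel_ids$row,
                  which(as.vector(tm$mask)))

  err <- tryCatch(sample_pixels(cube, tm$mask, n_tissue + 1, seed = 1),
                  error = conditionMessage)
  expect_match(err, as.character(n_tissue + 1))
  expect_match(err, as.character(n_tissue))

  corr <- sample_pixels(cube, tm$mask, 20, seed = 2, correct = TRUE)
  expect_gte(min(corr$matrix), -1e-9)
})
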