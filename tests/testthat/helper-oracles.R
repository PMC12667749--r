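# Independent oracles and small fixture factories shared across the suite.

# Exhaustive Otsu: try the midpoint between every adjacent pair of sorted
# unique values and maximize the between-class variance directly.
brute_force_otsu <- function(values) {
  u <- sort(unique(values))
  cuts <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cuts, function(t) {
    a <- values[values <= t]; b <- values[values > t]
    (length(a) / length(values)) * (length(b) / length(values)) *
      (mean(a) - mean(b))^2
  }, 0)
  cuts[which.max(bcv)]
}

# O(n^2)-per-point lower convex hull: the hull value at x_i is the minimum
# over all chords between data points spanning x_i (no chord passes under
# the hull, and the active hull segment is itself such a chord).
brute_force_rubberband <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- y[i]
    for (j in seq_len(i)) {
      k <- i:n
      k <- k[k > j]
      if (length(k) == 0) next
      chord <- ((x[k] - x[i]) * y[j] + (x[i] - x[j]) * y[k]) / (x[k] - x[j])
      best <- min(best, chord)
    }
    out[i] <- best
  }
  out
}

# Closed-form area of a Gaussian band A * exp(-4 ln2 (v - c)^2 / fwhm^2).
gaussian_area <- function(amplitude, fwhm) {
  amplitude * fwhm * sqrt(pi / log(16))
}

# Small grid for fast unit tests (46 points).
small_grid <- function() make_grid(950, 1040, 2)

# Random cube on a small grid for serialization tests.
random_cube <- function(seed = 1, h = 8, w = 8, grid = small_grid()) {
  set.seed(seed)
  new_cube(array(rnorm(h * w * length(grid$values)),
                 dim = c(h, w, length(grid$values))),
           grid, tissue = "kidney", prep = "FF", roi_id = "rand")
}

# Desk-scale generator config for pipeline tests: smaller cubes, same
# spectral structure.
tiny_config <- function(...) default_config(height = 32, width = 32, ...)

# Single-band noise-free configuration on the default grid: one Gaussian,
# flat zero baseline, no envelope, no spatial amplitude variation.
single_band_config <- function(center = 1658, fwhm = 20, amplitude = 1,
                               presence = 1, noise_sd = 0, cv = 0,
                               height = 16, width = 16) {
  cfg <- default_config(height = height, width = width,
                        amplitude_field_cv = cv, noise_sd = noise_sd)
  one <- data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
                    presence_prob = presence)
  cfg$band_tables <- lapply(cfg$band_tables, function(b) one)
  zero <- list(offset = 0, slope = 0, curvature_amplitude = 0)
  cfg$baseline <- lapply(cfg$baseline, function(b) zero)
  cfg$envelope_amplitude[] <- 0
  cfg
}
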