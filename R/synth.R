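#' Deterministic seed derivation
#'
#' Fans a master seed out to per-stage / per-ROI seeds via a small
#' counter-based hash, so that independent stages get independent but fully
#' reproducible RNG streams. All derived seeds stay below 2^31.
#'
#' @param seed Master seed (integer).
#' @param ... Integer counters (stage index, class index, ROI index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  acc <- 17
  for (p in parts) acc <- (acc * 48271 + p * 9973 + 1) %% 2147483629
  as.integer(acc)
}

gaussian_band <- function(wn, center, fwhm, amplitude = 1) {
  amplitude * exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
}

band_specs <- function(center, fwhm, amplitude, presence_prob = 1) {
  data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
             presence_prob = presence_prob)
}

#' Default synthetic-study generator configuration
#'
#' Parameterizes four tissue/preparation classes with Gaussian band
#' structure over the fingerprint region:
#'
#' * kidney-FF: 13 bands (966, 1035, 1082, 1168, 1238, 1308, 1400, 1448,
#'   1462, 1516, 1546, 1658, 1744 cm^-1);
#' * liver-FF: 13 bands (glycogen 1030 and 1154 replacing DNA 1035 and
#'   protein 1168);
#' * kidney-FFPE: 8 bands (1026, 1238, 1400, 1448, 1516, 1546, 1658, 1744),
#'   the 1026 cm^-1 formalin artifact expressed in a subset of pixels;
#' * liver-FFPE: 7 bands (as kidney-FFPE without 1516), 1026 expressed in
#'   every tissue pixel.
#'
#' The amide absorption is modeled as a sharp Amide I Gaussian (1658
#' cm^-1, fwhm 40, FF amplitude 0.80) riding on a broad tissue absorption
#' envelope (same center, fwhm 600, FF amplitude 0.25) that provides the
#' image contrast used for Otsu masking at 1608 cm^-1; together they put
#' the single-pixel Amide I SNR near 50 at `noise_sd = 0.02`. Both amide
#' components are attenuated in FFPE to `0.337x` (kidney) and `0.538x`
#' (liver) their FF amplitude, i.e. Amide I band integrals drop by 66.3%
#' and 46.2%. Amide II (1546) is 0.6; remaining bands are 0.25-0.35 with
#' fwhm 20 (14 for the narrow 1448/1462 CH2/CH3 bending doublet, which
#' would otherwise merge in second-derivative analysis). The scattering
#' baseline is an offset plus linear slope plus one broad (fwhm 700
#' cm^-1) Gaussian bump; per-pixel band amplitudes ride on a smooth
#' spatial field with mean 1 and CV 0.15.
#'
#' @param grid Wavenumber grid (default [default_grid()]).
#' @param height,width Cube size in pixels (desk-scale default 64 x 64).
#' @param tissue_fraction Target on-tissue pixel fraction (default 0.7).
#' @param amplitude_field_cv Coefficient of variation of the smooth
#'   per-pixel amplitude field (default 0.15).
#' @param noise_sd Additive white detector noise, absorbance units
#'   (default 0.02).
#' @param seed Default master seed recorded in the config.
#' @return An object of class `mirsi_config`.
#' @export
default_config <- function(grid = default_grid(), height = 64, width = 64,
                           tissue_fraction = 0.7, amplitude_field_cv = 0.15,
                           noise_sd = 0.02, seed = 1L) {
  amide1 <- list(center = 1658, fwhm = 40, amplitude = 0.80)
  amide1_attenuation <- c(kidney = 0.337, liver = 0.538)
  common <- rbind(
    band_specs(1238, 20, 0.35),  # Amide III
    band_specs(1400, 20, 0.35),  # protein COO-
    band_specs(1448, 14, 0.32),  # CH2/CH3 bending doublet (narrow)
    band_specs(1546, 20, 0.60)   # Amide II
  )
  ff_extra <- rbind(
    band_specs(966, 20, 0.25),   # DNA
    band_specs(1082, 20, 0.32),  # DNA PO2-
    band_specs(1308, 20, 0.28),  # Amide III
    band_specs(1462, 14, 0.34),  # lipid CH2 (doublet interference with 1448
                                 # shaves its derivative dip; amplitude set so
                                 # the effective dip clears 8 sigma per pixel)
    band_specs(1516, 20, 0.35),  # Amide II shoulder
    band_specs(1744, 20, 0.35)   # lipid C=O ester
  )
  ff_bands <- function(tissue_specific) {
    b <- rbind(common, ff_extra, tissue_specific,
               band_specs(amide1$center, amide1$fwhm, amide1$amplitude))
    b[order(b$center), ]
  }
  # 1035 sits off the even-wavenumber grid, which costs its dip one grid
  # point of the +/-2 cm-1 matching window; a deeper dip keeps per-pixel
  # localization above the recovery requirement
  kidney_dna <- band_specs(1035, 20, 0.38)
  ffpe_bands <- function(tissue) {
    keep <- rbind(common,
                  band_specs(1744, 20, 0.35),
                  if (tissue == "kidney") band_specs(1516, 20, 0.35),
                  band_specs(1026, 20, 0.30,
                             presence_prob = if (tissue == "kidney") 0.65 else 1.0),
                  band_specs(amide1$center, amide1$fwhm,
                             amide1$amplitude * amide1_attenuation[[tissue]]))
    keep[order(keep$center), ]
  }
  band_tables <- list(
    kidney_FF = ff_bands(rbind(kidney_dna,
                               band_specs(1168, 20, 0.25))),
    kidney_FFPE = ffpe_bands("kidney"),
    liver_FF = ff_bands(rbind(band_specs(1030, 20, 0.30),
                              band_specs(1154, 20, 0.25))),
    liver_FFPE = ffpe_bands("liver")
  )
  band_tables <- lapply(band_tables, function(b) { rownames(b) <- NULL; b })
  baseline_one <- list(offset = 0.05, slope = 1e-4, curvature_amplitude = 0.05)
  # Broad tissue absorption envelope centered on the amide complex: carries
  # the image contrast that lets Otsu segmentation work at 1608 cm-1 (sharp
  # bands alone leave that flank near the noise floor). Attenuated in FFPE
  # by the same factor as Amide I, so windowed integral ratios are
  # preserved. Total peak absorbance at 1658 is 0.80 + 0.25, putting the
  # single-pixel Amide I SNR at ~52 for noise_sd 0.02.
  env_amp <- 0.25
  envelope_amplitude <- c(kidney_FF = env_amp,
                          kidney_FFPE = env_amp * amide1_attenuation[["kidney"]],
                          liver_FF = env_amp,
                          liver_FFPE = env_amp * amide1_attenuation[["liver"]])
  config <- structure(list(
    grid = grid,
    height = height, width = width,
    band_tables = band_tables,
    baseline = list(kidney_FF = baseline_one, kidney_FFPE = baseline_one,
                    liver_FF = baseline_one, liver_FFPE = baseline_one),
    baseline_bump_center = 1100, baseline_bump_fwhm = 700,
    envelope_center = 1658, envelope_fwhm = 600,
    envelope_amplitude = envelope_amplitude,
    amplitude_field_cv = amplitude_field_cv,
    noise_sd = noise_sd,
    tissue_fraction = tissue_fraction,
    amide1_attenuation = amide1_attenuation,
    seed = as.integer(seed)
  ), class = "mirsi_config")
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  stopifnot(inherits(config, "mirsi_config"))
  if (config$noise_sd < 0) stop("noise_sd must be >= 0")
  if (config$tissue_fraction <= 0 || config$tissue_fraction >= 1) {
    stop("tissue_fraction must lie strictly between 0 and 1")
  }
  for (key in names(config$band_tables)) {
    b <- config$band_tables[[key]]
    if (any(b$center < config$grid$start | b$center > config$grid$stop)) {
      stop("band center outside grid in class ", key)
    }
    if (any(b$fwhm <= 0) || any(b$amplitude < 0) ||
        any(b$presence_prob < 0 | b$presence_prob > 1)) {
      stop("invalid band spec in class ", key)
    }
  }
  invisible(config)
}

#' @export
print.mirsi_config <- function(x, ...) {
  cat(sprintf("<mirsi_config> %dx%d px cubes, grid %g-%g cm-1, noise_sd %g\n",
              x$height, x$width, x$grid$start, x$grid$stop, x$noise_sd))
  for (key in names(x$band_tables)) {
    cat(sprintf("  %-12s %2d bands\n", key, nrow(x$band_tables[[key]])))
  }
  invisible(x)
}

# White noise blurred with a separable Gaussian kernel (row-normalized so
# edge pixels keep comparable variance).
blurred_field <- function(height, width, smooth_sigma) {
  z <- matrix(stats::rnorm(height * width), height, width)
  k <- function(n) {
    idx <- seq_len(n)
    m <- exp(-outer(idx, idx, function(i, j) (i - j)^2) / (2 * smooth_sigma^2))
    m / rowSums(m)
  }
  k(height) %*% z %*% t(k(width))
}

# Smooth multiplicative amplitude field, standardized to the requested mean
# and coefficient of variation (clipped at zero; at CV 0.15 clipping is a
# > 6-sigma event and never observed in practice).
smooth_field <- function(height, width, smooth_sigma, mean = 1, cv = 0) {
  if (cv <= 0) return(matrix(mean, height, width))
  f <- blurred_field(height, width, smooth_sigma)
  pmax(mean * (1 + cv * (f - base::mean(f)) / stats::sd(f)), 0)
}

#' Generate a smooth synthetic tissue mask
#'
#' Thresholds a smoothed Gaussian random field at the quantile matching the
#' requested on-tissue fraction, producing smooth connected blob(s).
#' Deterministic for a fixed seed. The achieved fraction (exact up to the
#' pixel-count granularity) is attached as attribute `achieved_fraction`.
#'
#' @param height,width Mask size in pixels.
#' @param tissue_fraction Target fraction of on-tissue pixels, in (0, 1).
#' @param seed Integer seed.
#' @param smooth_sigma Blur scale of the underlying field (pixels).
#' @return Logical `height x width` matrix; `TRUE` marks tissue.
#' @export
make_tissue_mask <- function(height, width, tissue_fraction, seed,
                             smooth_sigma = 8) {
  if (tissue_fraction <= 0 || tissue_fraction >= 1) {
    stop("tissue_fraction must lie strictly between 0 and 1")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- blurred_field(height, width, smooth_sigma)
  n <- height * width
  n_on <- min(max(round(tissue_fraction * n), 1L), n - 1L)
  thr <- sort(f, decreasing = TRUE)[n_on]
  mask <- f >= thr
  # ties at the threshold can overshoot; trim deterministically
  if (sum(mask) > n_on) {
    extra <- which(mask & f == thr)
    mask[extra[seq_len(sum(mask) - n_on)]] <- FALSE
  }
  attr(mask, "achieved_fraction") <- sum(mask) / n
  mask
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one hyperspectral ROI cube
#'
#' Per-pixel model: `baseline(v) + a(pixel) * sum_b present_b(pixel) *
#' A_b exp(-4 ln2 (v - c_b)^2 / fwhm_b^2) + noise` on tissue pixels, and
#' `baseline(v) + noise` off tissue. `a` is a smooth spatial amplitude field
#' with mean 1 and the configured CV; per-pixel band presence is Bernoulli
#' in each band's `presence_prob`; noise is additive white Gaussian,
#' identical on and off tissue. Fully reproducible for a fixed seed.
#'
#' @param config A `mirsi_config`.
#' @param tissue,prep Class to simulate.
#' @param roi_id ROI identifier stored in the cube.
#' @param seed Integer seed.
#' @return A `mir_cube` with the generator's tissue mask attached as
#'   attribute `tissue_mask` and the amplitude field as `amplitude_field`.
#' @export
simulate_cube <- function(config, tissue, prep, roi_id = 1L,
                          seed = config$seed) {
  validate_generator_config(config)
  key <- class_key(tissue, prep)
  if (!key %in% names(config$band_tables)) {
    stop("class ", key, " not present in config$band_tables")
  }
  bands <- config$band_tables[[key]]
  wn <- config$grid$values
  H <- config$height; W <- config$width; B <- length(wn)
  n_pix <- H * W

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  mask <- make_tissue_mask(H, W, config$tissue_fraction, derive_seed(seed, 1))
  set.seed(derive_seed(seed, 2))
  field <- smooth_field(H, W, smooth_sigma = 8, mean = 1,
                        cv = config$amplitude_field_cv)
  bl <- config$baseline[[key]]
  baseline <- bl$offset + bl$slope * (wn - config$grid$start) +
    bl$curvature_amplitude *
      gaussian_band(wn, config$baseline_bump_center, config$baseline_bump_fwhm)

  env <- if (!is.null(config$envelope_amplitude)) {
    config$envelope_amplitude[[key]] *
      gaussian_band(wn, config$envelope_center, config$envelope_fwhm)
  } else rep(0, B)

  # coefficient matrix (pixels x bands) times band shapes (bands x wavenumbers)
  pres <- matrix(0, n_pix, nrow(bands))
  on_idx <- which(as.vector(mask))
  for (j in seq_len(nrow(bands))) {
    p <- bands$presence_prob[j]
    pres[on_idx, j] <- if (p >= 1) 1 else stats::rbinom(length(on_idx), 1, p)
  }
  coefs <- pres * as.vector(field) # recycles field over columns
  coefs <- sweep(coefs, 2, bands$amplitude, `*`)
  shapes <- t(vapply(seq_len(nrow(bands)),
                     function(j) gaussian_band(wn, bands$center[j], bands$fwhm[j]),
                     numeric(B)))
  spectra <- coefs %*% shapes
  on_field <- as.vector(field) * (as.vector(mask))
  spectra <- spectra + on_field %o% env
  spectra <- sweep(spectra, 2, baseline, `+`)
  if (config$noise_sd > 0) {
    spectra <- spectra + matrix(stats::rnorm(n_pix * B, sd = config$noise_sd),
                                n_pix, B)
  }
  cube <- new_cube(array(spectra, dim = c(H, W, B)), config$grid,
                   tissue = tissue, prep = prep, roi_id = roi_id)
  attr(cube, "tissue_mask") <- mask
  attr(cube, "amplitude_field") <- field
  cube
}

#' Simulate a full multi-ROI study
#'
#' Generates `rois_per_class` cubes for each of the four tissue/preparation
#' classes, with ROI-level seeds derived deterministically from
#' `(seed, class index, ROI index)`.
#'
#' @param config A `mirsi_config`.
#' @param rois_per_class Number of ROIs per class (study default 8).
#' @param seed Master seed.
#' @param classes Optional data.frame of classes to simulate (columns
#'   `tissue`, `prep`); defaults to all four.
#' @return Named list of `mir_cube`s (`<tissue>_<prep>_roi<i>`), with a
#'   manifest data.frame attached as attribute `manifest`.
#' @export
simulate_study <- function(config, rois_per_class = 8, seed = config$seed,
                           classes = study_classes()) {
  stopifnot(rois_per_class >= 1)
  cubes <- list()
  manifest <- NULL
  for (ci in seq_len(nrow(classes))) {
    tissue <- classes$tissue[ci]; prep <- classes$prep[ci]
    for (r in seq_len(rois_per_class)) {
      roi_seed <- derive_seed(seed, 100, ci, r)
      id <- sprintf("%s_roi%d", class_key(tissue, prep), r)
      cubes[[id]] <- simulate_cube(config, tissue, prep, roi_id = id,
                                   seed = roi_seed)
      manifest <- rbind(manifest,
                        data.frame(key = id, tissue = tissue, prep = prep,
                                   roi = r, seed = roi_seed))
    }
  }
  attr(cubes, "manifest") <- manifest
  cubes
}

#' Write / read a generator configuration as JSON
#'
#' Serializes everything except the grid object itself (stored as
#' start/stop/step) so configurations can be archived with a run.
#'
#' @param config A `mirsi_config`.
#' @param path JSON file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns a `mirsi_config`.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  payload <- config
  payload$grid <- list(start = config$grid$start, stop = config$grid$stop,
                       step = config$grid$step)
  # named atomic vectors lose their names as JSON arrays; store as objects
  payload$envelope_amplitude <- as.list(config$envelope_amplitude)
  payload$amide1_attenuation <- as.list(config$amide1_attenuation)
  jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$grid <- make_grid(p$grid$start, p$grid$stop, p$grid$step)
  p$band_tables <- lapply(p$band_tables, as.data.frame)
  p$envelope_amplitude <- unlist(p$envelope_amplitude)
  p$amide1_attenuation <- unlist(p$amide1_attenuation)
  p$seed <- as.integer(p$seed)
  config <- structure(p, class = "mirsi_config")
  validate_generator_config(config)
  config
}
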