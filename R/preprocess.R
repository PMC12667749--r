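#' Otsu threshold of an intensity sample
#'
#' Classic histogram Otsu: builds a 256-bin histogram spanning
#' `[min(values), max(values)]` and returns the cut maximizing the
#' between-class variance. When several cuts tie (flat plateaus between
#' well-separated modes) the middle of the optimal run is taken, so the
#' threshold is deterministic and translation-equivariant.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Histogram resolution (default 256).
#' @return A single threshold; pixels with intensity strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || min(values) == max(values)) {
    stop("Otsu threshold undefined: need at least two distinct finite values")
  }
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / n_bins
  bin <- pmin(pmax(floor((values - lo) / width) + 1, 1), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(counts)
  total <- w0[n_bins]
  sum0 <- cumsum(counts * mids)
  mu_total <- sum0[n_bins] / total
  w1 <- total - w0
  # between-class variance for a cut after bin t
  valid <- w0 > 0 & w1 > 0
  mu0 <- sum0 / w0
  mu1 <- (sum0[n_bins] - sum0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which(bcv == max(bcv))
  t_star <- best[ceiling(length(best) / 2)]
  lo + t_star * width  # upper edge of the optimal bin
}

#' Tissue/background segmentation of a cube
#'
#' Thresholds the single-band image at the requested wavenumber (the strong
#' Amide I flank at 1608 cm^-1 by default) with [otsu_threshold()]. The
#' nearest grid point is used (with a message when not exact); tissue pixels
#' are those above the threshold.
#'
#' @param cube A `mir_cube`.
#' @param mask_band Wavenumber of the masking image (default 1608 cm^-1).
#' @return A list of class `tissue_mask`: `mask` (logical H x W, TRUE =
#'   tissue), `threshold`, `band_image`, and `mask_band` (the grid
#'   wavenumber actually used).
#' @export
tissue_mask <- function(cube, mask_band = 1608) {
  stopifnot(inherits(cube, "mir_cube"))
  idx <- grid_index(cube$grid, mask_band)
  used <- cube$grid$values[idx]
  if (used != mask_band) {
    message("mask band ", mask_band, " cm-1 not on grid; using nearest point ",
            used, " cm-1")
  }
  img <- cube$data[, , idx]
  thr <- otsu_threshold(as.vector(img))
  mask <- img > thr
  if (!any(mask) || all(mask)) {
    stop("degenerate segmentation at ", used,
         " cm-1: tissue and background must both be non-empty")
  }
  structure(list(mask = mask, threshold = thr, band_image = img,
                 mask_band = used), class = "tissue_mask")
}

#' Background spectrum and noise calibration
#'
#' The mean of the off-tissue pixels is the background spectrum. Its
#' Savitzky-Golay second derivative (edge-trimmed exactly as in the
#' downstream peak analysis, so the noise reference and the peak test live
#' on the same support) gives `sigma`, the noise scale of spectra at the
#' background-mean averaging level. `sigma_pixel` is the matching scale for
#' a single pixel spectrum: the pooled standard deviation of the individual
#' off-tissue second derivatives about their mean. Significance tests must
#' use the scale whose averaging level matches the tested spectrum
#' (`sigma` for ROI/class mean spectra, `sigma_pixel` for per-pixel calls).
#'
#' @param cube A `mir_cube`.
#' @param mask Logical tissue mask (`TRUE` = tissue), e.g.
#'   `tissue_mask(cube)$mask`.
#' @param params Savitzky-Golay/trimming parameters
#'   ([derivative_params()]).
#' @param mask_band Wavenumber used for the segmentation, carried through
#'   for provenance (optional).
#' @return A list of class `background_stats`: `background_spectrum`
#'   (`mir_spectrum`), `sigma`, `sigma_pixel`, `n_background_pixels`,
#'   `mask_band`.
#' @export
background_stats <- function(cube, mask, params = derivative_params(),
                             mask_band = NA) {
  stopifnot(inherits(cube, "mir_cube"), is.logical(mask))
  if (!identical(dim(mask), dim(cube$data)[1:2])) {
    stop("mask dimensions do not match the cube")
  }
  bg_idx <- which(!as.vector(mask))
  if (length(bg_idx) == 0) stop("no background pixels: cannot calibrate noise")
  mat <- cube_matrix(cube)[bg_idx, , drop = FALSE]
  bg_mean <- colMeans(mat)
  d_mean <- sg_second_derivative(matrix(bg_mean, nrow = 1),
                                 cube$grid$step, params)
  sigma <- stats::sd(as.vector(d_mean))
  d_all <- sg_second_derivative(mat, cube$grid$step, params)
  resid <- sweep(d_all, 2, colMeans(d_all))
  # robust (MAD) scale: a few percent of dim tissue pixels can leak through
  # the Otsu cut in low-contrast preparations, and their band structure
  # would inflate a plain standard deviation
  sigma_pixel <- if (nrow(mat) > 1) stats::mad(as.vector(resid)) else sigma
  structure(list(background_spectrum = new_spectrum(cube$grid, bg_mean),
                 sigma = sigma, sigma_pixel = sigma_pixel,
                 n_background_pixels = length(bg_idx), mask_band = mask_band),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf(
    "<background_stats> n=%d pixels, sigma=%.3g (mean level), sigma_pixel=%.3g\n",
    x$n_background_pixels, x$sigma, x$sigma_pixel))
  invisible(x)
}

# Indices of the lower convex hull of the point sequence (x ascending),
# Andrew's monotone chain. O(n).
lower_hull_indices <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      o <- stack[k - 1L]; a <- stack[k]
      # pop a while the turn o -> a -> i is not strictly right (clockwise)
      if ((x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o]) <= 0) {
        k <- k - 1L
      } else break
    }
    k <- k + 1L
    stack[k] <- i
  }
  stack[seq_len(k)]
}

rubberband_baseline_vec <- function(x, y) {
  idx <- lower_hull_indices(x, y)
  stats::approx(x[idx], y[idx], xout = x, method = "linear")$y
}

#' Rubberband baseline correction
#'
#' Subtracts the lower convex hull of the `(wavenumber, absorbance)` point
#' sequence, linearly interpolated between hull vertices and anchored at
#' both endpoints. Removes broad scattering backgrounds: any convex
#' spectrum (including any affine one) is corrected to exactly zero, and
#' adding a linear function of wavenumber to the input leaves the corrected
#' spectrum unchanged.
#'
#' @param spectrum A `mir_spectrum` (at least 3 points, finite values).
#' @return A list of class `baseline_result`: `baseline` and `corrected`,
#'   both `mir_spectrum`s, with `corrected = input - baseline` pointwise,
#'   non-negative (within 1e-9) and zero at both endpoints.
#' @export
rubberband_correct <- function(spectrum) {
  stopifnot(inherits(spectrum, "mir_spectrum"))
  y <- spectrum$absorbance
  if (length(y) < 3) stop("rubberband correction needs at least 3 points")
  base <- rubberband_baseline_vec(spectrum$grid$values, y)
  structure(list(baseline = new_spectrum(spectrum$grid, base),
                 corrected = new_spectrum(spectrum$grid, y - base)),
            class = "baseline_result")
}

# Row-wise rubberband correction of a spectra matrix.
rubberband_correct_matrix <- function(mat, wn) {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    out[i, ] <- mat[i, ] - rubberband_baseline_vec(wn, mat[i, ])
  }
  out
}

#' Randomly sample tissue pixel spectra from a cube
#'
#' Uniform sampling without replacement over the tissue pixels; each
#' sampled spectrum is rubberband-corrected before analysis (disable with
#' `correct = FALSE` when the downstream step corrects an averaged spectrum
#' instead).
#'
#' @param cube A `mir_cube`.
#' @param mask Logical tissue mask (`TRUE` = tissue).
#' @param n Number of pixels to draw; must not exceed the tissue pixel
#'   count.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param correct Rubberband-correct each sampled spectrum (default TRUE).
#' @return A `spectrum_set`.
#' @export
sample_pixels <- function(cube, mask, n, seed, correct = TRUE) {
  stopifnot(inherits(cube, "mir_cube"), is.logical(mask))
  tissue_idx <- which(as.vector(mask))
  if (n > length(tissue_idx)) {
    stop("requested ", n, " pixels but the mask holds only ",
         length(tissue_idx), " tissue pixels")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  take <- sort(sample(tissue_idx, n, replace = FALSE))
  H <- dim(cube$data)[1]
  mat <- cube_matrix(cube)[take, , drop = FALSE]
  if (correct) mat <- rubberband_correct_matrix(mat, cube$grid$values)
  spectrum_set(cube$grid, mat,
               pixel_ids = data.frame(row = (take - 1L) %% H + 1L,
                                      col = (take - 1L) %/% H + 1L),
               roi_id = cube$roi_id, tissue = cube$tissue, prep = cube$prep)
}
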