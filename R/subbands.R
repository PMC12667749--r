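#' Savitzky-Golay differentiation parameters
#'
#' Defaults follow the acquisition pipeline: window length 13 points,
#' polynomial order 2, and 26 spectral points trimmed in total to discard
#' filter edge effects. The trim is allocated asymmetrically: 6 points at
#' the low-wavenumber edge (the filter half-window, which is all the edge
#' actually corrupts) and 20 at the high edge, so that the lowest reference
#' band (DNA, 966 cm^-1) stays on the trimmed detection support - a
#' symmetric 13/13 split would silently exclude it.
#'
#' @param window_length Filter window in points (odd, `>= poly_order + 2`).
#' @param poly_order Fitted polynomial order.
#' @param trim_low,trim_high Points removed from the low/high wavenumber
#'   ends of the derivative.
#' @return An object of class `derivative_params`.
#' @export
derivative_params <- function(window_length = 13, poly_order = 2,
                              trim_low = 6, trim_high = 20) {
  if (window_length %% 2 != 1) stop("window_length must be odd, got ",
                                    window_length)
  if (window_length < poly_order + 2) {
    stop("window_length must be >= poly_order + 2")
  }
  if (trim_low < 0 || trim_high < 0) stop("trims must be non-negative")
  structure(list(window_length = as.integer(window_length),
                 poly_order = as.integer(poly_order),
                 trim_low = as.integer(trim_low),
                 trim_high = as.integer(trim_high)),
            class = "derivative_params")
}

# Savitzky-Golay second derivative of each row of `mat` (physical units,
# i.e. per cm^-2), trimmed. When both trims cover the filter half-window
# every retained point is an interior point, and the filter reduces to one
# matrix product with the central coefficient row; otherwise fall back to
# signal::sgolayfilt per row (its edge handling fits polynomials to the
# ends).
sg_second_derivative <- function(mat, step, params = derivative_params()) {
  stopifnot(is.matrix(mat))
  B <- ncol(mat)
  tl <- params$trim_low; th <- params$trim_high
  if (tl + th >= B) stop("trimming removes the whole spectrum (",
                         tl + th, " of ", B, " points)")
  keep <- (tl + 1):(B - th)
  hw <- (params$window_length - 1L) / 2L
  if (B < params$window_length) stop("spectrum shorter than the filter window")
  if (tl >= hw && th >= hw) {
    coefs <- as.matrix(signal::sgolay(p = params$poly_order,
                                      n = params$window_length,
                                      m = 2, ts = step))[hw + 1L, ]
    S <- matrix(0, B, length(keep))
    for (k in seq_len(params$window_length)) {
      S[cbind(keep - hw - 1L + k, seq_along(keep))] <- coefs[k]
    }
    mat %*% S
  } else {
    t(apply(mat, 1, function(y) {
      signal::sgolayfilt(y, p = params$poly_order, n = params$window_length,
                         m = 2, ts = step)[keep]
    }))
  }
}

trimmed_grid <- function(grid, params) {
  B <- length(grid$values)
  keep <- (params$trim_low + 1):(B - params$trim_high)
  make_grid(grid$values[keep[1]], grid$values[keep[length(keep)]], grid$step)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Returns the second derivative in physical units (absorbance per cm^-2)
#' on the edge-trimmed grid: with the 426-point default grid and default
#' parameters, 26 points are trimmed and 400 remain.
#'
#' @param x A `mir_spectrum` or `spectrum_set`.
#' @param params [derivative_params()].
#' @return Same class as `x`, on the trimmed grid.
#' @export
second_derivative <- function(x, params = derivative_params()) {
  UseMethod("second_derivative")
}

#' @export
second_derivative.mir_spectrum <- function(x, params = derivative_params()) {
  d <- sg_second_derivative(matrix(x$absorbance, nrow = 1), x$grid$step, params)
  new_spectrum(trimmed_grid(x$grid, params), as.vector(d))
}

#' @export
second_derivative.spectrum_set <- function(x, params = derivative_params()) {
  d <- sg_second_derivative(x$matrix, x$grid$step, params)
  spectrum_set(trimmed_grid(x$grid, params), d, x$pixel_ids, x$roi_id,
               x$tissue, x$prep)
}

# Strict-local-minimum mask of each row; columns 1 and n are never minima.
local_minima_matrix <- function(D) {
  n <- ncol(D)
  M <- matrix(FALSE, nrow(D), n)
  M[, 2:(n - 1)] <- D[, 2:(n - 1), drop = FALSE] < D[, 1:(n - 2), drop = FALSE] &
    D[, 2:(n - 1), drop = FALSE] < D[, 3:n, drop = FALSE]
  M
}

#' Significant second-derivative dips (3-sigma rule)
#'
#' Calls every strict local minimum of the second-derivative spectrum whose
#' value lies below `-n_sigma * sigma`. Absorption maxima appear as
#' negative dips in the second derivative, so the test is one-sided.
#' `sigma` must be the noise scale matching the averaging level of `deriv`
#' (see [background_stats()]).
#'
#' @param deriv A `mir_spectrum` holding a second derivative (typically on
#'   the trimmed grid).
#' @param sigma Noise scale of the derivative; must be positive.
#' @param n_sigma Significance multiple (default 3).
#' @return data.frame with one row per call, sorted by center: `center`
#'   (cm^-1), `depth` (the derivative value, negative) and `significance`
#'   (`|depth| / sigma`, always `> n_sigma`).
#' @export
detect_significant_peaks <- function(deriv, sigma, n_sigma = 3) {
  stopifnot(inherits(deriv, "mir_spectrum"))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be positive: a noise model is required for the ",
         n_sigma, "-sigma rule")
  }
  d <- deriv$absorbance
  M <- local_minima_matrix(matrix(d, nrow = 1))
  hit <- which(as.vector(M) & d < -n_sigma * sigma)
  data.frame(center = deriv$grid$values[hit],
             depth = d[hit],
             significance = -d[hit] / sigma)
}

#' Per-band peak-occurrence counts across ROIs
#'
#' For each ROI, draws `n_per_roi` spectra (seeded, without replacement)
#' from the supplied set and counts how many contain at least one
#' significant second-derivative dip within `tolerance` cm^-1 of each
#' reference band center.
#'
#' @param spectra_sets List of `spectrum_set`s, one per ROI (rubberband-
#'   corrected absorbance spectra, or raw with `correct = TRUE`).
#' @param bands Band table (see [load_band_table()]).
#' @param sigma Per-pixel noise scale(s): a single value or one per ROI
#'   (use `background_stats()$sigma_pixel`).
#' @param params [derivative_params()].
#' @param tolerance Matching tolerance in cm^-1 (default 2; must be at
#'   least the grid step).
#' @param n_per_roi Spectra analysed per ROI (default 100).
#' @param seed Integer seed for the per-ROI subsampling.
#' @param n_sigma Significance multiple (default 3).
#' @param correct Rubberband-correct the drawn spectra before
#'   differentiation (set when `spectra_sets` holds raw absorbance).
#' @return An `occurrence_table`: integer matrix, one row per band center,
#'   one column per ROI, with attributes `n_per_roi`, `tolerance` and
#'   `bands`.
#' @export
peak_occurrence <- function(spectra_sets, bands, sigma,
                            params = derivative_params(), tolerance = 2,
                            n_per_roi = 100, seed = 1L, n_sigma = 3,
                            correct = FALSE) {
  stopifnot(length(spectra_sets) >= 1)
  bands <- validate_band_table(bands)
  if (nrow(bands) == 0) stop("empty band table")
  grid <- spectra_sets[[1]]$grid
  if (tolerance < grid$step) {
    stop("tolerance (", tolerance, " cm-1) must be at least the grid step (",
         grid$step, " cm-1)")
  }
  tg <- trimmed_grid(grid, params)
  if (any(bands$center < tg$start | bands$center > tg$stop)) {
    off <- bands$center[bands$center < tg$start | bands$center > tg$stop]
    stop("band center(s) off the trimmed grid range [", tg$start, ", ",
         tg$stop, "]: ", paste(off, collapse = ", "))
  }
  sigma <- rep_len(sigma, length(spectra_sets))
  if (any(!is.finite(sigma) | sigma <= 0)) stop("sigma must be positive")
  counts <- matrix(0L, nrow(bands), length(spectra_sets))
  rownames(counts) <- format(bands$center, trim = TRUE)
  colnames(counts) <- vapply(spectra_sets, function(s) as.character(s$roi_id), "")
  band_cols <- lapply(bands$center, function(cc) {
    which(abs(tg$values - cc) <= tolerance)
  })
  for (si in seq_along(spectra_sets)) {
    set <- spectra_sets[[si]]
    if (n_per_roi > nrow(set$matrix)) {
      stop("n_per_roi (", n_per_roi, ") exceeds the ", nrow(set$matrix),
           " spectra in ROI ", set$roi_id)
    }
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, 300, si))
    rows <- sample(nrow(set$matrix), n_per_roi, replace = FALSE)
    .Random.seed_restore(old)
    mat <- set$matrix[rows, , drop = FALSE]
    if (correct) mat <- rubberband_correct_matrix(mat, set$grid$values)
    D <- sg_second_derivative(mat, grid$step, params)
    hits <- local_minima_matrix(D) & D < -n_sigma * sigma[si]
    for (bi in seq_len(nrow(bands))) {
      cols <- band_cols[[bi]]
      if (length(cols) > 0) {
        counts[bi, si] <- sum(rowSums(hits[, cols, drop = FALSE]) > 0)
      }
    }
  }
  structure(counts, n_per_roi = n_per_roi, tolerance = tolerance,
            bands = bands, class = c("occurrence_table", "matrix"))
}

#' Number of consistently observed bands
#'
#' A band counts as consistently observed when its median occurrence
#' across ROIs reaches `min_fraction` of the spectra analysed per ROI.
#'
#' @param table An `occurrence_table` from [peak_occurrence()].
#' @param min_fraction Consistency threshold (default 0.5).
#' @return Integer count of consistent bands.
#' @export
count_consistent_bands <- function(table, min_fraction = 0.5) {
  if (is.null(table) || length(table) == 0 || nrow(table) == 0) return(0L)
  n <- attr(table, "n_per_roi")
  med <- apply(unclass(table), 1, stats::median)
  sum(med >= min_fraction * n)
}

#' Gaussian sub-band fit of a mean spectrum
#'
#' Least-squares fit of a sum of Gaussians (one per initial center, as
#' identified by second-derivative analysis) to a baseline-corrected mean
#' spectrum. Centers are bounded within `center_slack` of their
#' initialization, widths within `fwhm_bounds`, amplitudes non-negative.
#' Non-convergence is flagged in the result, never silent.
#'
#' @param mean_spectrum A `mir_spectrum` (baseline-corrected absorbance).
#' @param initial_centers Numeric vector of dip centers (cm^-1), e.g. from
#'   [detect_significant_peaks()] on the mean spectrum.
#' @param center_slack Center bound, cm^-1 (default 4).
#' @param fwhm_bounds Width bounds, cm^-1 (default `c(6, 80)`).
#' @param fwhm_start Starting width (default 20).
#' @return A list of class `gaussian_fit`: `bands` (data.frame with
#'   `center`, `fwhm`, `amplitude` per sub-band), `residual_rms`,
#'   `converged` and `message`.
#' @export
fit_gaussian_subbands <- function(mean_spectrum, initial_centers,
                                  center_slack = 4, fwhm_bounds = c(6, 80),
                                  fwhm_start = 20) {
  stopifnot(inherits(mean_spectrum, "mir_spectrum"))
  if (length(initial_centers) == 0) {
    stop("initial_centers is empty: run peak detection on the mean spectrum first")
  }
  wn <- mean_spectrum$grid$values
  y <- mean_spectrum$absorbance
  k <- length(initial_centers)
  a0 <- vapply(initial_centers,
               function(cc) max(y[abs(wn - cc) <= 4], 1e-3), 0)
  theta0 <- c(a0, initial_centers, rep(fwhm_start, k))
  lower <- c(rep(0, k), initial_centers - center_slack,
             rep(fwhm_bounds[1], k))
  upper <- c(rep(Inf, k), initial_centers + center_slack,
             rep(fwhm_bounds[2], k))
  model <- function(theta) {
    A <- theta[seq_len(k)]
    cc <- theta[k + seq_len(k)]
    f <- theta[2 * k + seq_len(k)]
    colSums(A * exp(-4 * log(2) * outer(cc, wn, `-`)^2 / f^2))
  }
  fit <- minpack.lm::nls.lm(par = theta0,
                            fn = function(theta) y - model(theta),
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  # info 1-3: step/ftol convergence; 4: gradient orthogonality (reached at
  # an exact optimum). 0 and 5+ signal failure.
  converged <- fit$info %in% 1:4
  theta <- fit$par
  res <- y - model(theta)
  structure(list(
    bands = data.frame(center = theta[k + seq_len(k)],
                       fwhm = theta[2 * k + seq_len(k)],
                       amplitude = theta[seq_len(k)]),
    residual_rms = sqrt(mean(res^2)),
    converged = converged,
    message = fit$message
  ), class = "gaussian_fit")
}

#' Composite Simpson integral on a uniform grid
#'
#' Composite Simpson's rule over `(x, y)` samples; when the point count is
#' even (odd number of subintervals) Simpson covers the first `n - 1`
#' points and the final subinterval is handled by the trapezoid rule.
#' Exact for polynomials up to cubic on the Simpson part.
#'
#' @param x Evenly spaced, ascending sample positions (>= 2 points).
#' @param y Sample values.
#' @return The integral.
#' @export
composite_simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-9 * max(1, abs(h[1]))) {
    stop("composite_simpson requires an evenly spaced grid")
  }
  h <- h[1]
  total <- 0
  m <- if (n %% 2 == 1) n else n - 1L
  if (m >= 3) {
    idx <- seq_len(m)
    w <- rep(c(2, 4), length.out = m)
    w[1] <- 1; w[m] <- 1
    total <- total + h / 3 * sum(w * y[idx])
  } else {
    m <- 1L  # only two points in total: pure trapezoid below
  }
  if (m < n) total <- total + h / 2 * (y[n - 1] + y[n])
  total
}

#' Band integral of a spectrum
#'
#' Composite Simpson integral of the (baseline-corrected) spectrum over a
#' band's integration window.
#'
#' @param spectrum A `mir_spectrum`.
#' @param band One-row band definition (needs `window_low`, `window_high`),
#'   or a list with those fields.
#' @return Integral in absorbance * cm^-1.
#' @export
band_integral <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "mir_spectrum"))
  lo <- band$window_low; hi <- band$window_high
  wn <- spectrum$grid$values
  if (lo < wn[1] || hi > wn[length(wn)]) {
    stop("integration window [", lo, ", ", hi, "] lies outside the grid [",
         wn[1], ", ", wn[length(wn)], "]")
  }
  sel <- which(wn >= lo - 1e-9 & wn <= hi + 1e-9)
  if (length(sel) < 2) stop("integration window [", lo, ", ", hi,
                            "] spans fewer than 2 grid points")
  composite_simpson(wn[sel], spectrum$absorbance[sel])
}

#' Band integrals of per-ROI mean spectra
#'
#' Integrates every band of a reference table over each ROI mean spectrum,
#' either on the baseline-corrected absorbance (default) or on the negated
#' second derivative over the same windows.
#'
#' @param mean_spectra List of `mir_spectrum`s (baseline-corrected ROI
#'   means), one per ROI.
#' @param bands Band table.
#' @param mode `"absorbance"` or `"second_derivative"`.
#' @param params [derivative_params()] (second-derivative mode only).
#' @return Matrix of integrals, one row per band, one column per ROI, with
#'   the band table attached as attribute `bands`.
#' @export
roi_band_integrals <- function(mean_spectra, bands,
                               mode = c("absorbance", "second_derivative"),
                               params = derivative_params()) {
  mode <- match.arg(mode)
  bands <- validate_band_table(bands)
  if (nrow(bands) == 0) stop("empty band table")
  specs <- lapply(mean_spectra, function(s) {
    stopifnot(inherits(s, "mir_spectrum"))
    if (mode == "absorbance") s
    else {
      d <- second_derivative(s, params)
      new_spectrum(d$grid, -d$absorbance)
    }
  })
  out <- vapply(specs, function(s) {
    vapply(seq_len(nrow(bands)),
           function(i) band_integral(s, bands[i, ]), 0)
  }, numeric(nrow(bands)))
  out <- matrix(out, nrow = nrow(bands))
  rownames(out) <- format(bands$center, trim = TRUE)
  attr(out, "bands") <- bands
  out
}

#' Summarize band integrals over ROIs
#'
#' @param integrals Matrix from [roi_band_integrals()].
#' @return data.frame with `center`, `assignment`, `integral_mean`,
#'   `integral_sd`.
#' @export
band_quantification <- function(integrals) {
  bands <- attr(integrals, "bands")
  data.frame(center = bands$center, assignment = bands$assignment,
             integral_mean = apply(integrals, 1, mean),
             integral_sd = apply(integrals, 1, stats::sd),
             row.names = NULL)
}

#' Percent reduction of a band integral between preparations
#'
#' `100 * (integral_ff - integral_ffpe) / integral_ff`.
#'
#' @param integral_ff Mean band integral in the fresh-frozen class (> 0).
#' @param integral_ffpe Mean band integral in the FFPE class.
#' @return Percent reduction (positive when FFPE is lower).
#' @export
percent_reduction <- function(integral_ff, integral_ffpe) {
  if (!is.finite(integral_ff) || integral_ff <= 0) {
    stop("percent reduction requires a positive FF integral, got ",
         integral_ff)
  }
  100 * (integral_ff - integral_ffpe) / integral_ff
}
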