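#' Construct an evenly spaced wavenumber grid
#'
#' The spectral axis shared by all spectra in an acquisition: an ascending,
#' evenly spaced sequence of wavenumbers (cm^-1). The instrument default
#' covers the biochemical fingerprint region, 950 to 1800 cm^-1 in 2 cm^-1
#' steps (426 points); see [default_grid()].
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1); must be `>= start`.
#' @param step Grid spacing (cm^-1); must be positive, and `stop - start`
#'   must be an integer multiple of it (within 1e-9 relative tolerance).
#' @return An object of class `wn_grid`: a list with elements `start`,
#'   `stop`, `step` and `values` (the ascending wavenumber sequence).
#' @examples
#' g <- make_grid(950, 1800, 2)
#' length(g$values)  # 426
#' @export
make_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1)
  if (step <= 0) stop("`step` must be positive, got ", step)
  if (stop < start) stop("`stop` (", stop, ") must be >= `start` (", start, ")")
  span <- stop - start
  n_steps <- span / step
  if (abs(n_steps - round(n_steps)) > 1e-9 * max(1, abs(n_steps))) {
    stop("span (stop - start = ", span, ") is not an integer multiple of step (",
         step, ")")
  }
  n <- as.integer(round(n_steps)) + 1L
  values <- start + step * (seq_len(n) - 1)
  structure(list(start = start, stop = stop, step = step, values = values),
            class = "wn_grid")
}

#' Default instrument wavenumber grid
#'
#' 950-1800 cm^-1 at 2 cm^-1 spacing: 426 spectral points.
#'
#' @return A `wn_grid` with 426 points.
#' @export
default_grid <- function() make_grid(950, 1800, 2)

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g to %g cm-1, step %g (%d points)\n",
              x$start, x$stop, x$step, length(x$values)))
  invisible(x)
}

#' @export
length.wn_grid <- function(x) length(x$values)

is_wn_grid <- function(x) inherits(x, "wn_grid")

grids_equal <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) <= tol * pmax(1, abs(a$values)))
}

#' Index of the grid point nearest a wavenumber
#'
#' @param grid A `wn_grid`.
#' @param wavenumber Target wavenumber (cm^-1); must lie within the grid span.
#' @return Integer index into `grid$values`.
#' @export
grid_index <- function(grid, wavenumber) {
  stopifnot(is_wn_grid(grid))
  if (wavenumber < grid$start - grid$step / 2 ||
      wavenumber > grid$stop + grid$step / 2) {
    stop("wavenumber ", wavenumber, " lies outside grid [",
         grid$start, ", ", grid$stop, "]")
  }
  which.min(abs(grid$values - wavenumber))
}

#' Construct a single spectrum
#'
#' A carrier for one absorbance (or derivative) trace aligned to a grid.
#'
#' @param grid A `wn_grid`.
#' @param absorbance Numeric vector, one finite value per grid point.
#' @return An object of class `mir_spectrum` with elements `grid` and
#'   `absorbance`.
#' @export
new_spectrum <- function(grid, absorbance) {
  stopifnot(is_wn_grid(grid))
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(grid$values)) {
    stop("absorbance length (", length(absorbance),
         ") does not match grid length (", length(grid$values), ")")
  }
  if (!all(is.finite(absorbance))) stop("absorbance contains non-finite values")
  structure(list(grid = grid, absorbance = absorbance), class = "mir_spectrum")
}

#' @export
print.mir_spectrum <- function(x, ...) {
  cat(sprintf("<mir_spectrum> %d points, %g to %g cm-1, range [%.4g, %.4g]\n",
              length(x$absorbance), x$grid$start, x$grid$stop,
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

# --- sample-class bookkeeping ------------------------------------------------

TISSUES <- c("kidney", "liver")
PREPS <- c("FF", "FFPE")

#' The four tissue-by-preparation classes of the study
#'
#' @return A data.frame with columns `tissue` (kidney/liver) and `prep`
#'   (FF/FFPE), one row per class, in a fixed order.
#' @export
study_classes <- function() {
  expand.grid(prep = PREPS, tissue = TISSUES,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c("tissue", "prep")]
}

check_class_label <- function(tissue, prep) {
  if (!tissue %in% TISSUES) stop("unknown tissue '", tissue,
                                 "'; expected one of: ", paste(TISSUES, collapse = ", "))
  if (!prep %in% PREPS) stop("unknown prep '", prep,
                             "'; expected one of: ", paste(PREPS, collapse = ", "))
  invisible(TRUE)
}

#' Canonical key for a tissue/preparation class
#'
#' @param tissue "kidney" or "liver".
#' @param prep "FF" or "FFPE".
#' @return A string such as `"kidney_FF"`.
#' @export
class_key <- function(tissue, prep) {
  check_class_label(tissue, prep)
  paste(tissue, prep, sep = "_")
}

#' Construct a set of spectra sampled from one ROI
#'
#' @param grid A `wn_grid`.
#' @param mat Numeric matrix, one spectrum per row, `length(grid)` columns.
#' @param pixel_ids data.frame with columns `row`, `col` giving each
#'   spectrum's source pixel; rows must be unique within the set.
#' @param roi_id Identifier of the source ROI.
#' @param tissue,prep Class label of the source sample.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(grid, mat, pixel_ids, roi_id, tissue, prep) {
  stopifnot(is_wn_grid(grid), is.matrix(mat))
  check_class_label(tissue, prep)
  if (ncol(mat) != length(grid$values)) {
    stop("matrix has ", ncol(mat), " columns but grid has ",
         length(grid$values), " points")
  }
  stopifnot(is.data.frame(pixel_ids), all(c("row", "col") %in% names(pixel_ids)),
            nrow(pixel_ids) == nrow(mat))
  if (anyDuplicated(pixel_ids[, c("row", "col")])) {
    stop("pixel_ids contains duplicated (row, col) pairs")
  }
  structure(list(grid = grid, matrix = mat, pixel_ids = pixel_ids,
                 roi_id = roi_id, tissue = tissue, prep = prep),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavenumbers, ROI %s (%s %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$roi_id, x$tissue, x$prep))
  invisible(x)
}

#' Mean spectrum of a spectrum set
#'
#' @param set A `spectrum_set`.
#' @return A `mir_spectrum` holding the per-wavenumber mean.
#' @export
roi_mean_spectrum <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  new_spectrum(set$grid, colMeans(set$matrix))
}

#' Construct a hyperspectral cube
#'
#' One acquisition (ROI): an H x W image of absorbance spectra.
#'
#' @param data Numeric array `height x width x bands`; all values finite.
#' @param grid `wn_grid` whose length equals the third dimension.
#' @param tissue,prep Class label.
#' @param roi_id ROI identifier.
#' @return An object of class `mir_cube`.
#' @export
new_cube <- function(data, grid, tissue, prep, roi_id) {
  stopifnot(is.array(data), length(dim(data)) == 3, is_wn_grid(grid))
  check_class_label(tissue, prep)
  d <- dim(data)
  if (d[1] < 8 || d[2] < 8) stop("cube must be at least 8 x 8 pixels, got ",
                                 d[1], " x ", d[2])
  if (d[3] != length(grid$values)) {
    stop("cube has ", d[3], " bands but grid has ", length(grid$values), " points")
  }
  if (!all(is.finite(data))) stop("cube contains non-finite values")
  structure(list(data = data, grid = grid, tissue = tissue, prep = prep,
                 roi_id = roi_id), class = "mir_cube")
}

#' @export
print.mir_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mir_cube> %d x %d pixels x %d bands, ROI %s (%s %s)\n",
              d[1], d[2], d[3], x$roi_id, x$tissue, x$prep))
  invisible(x)
}

#' Flatten a cube to a pixels-by-wavenumbers matrix
#'
#' @param cube A `mir_cube`.
#' @return Matrix with `height * width` rows (pixel (r, c) at row
#'   `(c - 1) * height + r`, i.e. column-major) and one column per band.
#' @export
cube_matrix <- function(cube) {
  stopifnot(inherits(cube, "mir_cube"))
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}
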