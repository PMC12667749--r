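#' Derive integration windows from band centers
#'
#' Reference band tables list peak centers only; integration windows default
#' to `center +/- half_width`, truncated at the midpoint to any neighbouring
#' center closer than `2 * half_width`. This keeps windows symmetric at the
#' instrument's band spacing while making them collision-free by construction
#' (windows may touch, but never cross a neighbour's center).
#'
#' @param centers Numeric vector of band centers (cm^-1); need not be sorted.
#' @param half_width Half window width (cm^-1), default 12.
#' @return data.frame with columns `center`, `window_low`, `window_high`,
#'   sorted by center.
#' @export
band_windows_from_centers <- function(centers, half_width = 12) {
  stopifnot(is.numeric(centers), length(centers) >= 1, half_width > 0)
  if (anyDuplicated(centers)) stop("duplicated band centers")
  centers <- sort(centers)
  low <- centers - half_width
  high <- centers + half_width
  n <- length(centers)
  if (n > 1) {
    mid <- (centers[-n] + centers[-1]) / 2
    clash <- diff(centers) < 2 * half_width
    high[-n][clash] <- mid[clash]
    low[-1][clash] <- mid[clash]
  }
  data.frame(center = centers, window_low = low, window_high = high)
}

validate_band_table <- function(bands) {
  req <- c("assignment", "center", "window_low", "window_high")
  missing <- setdiff(req, names(bands))
  if (length(missing) > 0) {
    stop("band table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(bands) == 0) return(bands[, req])
  bands <- bands[order(bands$center), req, drop = FALSE]
  rownames(bands) <- NULL
  bad <- bands$window_low >= bands$center | bands$center >= bands$window_high
  if (any(bad)) {
    stop("band(s) at ", paste(bands$center[bad], collapse = ", "),
         " violate window_low < center < window_high")
  }
  if (nrow(bands) > 1) {
    # windows may touch but must not cross a neighbour's center
    up <- bands$window_high[-nrow(bands)] > bands$center[-1]
    down <- bands$window_low[-1] < bands$center[-nrow(bands)]
    if (any(up | down)) {
      i <- which(up | down)[1]
      stop("integration windows of bands at ", bands$center[i], " and ",
           bands$center[i + 1], " cross each other's centers")
    }
  }
  bands
}

#' Load a band-definition table
#'
#' Reads a CSV with header `assignment,center,window_low,window_high`
#' (wavenumbers in cm^-1), validates it, and returns the bands sorted by
#' center. An empty file yields an empty table, which downstream stages
#' reject at use time.
#'
#' @param path Path to the CSV file.
#' @return data.frame with columns `assignment`, `center`, `window_low`,
#'   `window_high`, sorted by center.
#' @seealso [default_band_table()] for the packaged reference table.
#' @export
load_band_table <- function(path) {
  if (!file.exists(path)) stop("band table not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(assignment = character(0), center = numeric(0),
                      window_low = numeric(0), window_high = numeric(0)))
  }
  bands <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_band_table(bands)
}

#' The packaged reference band table
#'
#' Sixteen fingerprint-region bands: the fifteen reference assignments
#' (DNA 966/1035/1082, glycogen 1030/1154, protein 1168/1400/1448,
#' Amide III 1238/1308, lipid 1462/1744, Amide II 1516/1546, Amide I 1658)
#' plus the FFPE-specific -CH2OH artifact band at 1026 cm^-1 attributed to
#' formalin-induced collagen crosslinking. Windows follow
#' [band_windows_from_centers()] with the default 12 cm^-1 half width.
#'
#' @return data.frame of 16 band definitions sorted by center.
#' @export
default_band_table <- function() {
  path <- system.file("extdata", "band_table.csv", package = "mirspec",
                      mustWork = TRUE)
  load_band_table(path)
}
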