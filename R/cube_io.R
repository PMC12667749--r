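#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' Writes `<path>.hdr` (text header) and `<path>.dat` (raw binary,
#' band-sequential, little-endian, 8-byte IEEE doubles so that a
#' write/read round trip is bit-exact). The wavenumber axis is stored in
#' the header `wavelength` field; tissue, prep and ROI id are stored as
#' custom header keys.
#'
#' @param cube A `mir_cube`.
#' @param path Output path; a trailing `.hdr` or `.dat` extension is
#'   stripped and both files are written next to each other.
#' @return Invisibly, the path of the written header.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "mir_cube"))
  base <- sub("\\.(hdr|dat)$", "", path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = { mirspec hyperspectral absorbance cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Wavenumber",
    paste0("wavelength = { ",
           paste(format(cube$grid$values, trim = TRUE, digits = 15),
                 collapse = ", "), " }"),
    paste0("tissue = ", cube$tissue),
    paste0("prep = ", cube$prep),
    paste0("roi id = ", cube$roi_id)
  )
  writeLines(hdr, paste0(base, ".hdr"))
  # BSQ, row-major within band: samples vary fastest, then lines, then bands
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, c(2, 1, 3))), con,
           size = 8, endian = "little")
  invisible(paste0(base, ".hdr"))
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ENVI") {
    stop("not an ENVI header: ", hdr_path)
  }
  # re-join { ... } blocks that span lines
  text <- paste(lines[-1], collapse = "\n")
  fields <- list()
  pos <- 1
  pat <- "(?s)([^=\\n]+)=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(text, starts[i], starts[i] + lens[i] - 1)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1, eq - 1)))
    val <- trimws(substr(piece, eq + 1, nchar(piece)))
    fields[[key]] <- val
  }
  fields
}

envi_numeric_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read a hyperspectral cube from an ENVI header/binary pair
#'
#' Accepts BSQ, BIL and BIP interleaves and data types 4 (float) and
#' 5 (double). A descending wavelength axis is reversed on read (with a
#' message) so that cubes always carry an ascending grid in memory.
#'
#' @param path Path to the `.hdr` file, the `.dat` file, or their common
#'   base name.
#' @return A `mir_cube`.
#' @export
read_cube <- function(path) {
  base <- sub("\\.(hdr|dat)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  dat_path <- paste0(base, ".dat")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  if (!file.exists(dat_path)) stop("missing ENVI binary: ", dat_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) stop("ENVI header lacks field(s): ",
                             paste(miss, collapse = ", "))
  W <- as.integer(h$samples); H <- as.integer(h$lines); B <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unknown ENVI interleave: '", h$interleave, "'")
  }
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1)
    "big" else "little"
  n_expected <- as.double(W) * H * B
  n_avail <- (file.size(dat_path) - offset) / size
  if (n_avail != n_expected) {
    stop("ENVI payload holds ", n_avail, " values but header declares ",
         n_expected, " (", H, " x ", W, " x ", B, ")")
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  raw <- readBin(con, "double", n = n_expected, size = size, endian = endian)
  data <- switch(interleave,
    bsq = aperm(array(raw, dim = c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(raw, dim = c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(raw, dim = c(B, W, H)), c(3, 2, 1))
  )
  if (is.null(h$wavelength)) stop("ENVI header lacks a wavelength field")
  wl <- envi_numeric_list(h$wavelength)
  if (length(wl) != B) {
    stop("header wavelength list has ", length(wl), " entries for ", B, " bands")
  }
  if (is.unsorted(wl)) {
    if (is.unsorted(rev(wl))) stop("wavelength axis is not monotonic")
    message("descending wavenumber axis in ", hdr_path, "; reversing on read")
    wl <- rev(wl)
    data <- data[, , rev(seq_len(B)), drop = FALSE]
  }
  steps <- diff(wl)
  if (max(abs(steps - steps[1])) > 1e-9 * max(1, abs(steps[1]))) {
    stop("wavelength axis is not evenly spaced")
  }
  grid <- make_grid(wl[1], wl[length(wl)], steps[1])
  new_cube(data, grid,
           tissue = if (is.null(h$tissue)) "kidney" else h$tissue,
           prep = if (is.null(h$prep)) "FF" else h$prep,
           roi_id = if (is.null(h[["roi id"]])) basename(base) else h[["roi id"]])
}
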