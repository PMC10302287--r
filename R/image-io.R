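# Minimal MRC2014 (mode 2, float32) reader/writer for micrographs, particle
# stacks and class averages, plus plain-text fallbacks (CSV matrix, x/y
# coordinate lists). Only the subset of the MRC2014 standard needed here is
# implemented: single-volume / stack, little-endian, no extended header.

#' Read an MRC2014 image or stack
#'
#' Supports mode 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) volumes
#' without extended headers. Sections are returned as a matrix (single image)
#' or a y-by-x-by-n array (stack), with pixel size in Angstrom taken from the
#' cell dimensions.
#'
#' @param file path to an `.mrc` file
#' @return List with `data` (matrix or array, rows = y, cols = x),
#'   `pixel_size` (Angstrom), `n` (number of sections).
#' @export
read_mrc <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + max(nsymbt, 0))
  npix <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = npix, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = npix, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = npix, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = npix, size = 2, signed = FALSE,
                  endian = "little"),
    stop_domain("unsupported MRC mode: ", mode))
  if (length(vals) != npix) stop_domain("truncated MRC data block")
  px <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else NA_real_
  # MRC stores x fastest; our convention is rows = y, cols = x
  arr <- array(as.numeric(vals), dim = c(nx, ny, nz))
  arr <- aperm(arr, c(2, 1, 3))
  if (nz == 1L) arr <- arr[, , 1]
  list(data = arr, pixel_size = px, n = nz)
}

#' Write an MRC2014 mode-2 image or stack
#'
#' @param data matrix (rows = y, cols = x) or y-by-x-by-n array
#' @param file output path
#' @param pixel_size pixel size in Angstrom, stored in the cell dimensions
#' @return The file path, invisibly.
#' @export
write_mrc <- function(data, file, pixel_size = 1) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  ny <- dim(data)[1]; nx <- dim(data)[2]; nz <- dim(data)[3]
  con <- file(file, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L))                       # nx ny nz mode
  wi(c(0L, 0L, 0L))                           # nxstart nystart nzstart
  wi(c(nx, ny, nz))                           # mx my mz
  wf(c(nx, ny, nz) * pixel_size)              # cella (Angstrom)
  wf(c(90, 90, 90))                           # cellb
  wi(c(1L, 2L, 3L))                           # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))     # dmin dmax dmean
  wi(c(1L, 0L))                               # ispg nsymbt
  writeBin(raw(100), con)                     # extra
  wf(c(0, 0, 0))                              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(as.numeric(data)))             # rms
  wi(1L)                                      # nlabl
  lab <- sprintf("%-80s", "vlpsizer")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeBin(raw(80 * 9), con)
  # x fastest within each section
  for (k in seq_len(nz)) wf(as.numeric(t(data[, , k])))
  invisible(file)
}

#' Read particle coordinates from a text file
#'
#' Whitespace-delimited `x y` pairs, one particle per line, 0-based pixel
#' units, (x right, y down). Lines starting with `#` are ignored.
#'
#' @param file path
#' @return Two-column numeric matrix with columns `x`, `y`.
#' @export
read_coordinates <- function(file) {
  df <- utils::read.table(file, header = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop_domain("coordinate file needs two columns: x y")
  m <- as.matrix(df[, 1:2]); colnames(m) <- c("x", "y")
  m
}

#' Write particle coordinates
#' @param coords two-column matrix `x y`
#' @param file output path
#' @return The file path, invisibly.
#' @export
write_coordinates <- function(coords, file) {
  utils::write.table(coords, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read/write an image as a plain-text CSV matrix (rows = y, cols = x)
#' @param file path
#' @return `read_image_csv`: numeric matrix.
#' @export
read_image_csv <- function(file) {
  as.matrix(utils::read.table(file, header = FALSE, sep = ","))
}

#' @rdname read_image_csv
#' @param data numeric matrix
#' @export
write_image_csv <- function(data, file) {
  utils::write.table(data, file, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(file)
}
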