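#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Minimal single-strip, uncompressed, little-endian baseline TIFF writer.
#' Values are clipped to \[0, 65535\] and rounded to integers. The in-memory
#' pipeline works on floating-point matrices; this is only the file
#' interface. A hand-written codec is used because no TIFF package is
#' available in the target R stack.
#'
#' @param pixels numeric matrix (rows x cols).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff16()]
#' @export
write_tiff16 <- function(pixels, path) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  nr <- nrow(pixels); nc <- ncol(pixels)
  vals <- as.integer(round(pmin(pmax(pixels, 0), 65535)))
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  # header: II, magic 42, IFD offset right after pixel data
  writeBin(charToRaw("II"), con)
  w2(42L)
  data_offset <- 8L
  nbytes <- 2L * nr * nc
  w4(data_offset + nbytes)           # IFD offset
  # pixel data, row-major (TIFF rows are image rows)
  writeBin(as.integer(t(pixels_to_u16(vals, nr, nc))), con, size = 2,
           endian = "little")
  # IFD: 8 entries
  tags <- list(
    c(256L, 4L, 1L, nc),             # ImageWidth
    c(257L, 4L, 1L, nr),             # ImageLength
    c(258L, 3L, 1L, 16L),            # BitsPerSample
    c(259L, 3L, 1L, 1L),             # Compression = none
    c(262L, 3L, 1L, 1L),             # Photometric = BlackIsZero
    c(273L, 4L, 1L, data_offset),    # StripOffsets
    c(278L, 4L, 1L, nr),             # RowsPerStrip
    c(279L, 4L, 1L, nbytes)          # StripByteCounts
  )
  w2(length(tags))
  for (tg in tags) {
    w2(tg[1]); w2(tg[2]); w4(tg[3])
    if (tg[2] == 3L) { w2(tg[4]); w2(0L) } else w4(tg[4])
  }
  w4(0L)                             # next IFD
  invisible(path)
}

# reshape clipped integer vector back to a matrix for row-major writing
pixels_to_u16 <- function(vals, nr, nc) {
  matrix(vals, nrow = nr, ncol = nc)
}

#' Read a 16-bit grayscale TIFF written by [write_tiff16()]
#'
#' Supports uncompressed, little-endian, single-sample 8/16-bit grayscale
#' TIFFs with contiguous strips (the subset this package writes).
#'
#' @param path TIFF file path.
#' @return numeric matrix of pixel values.
#' @export
read_tiff16 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readChar(con, 2, useBytes = TRUE)
  if (order_bytes != "II")
    stop("only little-endian TIFF supported", call. = FALSE)
  magic <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (magic != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, size = 2, endian = "little")
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, endian = "little",
                   signed = FALSE)
    typ <- readBin(con, "integer", 1, size = 2, endian = "little")
    cnt <- readBin(con, "integer", 1, size = 4, endian = "little")
    val <- if (typ == 3L) {
      v <- readBin(con, "integer", 2, size = 2, endian = "little",
                   signed = FALSE)
      v[1]
    } else readBin(con, "integer", 1, size = 4, endian = "little")
    tags[[as.character(tag)]] <- c(type = typ, count = cnt, value = val)
  }
  need <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) {
      if (is.null(default)) stop("missing TIFF tag ", tag, call. = FALSE)
      return(default)
    }
    t[["value"]]
  }
  nc <- need(256); nr <- need(257)
  bits <- need(258, 16L)
  if (!(bits %in% c(8L, 16L)))
    stop("only 8/16-bit grayscale supported", call. = FALSE)
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
  strip_off <- need(273)
  seek(con, strip_off)
  vals <- readBin(con, "integer", nr * nc, size = bits / 8L,
                  endian = "little", signed = FALSE)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
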