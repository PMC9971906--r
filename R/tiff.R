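#' Minimal multi-page 16-bit grayscale TIFF I/O
#'
#' The pre-installed R stack has no TIFF package, so the package carries a
#' minimal baseline-TIFF codec: little-endian, uncompressed, one strip per
#' page, 16-bit (read also accepts 8-bit) single-sample grayscale. This
#' covers the uncompressed stacks exported by EMCCD acquisition software and
#' everything the simulator writes; it is not a general TIFF library.
#'
#' `write_tiff16()` rounds and clamps values to \[0, 65535\].
#'
#' @param stack Numeric matrix (one page) or array `[rows, cols, frames]`.
#' @param path Output file path.
#' @return `write_tiff16()` returns `path` invisibly; `read_tiff16()` returns
#'   an array `[rows, cols, frames]` of non-negative numerics.
#' @export
write_tiff16 <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  d <- dim(stack)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_size <- nr * nc * 2L
  page_size <- ifd_size + data_size
  con <- file(path, "wb")
  on.exit(close(con))
  # header: little-endian magic, offset of first IFD
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT, left-justified in 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(nf)) {
    ifd_off <- 8L + (i - 1L) * page_size
    data_off <- ifd_off + ifd_size
    writeBin(n_tags, con, size = 2, endian = "little")
    tag(256, 4, 1, nc)             # ImageWidth
    tag(257, 4, 1, nr)             # ImageLength
    tag(258, 3, 1, 16)             # BitsPerSample
    tag(259, 3, 1, 1)              # Compression: none
    tag(262, 3, 1, 1)              # Photometric: BlackIsZero
    tag(273, 4, 1, data_off)       # StripOffsets
    tag(277, 3, 1, 1)              # SamplesPerPixel
    tag(278, 4, 1, nr)             # RowsPerStrip
    tag(279, 4, 1, data_size)      # StripByteCounts
    next_ifd <- if (i < nf) 8L + i * page_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    # pixel data, row-major; reinterpret >32767 as signed for writeBin
    v <- round(t(stack[, , i]))
    v <- as.integer(clamp(v, 0, 65535))
    v <- ifelse(v > 32767L, v - 65536L, v)
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_tiff16
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  rd <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(2, 2, signed = FALSE) != 42L) stop("bad TIFF magic", call. = FALSE)
  ifd_off <- rd(4, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_tags <- rd(ifd_off, 2, signed = FALSE)
    tags <- list()
    for (k in seq_len(n_tags)) {
      e <- ifd_off + 2L + (k - 1L) * 12L
      id <- rd(e, 2, signed = FALSE)
      type <- rd(e + 2, 2, signed = FALSE)
      count <- rd(e + 4, 4)
      val <- if (type == 3L) rd(e + 8, 2, signed = FALSE) else rd(e + 8, 4)
      # multi-valued tags store an offset; resolve what we need
      if (count > 1L) {
        off <- rd(e + 8, 4)
        sz <- if (type == 3L) 2L else 4L
        val <- rd(off, sz, n = count, signed = FALSE)
      }
      tags[[as.character(id)]] <- val
    }
    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop("TIFF tag ", id, " missing", call. = FALSE)
      v
    }
    if ((tags[["259"]] %||% 1L) != 1L) {
      stop("only uncompressed TIFF supported", call. = FALSE)
    }
    bits <- tags[["258"]] %||% 1L
    bits <- bits[1]
    if (!bits %in% c(8L, 16L)) {
      stop("only 8/16-bit grayscale TIFF supported", call. = FALSE)
    }
    nc <- need(256); nr <- need(257)
    offs <- need(273)
    counts <- tags[["279"]] %||% (nr * nc * bits / 8)
    px <- unlist(lapply(seq_along(offs), function(s) {
      nb <- counts[s]
      npx <- nb / (bits / 8)
      if (bits == 16L) rd(offs[s], 2, n = npx, signed = FALSE)
      else as.integer(raw[(offs[s] + 1):(offs[s] + nb)])
    }))
    pages[[length(pages) + 1L]] <- matrix(px, nrow = nr, ncol = nc,
                                          byrow = TRUE)
    ifd_off <- rd(ifd_off + 2L + n_tags * 12L, 4)
  }
  d1 <- dim(pages[[1]])
  out <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (i in seq_along(pages)) out[, , i] <- pages[[i]]
  out
}
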