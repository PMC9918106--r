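# Minimal PNG codec.
#
# No PNG library is available in the supported dependency set, so the package
# carries a small self-contained codec: enough of the PNG spec for 8-bit
# grayscale / RGB / RGBA images, which is all the pipeline produces or
# consumes. Compression rides on base R's memCompress/memDecompress, which
# emit and accept zlib (RFC 1950) streams -- exactly what PNG IDAT chunks
# hold. The writer always emits filter type 0; the reader understands all
# five standard scanline filters so PNGs from other writers load too.

# Unsigned 32-bit values are carried as doubles in [0, 2^32); xor is done on
# 16-bit halves (safe for R's signed-integer bit ops).
dxor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

.crc32_table <- local({
  poly <- 3988292384  # 0xEDB88320
  tab <- numeric(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (c %% 2 == 1) dxor32(poly, floor(c / 2)) else floor(c / 2)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295  # 0xFFFFFFFF
  tab <- .crc32_table
  for (b in as.integer(bytes)) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- dxor32(tab[idx + 1], floor(crc / 256))
  }
  dxor32(crc, 4294967295)
}

int_to_raw4 <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

raw4_to_num <- function(r) {
  sum(as.numeric(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(int_to_raw4(length(data)), body, int_to_raw4(as.numeric(crc) %% 4294967296))
}

#' Write an image as PNG
#'
#' Encodes an `H x W x 3` (RGB), `H x W x 4` (RGBA) array or `H x W` matrix
#' (grayscale) with values in `[0, 1]` as an 8-bit PNG.
#'
#' @param image numeric array/matrix with values in `[0, 1]`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_png <- function(image, path) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  d <- dim(image)
  if (length(d) != 3 || !(d[3] %in% c(1, 3, 4)))
    stop("image must be H x W, H x W x 3, or H x W x 4")
  if (anyNA(image) || min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image values must be in [0, 1]")
  h <- d[1]; w <- d[2]; nc <- d[3]
  color_type <- switch(as.character(nc), "1" = 0L, "3" = 2L, "4" = 6L)
  bytes <- as.integer(round(pmin(pmax(image, 0), 1) * 255))
  # interleave channels within each row: scanline = filter byte + RGB triples
  px <- aperm(array(bytes, d), c(3, 2, 1))  # [channel, col, row]
  scan <- matrix(as.raw(px), nc * w, h)
  stream <- as.raw(rbind(matrix(as.raw(0), 1, h), scan))
  idat <- memCompress(stream, type = "gzip")  # zlib stream
  ihdr <- c(int_to_raw4(w), int_to_raw4(h), as.raw(c(8L, color_type, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}

#' Read a PNG image
#'
#' Decodes 8-bit grayscale, RGB or RGBA PNGs (no interlacing, no palette).
#' All five standard scanline filters are supported.
#'
#' @param path PNG file path.
#' @return Numeric array `H x W x channels` with values in `[0, 1]`.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (!identical(as.integer(bytes[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    stop("not a PNG file")
  pos <- 9
  idat <- raw(0)
  w <- h <- bit_depth <- color_type <- NULL
  while (pos + 7 <= length(bytes)) {
    len <- raw4_to_num(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      w <- raw4_to_num(data[1:4]); h <- raw4_to_num(data[5:8])
      bit_depth <- as.integer(data[9]); color_type <- as.integer(data[10])
      if (as.integer(data[13]) != 0L) stop("interlaced PNG not supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (bit_depth != 8L) stop("only 8-bit PNGs supported")
  nc <- switch(as.character(color_type), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop("palette PNGs not supported"))
  stream <- memDecompress(idat, type = "gzip")
  stride <- nc * w
  px <- matrix(0L, stride, h)
  prev <- integer(stride)
  off <- 0L
  for (row in seq_len(h)) {
    filt <- as.integer(stream[off + 1L])
    cur <- as.integer(stream[(off + 2L):(off + 1L + stride)])
    if (filt == 1L) {          # Sub
      for (i in seq_len(stride))
        cur[i] <- (cur[i] + if (i > nc) cur[i - nc] else 0L) %% 256L
    } else if (filt == 2L) {   # Up
      cur <- (cur + prev) %% 256L
    } else if (filt == 3L) {   # Average
      for (i in seq_len(stride)) {
        left <- if (i > nc) cur[i - nc] else 0L
        cur[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256L
      }
    } else if (filt == 4L) {   # Paeth
      for (i in seq_len(stride)) {
        a <- if (i > nc) cur[i - nc] else 0L
        b <- prev[i]
        cc <- if (i > nc) prev[i - nc] else 0L
        p <- a + b - cc
        pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
        pred <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        cur[i] <- (cur[i] + pred) %% 256L
      }
    } else if (filt != 0L) stop("unknown PNG filter type ", filt)
    px[, row] <- cur
    prev <- cur
    off <- off + 1L + stride
  }
  arr <- aperm(array(px, dim = c(nc, w, h)), c(3, 2, 1))
  arr / 255
}
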