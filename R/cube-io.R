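#' Write / read a hyperspectral cube in ENVI layout
#'
#' Flat little-endian float32 binary in band-sequential (BSQ) interleave plus
#' a text header (`<path>.hdr`) recording samples, lines, bands, data type
#' and the wavelength list -- the conventional exchange format for
#' hyperspectral data. `write_cube_gz()` / `read_cube_gz()` provide a
#' compressed single-file variant: a gzip stream holding a JSON header line
#' followed by the same float32 payload.
#'
#' @param cube a `hyperspectral_cube`.
#' @param path output path for the binary payload; the header is written to
#'   `paste0(path, ".hdr")`.
#' @return `read_cube()` / `read_cube_gz()` return a `hyperspectral_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  wl <- grid_wavelengths(cube$grid)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", cube$width),
    sprintf("lines = %d", cube$height),
    sprintf("bands = %d", cube$grid$n),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ", paste(format(wl, trim = TRUE), collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band planes in order; within a plane, row-major (line by line)
  v <- aperm(cube$values, c(2, 1, 3))  # now [col, row, band]; column-major = row-major plane
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_lines <- readLines(paste0(path, ".hdr"))
  get_num <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr_lines, value = TRUE)
    as.integer(sub(".*= *", "", ln[1]))
  }
  w <- get_num("samples"); h <- get_num("lines"); nb <- get_num("bands")
  if (get_num("data type") != 4L) stop("only float32 (data type 4) cubes supported")
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, numeric(), n = w * h * nb, size = 4, endian = "little")
  wl_line <- grep("^wavelength *= *\\{", hdr_lines, value = TRUE)
  wl <- as.numeric(strsplit(gsub("^wavelength *= *\\{|\\}", "", wl_line), ",")[[1]])
  grid <- spectral_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  v <- array(raw_vals, dim = c(w, h, nb))
  hyperspectral_cube(aperm(v, c(2, 1, 3)), grid)
}

#' @rdname write_cube
#' @export
write_cube_gz <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  meta <- jsonlite::toJSON(list(
    height = cube$height, width = cube$width,
    start_nm = cube$grid$start_nm, end_nm = cube$grid$end_nm,
    step_nm = cube$grid$step_nm), auto_unbox = TRUE)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  meta_raw <- charToRaw(as.character(meta))
  writeBin(length(meta_raw), con, size = 4, endian = "little")
  writeBin(meta_raw, con)
  v <- aperm(cube$values, c(2, 1, 3))
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube_gz <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  meta_len <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), n = meta_len)))
  grid <- spectral_grid(meta$start_nm, meta$end_nm, meta$step_nm)
  v <- readBin(con, numeric(), n = meta$height * meta$width * grid$n,
               size = 4, endian = "little")
  v <- array(v, dim = c(meta$width, meta$height, grid$n))
  hyperspectral_cube(aperm(v, c(2, 1, 3)), grid)
}
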