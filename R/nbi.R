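#' Wavelength band windows
#'
#' A band window is an inclusive wavelength interval `[lo_nm, hi_nm]` whose
#' endpoints lie on the shared grid. The two default windows -- 405--435 nm
#' (the Soret band of hemoglobin) and 525--555 nm (the oxy-hemoglobin Q
#' bands) -- are the characteristic skin-absorption bands driving narrow-band
#' image synthesis; each spans 31 channels at 1 nm spacing.
#'
#' @param lo_nm,hi_nm window endpoints in nanometres, `lo_nm <= hi_nm`.
#' @param grid the shared `spectral_grid`.
#' @return An object of class `band_window`.
#' @export
band_window <- function(lo_nm, hi_nm, grid = spectral_grid()) {
  if (lo_nm > hi_nm) stop("lo_nm must not exceed hi_nm")
  lo_i <- grid_index(lo_nm, grid)  # errors if off-grid
  hi_i <- grid_index(hi_nm, grid)
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm, lo_index = lo_i,
                 hi_index = hi_i, grid = grid),
            class = "band_window")
}

#' @rdname band_window
#' @export
default_windows <- function(grid = spectral_grid()) {
  list(band_window(405, 435, grid), band_window(525, 555, grid))
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band_window> %g-%g nm (%d channels)\n",
              x$lo_nm, x$hi_nm, x$hi_index - x$lo_index + 1L))
  invisible(x)
}

#' Average a cube over a wavelength window
#'
#' Per-pixel arithmetic mean of reflectance over every channel with
#' `lo <= lambda <= hi` (inclusive at both ends, so 405--435 nm averages 31
#' channels).
#'
#' @param cube a `hyperspectral_cube`.
#' @param window a `band_window` on the cube's grid.
#' @return H x W numeric matrix.
#' @export
band_average <- function(cube, window) {
  stopifnot(inherits(cube, "hyperspectral_cube"), inherits(window, "band_window"))
  if (!identical(unclass(window$grid), unclass(cube$grid)))
    stop("window grid does not match cube grid")
  idx <- window$lo_index:window$hi_index
  plane <- cube$values[, , idx, drop = FALSE]
  rowMeans(matrix(plane, cube$height * cube$width, length(idx))) |>
    matrix(cube$height, cube$width)
}

#' Synthesize a narrow-band pseudo-colour image
#'
#' Averages the cube over one to three wavelength windows and maps the
#' averages to display channels. The default mapping follows the endoscopic
#' narrow-band-imaging convention: the short (Soret, 405--435 nm) window
#' feeds the blue and red channels and the longer (525--555 nm) window feeds
#' green, which renders hemoglobin-rich tissue in high contrast. With a
#' single window the result is grayscale replicated to three channels.
#'
#' Normalization is fixed-range by default (reflectance 0..1 clipped), so
#' narrow-band images are comparable across scenes; `"minmax"` stretches each
#' channel to the full range instead.
#'
#' @param cube a `hyperspectral_cube`.
#' @param windows list of 1--3 `band_window` objects (default: the two
#'   hemoglobin windows).
#' @param channel_map integer vector mapping display channels (R, G, B) to
#'   window indices. Default for two windows: `c(1, 2, 1)`.
#' @param normalization `"fixed"` (clip reflectance to `[0, 1]`) or
#'   `"minmax"` (per-channel stretch).
#' @return An object of class `nbi_image`: list with `channels`
#'   (H x W x 3 array in `[0, 1]`) and `provenance` (windows, mapping,
#'   normalization).
#' @export
synthesize_nbi <- function(cube, windows = default_windows(cube$grid),
                           channel_map = NULL,
                           normalization = c("fixed", "minmax")) {
  normalization <- match.arg(normalization)
  if (inherits(windows, "band_window")) windows <- list(windows)
  nw <- length(windows)
  if (nw < 1 || nw > 3) stop("between 1 and 3 windows required")
  if (is.null(channel_map)) {
    channel_map <- switch(nw, c(1L, 1L, 1L), c(1L, 2L, 1L), c(1L, 2L, 3L))
  }
  if (length(channel_map) != 3 || any(channel_map < 1) || any(channel_map > nw))
    stop("channel_map must give a window index for each of R, G, B")
  planes <- lapply(windows, function(w) band_average(cube, w))
  chan <- array(0, dim = c(cube$height, cube$width, 3))
  for (i in 1:3) chan[, , i] <- planes[[channel_map[i]]]
  if (normalization == "fixed") {
    chan <- pmin(pmax(chan, 0), 1)
  } else {
    for (i in 1:3) {
      p <- chan[, , i]
      rng <- range(p)
      chan[, , i] <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0
    }
  }
  structure(
    list(channels = chan,
         provenance = list(
           windows = lapply(windows, function(w) c(lo_nm = w$lo_nm, hi_nm = w$hi_nm)),
           channel_map = channel_map,
           normalization = normalization)),
    class = "nbi_image")
}

#' @export
print.nbi_image <- function(x, ...) {
  wins <- vapply(x$provenance$windows,
                 function(w) sprintf("%g-%g", w["lo_nm"], w["hi_nm"]), "")
  cat(sprintf("<nbi_image> %d x %d, windows %s, %s normalization\n",
              dim(x$channels)[1], dim(x$channels)[2],
              paste(wins, collapse = " / "), x$provenance$normalization))
  invisible(x)
}

#' Write a narrow-band image to PNG with a provenance sidecar
#'
#' Writes the 3-channel composite as an 8-bit PNG and a `<path>.json`
#' sidecar recording the windows, channel mapping and normalization used.
#'
#' @param nbi an `nbi_image`.
#' @param path output PNG path.
#' @return The PNG path, invisibly.
#' @export
write_nbi <- function(nbi, path) {
  stopifnot(inherits(nbi, "nbi_image"))
  write_png(nbi$channels, path)
  jsonlite::write_json(nbi$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
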