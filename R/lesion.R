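#' Per-class spectrum collections
#'
#' Bundles the reflectance spectra observed for one lesion class (e.g. BCC,
#' SCC or SK) together with their pointwise mean spectrum.
#'
#' @param class_label character class name.
#' @param spectra n x 401 matrix or list of spectra.
#' @param grid the shared grid.
#' @return An object of class `class_spectrum_set` with fields `class_label`,
#'   `spectra` (matrix) and `mean_spectrum`.
#' @export
class_spectrum_set <- function(class_label, spectra, grid = spectral_grid()) {
  stopifnot(is.character(class_label), length(class_label) == 1)
  S <- spectra_matrix(spectra, grid)
  structure(list(class_label = class_label, spectra = S,
                 mean_spectrum = colMeans(S), grid = grid),
            class = "class_spectrum_set")
}

#' @export
print.class_spectrum_set <- function(x, ...) {
  cat(sprintf("<class_spectrum_set> %s: %d spectra\n",
              x$class_label, nrow(x$spectra)))
  invisible(x)
}

#' Mean spectrum over a region of interest
#'
#' Per-band mean over the pixels selected by `region`: either a box
#' `c(xmin, ymin, xmax, ymax)` in the 0-based half-open pixel convention, or
#' a logical H x W mask.
#'
#' @param cube a `hyperspectral_cube`.
#' @param region length-4 numeric box or logical matrix mask.
#' @return Length-401 numeric spectrum.
#' @export
roi_mean_spectrum <- function(cube, region) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  flat <- matrix(cube$values, cube$height * cube$width, cube$grid$n)
  if (is.matrix(region) && is.logical(region)) {
    if (!all(dim(region) == c(cube$height, cube$width)))
      stop("mask dimensions do not match the cube")
    sel <- as.vector(region)
  } else if (is.numeric(region) && length(region) == 4) {
    b <- validate_box(region)
    if (b[1] < 0 || b[2] < 0 || b[3] > cube$width || b[4] > cube$height)
      stop("region extends outside the image")
    cols <- (floor(b[1]) + 1):ceiling(b[3])
    rows <- (floor(b[2]) + 1):ceiling(b[4])
    sel <- rep(FALSE, cube$height * cube$width)
    sel[as.vector(outer(rows, (cols - 1) * cube$height, `+`))] <- TRUE
  } else stop("region must be a box (xmin, ymin, xmax, ymax) or a logical mask")
  if (!any(sel)) stop("empty region")
  colMeans(flat[sel, , drop = FALSE])
}

#' Normalize a reflectance spectrum
#'
#' `method = "max"` (default, matching how normalized lesion reflectance
#' curves are conventionally displayed) divides by the peak so the maximum is
#' exactly 1 and illumination scale drops out; `method = "area"` divides by
#' the channel sum.
#'
#' @param s numeric spectrum.
#' @param method `"max"` or `"area"`.
#' @return The normalized spectrum.
#' @export
normalize_spectrum <- function(s, method = c("max", "area")) {
  method <- match.arg(method)
  if (all(s == 0)) stop("cannot normalize an all-zero spectrum")
  if (any(s < 0)) stop("reflectance must be non-negative")
  switch(method, max = s / max(s), area = s / sum(s))
}

#' Between-class band separation profile
#'
#' Scores every wavelength by how well it separates the class mean spectra:
#' for each channel, the maximum over class pairs of the absolute difference
#' of max-normalized mean spectra (`statistic = "max_diff"`, default), or a
#' Fisher-ratio variant (`"fisher"`: squared mean difference over pooled
#' within-class variance, maximized over pairs).
#'
#' @param sets list of at least two `class_spectrum_set` objects.
#' @param statistic `"max_diff"` or `"fisher"`.
#' @return Length-401 non-negative numeric profile (class
#'   `band_separation_profile`).
#' @export
band_separation <- function(sets, statistic = c("max_diff", "fisher")) {
  statistic <- match.arg(statistic)
  if (length(sets) < 2) stop("at least two classes required")
  stopifnot(all(vapply(sets, inherits, TRUE, "class_spectrum_set")))
  grid <- sets[[1]]$grid
  means <- lapply(sets, function(s) normalize_spectrum(s$mean_spectrum))
  vars <- lapply(sets, function(s) {
    norm <- s$spectra / max(s$mean_spectrum)
    apply(norm, 2, stats::var)
  })
  prof <- rep(0, grid$n)
  pairs <- utils::combn(length(sets), 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- if (statistic == "max_diff") {
      abs(means[[i]] - means[[j]])
    } else {
      pooled <- (vars[[i]] + vars[[j]]) / 2
      (means[[i]] - means[[j]])^2 / pmax(pooled, 1e-12)
    }
    prof <- pmax(prof, d)
  }
  structure(prof, class = "band_separation_profile", grid = grid)
}

#' Greedy selection of discriminative wavelength windows
#'
#' Selects `n_windows` non-overlapping windows of `width_nm` channels
#' (31 channels = the conventional 405--435-style window) maximizing the
#' window-summed separation score, greedily; ties break toward the shorter
#' wavelength. The selection is invariant to positive rescaling of the
#' profile.
#'
#' @param profile a `band_separation_profile` (or plain length-401 vector).
#' @param width_nm window width in channels at 1 nm spacing (a window covers
#'   `width_nm` grid points, e.g. 31 gives spans like 405--435).
#' @param n_windows number of windows to select.
#' @param grid the shared grid.
#' @return List of `band_window` objects, ordered by selection.
#' @export
select_windows <- function(profile, width_nm = 31, n_windows = 2,
                           grid = spectral_grid()) {
  if (!is.null(attr(profile, "grid"))) grid <- attr(profile, "grid")
  prof <- as.numeric(profile)
  if (length(prof) != grid$n) stop("profile length does not match grid")
  if (n_windows < 1) stop("n_windows must be at least 1")
  w <- as.integer(width_nm)
  if (w < 1 || w > grid$n) stop("width_nm must be between 1 and the grid length")
  n_start <- grid$n - w + 1L
  sums <- as.numeric(stats::filter(prof, rep(1, w), sides = 1))[w:grid$n]
  blocked <- rep(FALSE, n_start)
  wl <- grid_wavelengths(grid)
  out <- vector("list", n_windows)
  for (s in seq_len(n_windows)) {
    avail <- which(!blocked)
    if (length(avail) == 0)
      stop(sprintf("cannot fit %d non-overlapping windows of width %d", n_windows, w))
    best <- avail[which.max(sums[avail])]  # which.max ties -> lowest index
    out[[s]] <- band_window(wl[best], wl[best + w - 1L], grid)
    lo_block <- max(1L, best - w + 1L)
    hi_block <- min(n_start, best + w - 1L)
    blocked[lo_block:hi_block] <- TRUE
  }
  out
}

#' Export mean spectra / separation profiles as CSV
#'
#' `write_mean_spectra()` writes long-format `(wavelength_nm, class,
#' reflectance)`; `write_separation_profile()` writes
#' `(wavelength_nm, score)`.
#'
#' @param sets list of `class_spectrum_set`.
#' @param profile a `band_separation_profile`.
#' @param path output CSV path.
#' @param normalized write max-normalized means (default TRUE).
#' @return The path, invisibly.
#' @export
write_mean_spectra <- function(sets, path, normalized = TRUE) {
  grid <- sets[[1]]$grid
  wl <- grid_wavelengths(grid)
  rows <- do.call(rbind, lapply(sets, function(s) {
    m <- if (normalized) normalize_spectrum(s$mean_spectrum) else s$mean_spectrum
    data.frame(wavelength_nm = wl, class = s$class_label, reflectance = m)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mean_spectra
#' @export
write_separation_profile <- function(profile, path) {
  grid <- attr(profile, "grid") %||% spectral_grid()
  utils::write.csv(data.frame(wavelength_nm = grid_wavelengths(grid),
                              score = as.numeric(profile)),
                   path, row.names = FALSE)
  invisible(path)
}
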