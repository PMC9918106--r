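#' Colorimetric constant tables
#'
#' The package ships a single CSV (`inst/extdata/cie_tables.csv`) holding, on
#' the 401-point grid, an analytic multi-lobe Gaussian fit to the CIE 1931
#' 2-degree colour matching functions and a smooth daylight illuminant
#' (Planckian radiator at 6504 K modulated by a quadratic) constrained so its
#' chromaticity is exactly the D65 white (x, y) = (0.3127, 0.3290) assumed by
#' sRGB. The loader validates the 401-row grid. The generator functions
#' [cmf_gaussian_fit()] and [daylight_illuminant()] reproduce the tables from
#' their formulas, so the CSV is regenerable and auditable.
#'
#' @param grid target `spectral_grid` (must be the canonical 401-point grid
#'   for the shipped table).
#' @return `cie_tables()`: a list with `wavelength_nm`, `xbar`, `ybar`,
#'   `zbar` (class `cmf`) and `illuminant` (numeric).
#' @export
cie_tables <- function(grid = spectral_grid()) {
  path <- system.file("extdata", "cie_tables.csv", package = "dermspectra")
  if (!nzchar(path)) stop("cie_tables.csv not found in installed package")
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "xbar", "ybar", "zbar", "illuminant")
  if (!all(need %in% names(tab))) stop("cie_tables.csv is missing columns")
  if (nrow(tab) != grid$n ||
      max(abs(tab$wavelength_nm - grid_wavelengths(grid))) > 1e-9)
    stop("cie_tables.csv does not match the 401-point grid")
  list(
    cmf = cmf(tab$xbar, tab$ybar, tab$zbar, grid),
    illuminant = illuminant(tab$illuminant, grid)
  )
}

#' Colour matching functions and illuminants
#'
#' Lightweight containers validating observer sensitivity curves and
#' illuminant spectral power on the shared grid.
#'
#' @param xbar,ybar,zbar observer sensitivity per grid point (non-negative).
#' @param grid the `spectral_grid`.
#' @return An object of class `cmf` (a list of the three curves).
#' @export
cmf <- function(xbar, ybar, zbar, grid = spectral_grid()) {
  for (v in list(xbar, ybar, zbar)) {
    if (length(v) != grid$n) stop("cmf curve length does not match grid")
    if (any(v < 0)) stop("cmf curves must be non-negative")
  }
  wl <- grid_wavelengths(grid)
  peak <- wl[which.max(ybar)]
  if (abs(peak - 555) > 15)
    stop(sprintf("ybar peaks at %g nm; expected near 555 nm", peak))
  structure(list(xbar = as.numeric(xbar), ybar = as.numeric(ybar),
                 zbar = as.numeric(zbar), grid = grid), class = "cmf")
}

#' @rdname cmf
#' @param power relative spectral power per grid point.
#' @return `illuminant()`: an object of class `illuminant`.
#' @export
illuminant <- function(power, grid = spectral_grid()) {
  if (length(power) != grid$n) stop("illuminant length does not match grid")
  if (any(power < 0)) stop("illuminant power must be non-negative")
  if (all(power == 0)) stop("illuminant must not be all zero")
  structure(list(power = as.numeric(power), grid = grid), class = "illuminant")
}

#' Analytic fit to the CIE 1931 2-degree observer
#'
#' Multi-lobe piecewise-Gaussian approximation (three lobes for x-bar, two
#' each for y-bar and z-bar), clamped at zero. Maximum pointwise error
#' against the standard observer is about 1 percent; the fit is used instead
#' of the tabulated observer so the constants are reproducible from formulas
#' alone.
#'
#' @param grid target grid.
#' @return A `cmf` object.
#' @export
cmf_gaussian_fit <- function(grid = spectral_grid()) {
  wl <- grid_wavelengths(grid)
  pg <- function(x, mu, s1, s2)
    ifelse(x < mu, exp(-(x - mu)^2 / (2 * s1^2)), exp(-(x - mu)^2 / (2 * s2^2)))
  xbar <- 1.056 * pg(wl, 599.8, 37.9, 31.0) + 0.362 * pg(wl, 442.0, 16.0, 26.7) -
    0.065 * pg(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * pg(wl, 568.8, 46.9, 40.5) + 0.286 * pg(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * pg(wl, 437.0, 11.8, 36.0) + 0.681 * pg(wl, 459.0, 26.0, 13.8)
  cmf(pmax(xbar, 0), pmax(ybar, 0), pmax(zbar, 0), grid)
}

#' Smooth daylight illuminant at the D65 white point
#'
#' A Planckian radiator at 6504 K multiplied by a quadratic polynomial in
#' normalized wavelength, with the three polynomial coefficients solved so
#' that (a) the chromaticity under `observer` is exactly
#' (x, y) = (0.3127, 0.3290) -- the D65 white assumed by sRGB -- and (b) the
#' power at 560 nm is 100. This is a synthetic stand-in: it matches D65 in
#' white point and broad shape but not D65's spectral fine structure.
#'
#' @param observer `cmf` used for the chromaticity constraint.
#' @param grid target grid.
#' @return An `illuminant` object.
#' @export
daylight_illuminant <- function(observer = cmf_gaussian_fit(grid),
                                grid = spectral_grid()) {
  wl <- grid_wavelengths(grid)
  c2 <- 1.4388e-2
  lm <- wl * 1e-9
  planck <- 1 / (lm^5 * (exp(c2 / (lm * 6504)) - 1))
  planck <- planck / planck[wl == 560]
  t <- (wl - 380) / 400
  B <- cbind(planck, planck * t, planck * t^2)
  TX <- colSums(B * observer$xbar)
  TY <- colSums(B * observer$ybar)
  TZ <- colSums(B * observer$zbar)
  xt <- 0.3127; yt <- 0.3290
  A <- rbind(TX - xt * (TX + TY + TZ),
             TY - yt * (TX + TY + TZ),
             B[wl == 560, ])
  co <- solve(A, c(0, 0, 100))
  illuminant(as.numeric(B %*% co), grid)
}

.colorimetry_cache <- new.env(parent = emptyenv())

default_cmf <- function() {
  if (is.null(.colorimetry_cache$cmf)) {
    tabs <- cie_tables()
    .colorimetry_cache$cmf <- tabs$cmf
    .colorimetry_cache$illuminant <- tabs$illuminant
  }
  .colorimetry_cache$cmf
}

default_illuminant <- function() {
  default_cmf()
  .colorimetry_cache$illuminant
}

#' Reflectance spectrum to tristimulus XYZ
#'
#' Rectangular-rule integration at the 1 nm grid spacing:
#' `X = k * sum(R * S * xbar)` and similarly for Y and Z, with
#' `k = 100 / sum(S * ybar)` so the illuminant's perfect reflector has
#' Y = 100. Accepts a single spectrum (vector) or a matrix with one spectrum
#' per row.
#'
#' @param spectrum numeric vector of length 401 or an n x 401 matrix.
#' @param illum an `illuminant` (default: the shipped daylight table).
#' @param observer a `cmf` (default: the shipped observer fit).
#' @return For a vector input, a named numeric `c(X, Y, Z)`; for a matrix,
#'   an n x 3 matrix with columns X, Y, Z.
#' @export
spectrum_to_xyz <- function(spectrum, illum = default_illuminant(),
                            observer = default_cmf()) {
  grid <- observer$grid
  if (!identical(unclass(illum$grid), unclass(grid)))
    stop("grid mismatch between illuminant and observer")
  single <- !is.matrix(spectrum)
  R <- if (single) matrix(spectrum, nrow = 1) else spectrum
  if (ncol(R) != grid$n)
    stop(sprintf("grid mismatch: spectrum has %d channels, grid has %d",
                 ncol(R), grid$n))
  S <- illum$power
  k <- 100 / sum(S * observer$ybar)
  out <- k * cbind(
    X = as.numeric(R %*% (S * observer$xbar)),
    Y = as.numeric(R %*% (S * observer$ybar)),
    Z = as.numeric(R %*% (S * observer$zbar))
  )
  if (single) out[1, ] else out
}

# Linear RGB <-> XYZ (Y on the 0..1 scale) derived from the sRGB primary
# chromaticities and the shipped white point. Because the shipped illuminant
# is constrained to the exact sRGB D65 chromaticity, this reproduces the
# standard published sRGB matrix.
srgb_matrices <- function(observer = default_cmf(),
                          illum = default_illuminant()) {
  key <- "srgb_mats"
  cached <- .colorimetry_cache[[key]]
  if (!is.null(cached)) return(cached)
  white <- spectrum_to_xyz(rep(1, observer$grid$n), illum, observer) / 100
  prim <- cbind(R = c(0.64, 0.33), G = c(0.30, 0.60), B = c(0.15, 0.06))
  P <- rbind(prim[1, ] / prim[2, ], 1, (1 - prim[1, ] - prim[2, ]) / prim[2, ])
  s <- solve(P, white)
  M <- P %*% diag(s)
  mats <- list(rgb2xyz = M, xyz2rgb = solve(M), white = white * 100)
  .colorimetry_cache[[key]] <- mats
  mats
}

# sRGB transfer curve and inverse.
srgb_encode <- function(linear) {
  ifelse(linear <= 0.0031308, 12.92 * linear,
         1.055 * pmax(linear, 0)^(1 / 2.4) - 0.055)
}

srgb_decode <- function(encoded) {
  ifelse(encoded <= 0.04045, encoded / 12.92, ((encoded + 0.055) / 1.055)^2.4)
}

#' XYZ to sRGB
#'
#' Standard sRGB linear matrix (D65 white) followed by the sRGB transfer
#' curve. Out-of-gamut channels are clipped to `[0, 1]`; the returned value
#' carries an attribute `clipped` (logical, per input row) flagging where
#' clipping occurred. Accepts `c(X, Y, Z)` or an n x 3 matrix, with Y on the
#' 0..100 scale.
#'
#' @param xyz numeric length-3 vector or n x 3 matrix of tristimulus values.
#' @return RGB in `[0, 1]`: length-3 vector or n x 3 matrix, with attribute
#'   `clipped`.
#' @export
xyz_to_srgb <- function(xyz) {
  single <- !is.matrix(xyz)
  M <- srgb_matrices()$xyz2rgb
  X <- if (single) matrix(xyz, nrow = 1) else xyz
  if (ncol(X) != 3) stop("xyz must have 3 columns")
  if (anyNA(X) || any(!is.finite(X))) stop("xyz must be finite")
  lin <- (X / 100) %*% t(M)
  clipped <- rowSums(lin < -1e-9 | lin > 1 + 1e-9) > 0
  lin <- pmin(pmax(lin, 0), 1)
  out <- srgb_encode(lin)
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- c("R", "G", "B")
  res <- if (single) out[1, ] else out
  attr(res, "clipped") <- if (single) clipped[1] else clipped
  res
}

#' sRGB to XYZ
#'
#' Exact inverse of [xyz_to_srgb()] on in-gamut values: sRGB transfer
#' decoding followed by the linear RGB-to-XYZ matrix, Y scaled to 0..100.
#'
#' @param rgb numeric length-3 vector or n x 3 matrix with channels in
#'   `[0, 1]`.
#' @return Tristimulus values: named length-3 vector or n x 3 matrix.
#' @export
srgb_to_xyz <- function(rgb) {
  single <- !is.matrix(rgb)
  C <- if (single) matrix(rgb, nrow = 1) else rgb
  if (ncol(C) != 3) stop("rgb must have 3 columns")
  if (anyNA(C) || any(C < -1e-12) || any(C > 1 + 1e-12))
    stop("rgb channels must lie in [0, 1]")
  C <- pmin(pmax(C, 0), 1)
  M <- srgb_matrices()$rgb2xyz
  out <- 100 * (srgb_decode(C) %*% t(M))
  colnames(out) <- c("X", "Y", "Z")
  if (single) out[1, ] else out
}
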