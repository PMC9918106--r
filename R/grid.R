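#' Spectral grid
#'
#' All spectra in the package live on one shared wavelength grid:
#' 380--780 nm sampled every 1 nm, i.e. 401 channels. `spectral_grid()`
#' constructs (and validates) such a grid; the default arguments give the
#' canonical 401-point grid used everywhere else.
#'
#' @param start_nm first wavelength in nanometres.
#' @param end_nm last wavelength in nanometres.
#' @param step_nm grid spacing in nanometres.
#' @return An object of class `spectral_grid` with fields `start_nm`,
#'   `end_nm`, `step_nm` and `n` (number of sample points).
#' @examples
#' g <- spectral_grid()
#' g$n  # 401
#' @export
spectral_grid <- function(start_nm = 380, end_nm = 780, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be positive")
  if (end_nm <= start_nm) stop("grid must be strictly increasing")
  span <- end_nm - start_nm
  if (abs(span / step_nm - round(span / step_nm)) > 1e-9)
    stop("grid span must be an integer multiple of step_nm")
  structure(
    list(start_nm = as.numeric(start_nm), end_nm = as.numeric(end_nm),
         step_nm = as.numeric(step_nm),
         n = as.integer(round(span / step_nm)) + 1L),
    class = "spectral_grid"
  )
}

#' @rdname spectral_grid
#' @param grid a `spectral_grid`.
#' @return `grid_wavelengths()`: numeric vector of wavelengths (nm).
#' @export
grid_wavelengths <- function(grid = spectral_grid()) {
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g nm, step %g nm (%d channels)\n",
              x$start_nm, x$end_nm, x$step_nm, x$n))
  invisible(x)
}

# Reflectance headroom: values above 1 up to this bound are tolerated
# (specular highlights); anything beyond is a data error.
REFLECTANCE_MAX <- 1.5

#' Validate a reflectance spectrum
#'
#' A reflectance spectrum is a plain numeric vector on the shared grid:
#' unitless, non-negative, with headroom up to 1.5 for specular highlights.
#'
#' @param values numeric vector of per-channel reflectance.
#' @param grid the `spectral_grid` the spectrum must live on.
#' @return The validated numeric vector, invisibly usable as-is.
#' @export
as_reflectance_spectrum <- function(values, grid = spectral_grid()) {
  if (!is.numeric(values)) stop("reflectance spectrum must be numeric")
  if (length(values) != grid$n)
    stop(sprintf("spectrum length %d does not match grid length %d",
                 length(values), grid$n))
  if (anyNA(values) || any(!is.finite(values)))
    stop("reflectance spectrum contains non-finite values")
  if (any(values < 0)) stop("reflectance must be non-negative")
  if (any(values > REFLECTANCE_MAX))
    stop(sprintf("reflectance exceeds headroom bound %.2f", REFLECTANCE_MAX))
  as.numeric(values)
}

# Coerce a collection of spectra to an n x grid$n matrix (rows = spectra).
spectra_matrix <- function(spectra, grid = spectral_grid()) {
  if (is.matrix(spectra)) {
    if (ncol(spectra) != grid$n)
      stop(sprintf("spectra matrix has %d columns; grid needs %d",
                   ncol(spectra), grid$n))
    return(spectra)
  }
  if (is.list(spectra))
    return(do.call(rbind, lapply(spectra, as_reflectance_spectrum, grid = grid)))
  if (is.numeric(spectra))
    return(matrix(as_reflectance_spectrum(spectra, grid), nrow = 1))
  stop("spectra must be a matrix, a list of vectors, or a single vector")
}

# Index of a wavelength on the grid; errors if off-grid.
grid_index <- function(nm, grid = spectral_grid()) {
  idx <- (nm - grid$start_nm) / grid$step_nm
  if (any(nm < grid$start_nm | nm > grid$end_nm) ||
      any(abs(idx - round(idx)) > 1e-9))
    stop(sprintf("wavelength %s nm is not on the grid", paste(nm, collapse = ", ")))
  as.integer(round(idx)) + 1L
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a purpose-specific random seed
#'
#' Fans a single top-level seed out into independent streams, one per named
#' purpose, so different generators never share a random stream. The
#' derivation hashes the purpose string into a 31-bit integer combined with
#' the base seed; it is deterministic and documented so any run can be
#' replayed.
#'
#' @param seed base integer seed.
#' @param purpose character tag naming the consumer (e.g. `"calibration"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(length(seed) == 1, is.character(purpose), length(purpose) == 1)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(purpose)) h <- (h * 131 + b) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
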