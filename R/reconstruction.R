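#' Fit a PCA spectral basis
#'
#' Mean-centred principal component analysis of a collection of reflectance
#' spectra. The basis holds the mean spectrum, `k` orthonormal component
#' spectra and their explained-variance ratios. Projecting a training
#' spectrum onto all `min(n - 1, 401)` components and adding the mean
#' reproduces it to numerical precision.
#'
#' When the sample covariance is numerically rank deficient (e.g. duplicated
#' spectra), components beyond the rank are an arbitrary orthonormal
#' completion with explained-variance ratio 0; requesting `k` larger than the
#' dimension bound `min(n - 1, 401)` is an error.
#'
#' @param spectra n x 401 matrix (rows = spectra), list of vectors, or a
#'   single vector.
#' @param k number of principal components to retain.
#' @param grid the shared `spectral_grid`.
#' @return An object of class `spectral_basis`: list with `mean_spectrum`
#'   (length 401), `components` (k x 401, orthonormal rows),
#'   `explained_variance_ratio` (length k, non-increasing) and `grid`.
#' @export
fit_basis <- function(spectra, k, grid = spectral_grid()) {
  S <- spectra_matrix(spectra, grid)
  n <- nrow(S)
  if (k < 1) stop("k must be at least 1")
  if (n < k + 1) stop(sprintf("need at least k + 1 = %d spectra, got %d", k + 1, n))
  kmax <- min(n - 1, grid$n)
  if (k > kmax)
    stop(sprintf("k = %d exceeds the available rank bound %d", k, kmax))
  mu <- colMeans(S)
  Xc <- sweep(S, 2, mu)
  sv <- svd(Xc, nu = 0, nv = kmax)
  var_all <- sv$d^2 / max(n - 1, 1)
  total <- sum(var_all)
  evr <- if (total > 0) (var_all / total)[seq_len(k)] else rep(0, k)
  structure(
    list(mean_spectrum = mu,
         components = t(sv$v[, seq_len(k), drop = FALSE]),
         explained_variance_ratio = evr,
         grid = grid),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> k = %d components on %d channels; cum. EVR %.4f\n",
              nrow(x$components), ncol(x$components),
              sum(x$explained_variance_ratio)))
  invisible(x)
}

# Project spectra (rows) onto a basis: scores = (S - mu) %*% t(components).
basis_scores <- function(basis, spectra) {
  S <- spectra_matrix(spectra, basis$grid)
  sweep(S, 2, basis$mean_spectrum) %*% t(basis$components)
}

# Inverse projection: mean + scores %*% components.
basis_reconstruct <- function(basis, scores) {
  scores <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  sweep(scores %*% basis$components, 2, basis$mean_spectrum, `+`)
}

#' Polynomial feature expansion of tristimulus coordinates
#'
#' A feature expansion is a set of monomials `(a, b, c)` evaluated as
#' `X^a * Y^b * Z^c` after pre-scaling XYZ by 1/100 (so the white point maps
#' to 1 and powers stay well conditioned). The default expansion holds the 10
#' monomials of total degree at most 2 plus the cubic cross term `XYZ`
#' (11 features), the smallest family that fits smooth reflectance families
#' well.
#'
#' @param monomials integer matrix with 3 columns (exponents of X, Y, Z), one
#'   row per monomial; must contain the constant `(0, 0, 0)` and no
#'   duplicates.
#' @return An object of class `feature_expansion`.
#' @export
feature_expansion <- function(monomials) {
  m <- as.matrix(monomials)
  if (ncol(m) != 3) stop("monomials must have 3 exponent columns")
  if (any(m < 0) || any(m != round(m))) stop("exponents must be non-negative integers")
  if (anyDuplicated(as.data.frame(m))) stop("duplicate monomials")
  if (!any(rowSums(m) == 0)) stop("expansion must contain the constant monomial")
  structure(list(monomials = m), class = "feature_expansion")
}

#' @rdname feature_expansion
#' @export
default_expansion <- function() {
  deg2 <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  deg2 <- as.matrix(deg2[rowSums(deg2) <= 2, ])
  feature_expansion(rbind(deg2, c(1, 1, 1)))
}

#' @rdname feature_expansion
#' @param xyz length-3 vector or n x 3 matrix of tristimulus values.
#' @param expansion a `feature_expansion`.
#' @return `expand_features()`: numeric feature vector (or n x m matrix),
#'   element j equal to the j-th monomial evaluated at XYZ / 100.
#' @export
expand_features <- function(xyz, expansion = default_expansion()) {
  single <- !is.matrix(xyz)
  X <- if (single) matrix(xyz, nrow = 1) else xyz
  if (ncol(X) != 3) stop("xyz must have 3 columns")
  Xs <- X / 100
  m <- expansion$monomials
  out <- matrix(1, nrow(Xs), nrow(m))
  for (j in seq_len(nrow(m))) {
    e <- m[j, ]
    if (e[1] > 0) out[, j] <- out[, j] * Xs[, 1]^e[1]
    if (e[2] > 0) out[, j] <- out[, j] * Xs[, 2]^e[2]
    if (e[3] > 0) out[, j] <- out[, j] * Xs[, 3]^e[3]
  }
  if (single) out[1, ] else out
}

#' Fit the spectrum-reconstruction model
#'
#' The core of the RGB-to-hyperspectral conversion: each calibration
#' spectrum is rendered to XYZ by the colorimetric forward model, the
#' spectra are summarized by a k-component PCA basis, and ordinary least
#' squares maps the expanded XYZ features to the PCA scores. Reconstruction
#' then goes colour -> features -> scores -> mean + weighted components.
#'
#' A rank-deficient design matrix is solved by minimum-norm least squares
#' (SVD pseudoinverse) with a warning.
#'
#' @param calibration_spectra n x 401 matrix or list of spectra.
#' @param illum,observer forward-model tables (defaults: shipped constants).
#' @param k number of PCA components (default 6; captures over 99 percent of
#'   variance on smooth skin-like calibration sets).
#' @param expansion `feature_expansion` (default: 11 monomials).
#' @param grid the shared grid.
#' @return An object of class `reconstruction_model`: `basis`, `expansion`,
#'   `coefficients` (k x m), `training_rmse` (reflectance units), plus the
#'   tables used.
#' @export
fit_reconstruction_model <- function(calibration_spectra,
                                     illum = default_illuminant(),
                                     observer = default_cmf(),
                                     k = 6,
                                     expansion = default_expansion(),
                                     grid = spectral_grid()) {
  S <- spectra_matrix(calibration_spectra, grid)
  n <- nrow(S)
  m <- nrow(expansion$monomials)
  if (n < m)
    stop(sprintf("need at least %d calibration spectra for %d features", m, m))
  # k = 0 is the degenerate mean-only model (useful with a single
  # calibration spectrum and a constant-only expansion).
  basis <- if (k == 0) {
    structure(list(mean_spectrum = colMeans(S),
                   components = matrix(0, 0, grid$n),
                   explained_variance_ratio = numeric(0),
                   grid = grid),
              class = "spectral_basis")
  } else fit_basis(S, k, grid)
  xyz <- spectrum_to_xyz(S, illum, observer)
  Fmat <- expand_features(xyz, expansion)
  Tsc <- basis_scores(basis, S)
  qrF <- qr(Fmat)
  if (qrF$rank < ncol(Fmat)) {
    warning("rank-deficient design matrix; using minimum-norm least squares")
    sv <- svd(Fmat)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    coefs <- t(pinv %*% Tsc)
  } else {
    coefs <- t(qr.coef(qrF, Tsc))
  }
  fitted_scores <- Fmat %*% t(coefs)
  recon <- basis_reconstruct(basis, fitted_scores)
  training_rmse <- sqrt(mean((recon - S)^2))
  structure(
    list(basis = basis, expansion = expansion, coefficients = coefs,
         training_rmse = training_rmse, illuminant = illum,
         observer = observer, grid = grid),
    class = "reconstruction_model"
  )
}

#' @export
print.reconstruction_model <- function(x, ...) {
  cat(sprintf("<reconstruction_model> k = %d, %d features, training RMSE %.5f\n",
              nrow(x$coefficients), ncol(x$coefficients), x$training_rmse))
  invisible(x)
}

#' Reconstruct a reflectance spectrum from an sRGB colour
#'
#' sRGB -> XYZ -> polynomial features -> PCA scores -> spectrum. Negative
#' reconstructed reflectance is clamped to 0; the returned vector carries a
#' `clamped` attribute counting clamped channels (a quality signal, not an
#' error).
#'
#' @param rgb length-3 vector in `[0, 1]`, or an n x 3 matrix of colours.
#' @param model a `reconstruction_model`.
#' @return Length-401 spectrum (or n x 401 matrix) with attribute `clamped`.
#' @export
reconstruct_spectrum <- function(rgb, model) {
  single <- !is.matrix(rgb)
  xyz <- srgb_to_xyz(rgb)
  Fmat <- expand_features(if (single) matrix(xyz, nrow = 1) else xyz,
                          model$expansion)
  scores <- Fmat %*% t(model$coefficients)
  recon <- basis_reconstruct(model$basis, scores)
  clamped <- sum(recon < 0)
  recon <- pmax(recon, 0)
  out <- if (single) recon[1, ] else recon
  attr(out, "clamped") <- clamped
  out
}

#' Reconstruct a hyperspectral cube from an RGB image
#'
#' Applies [reconstruct_spectrum()] per pixel, vectorized over the set of
#' distinct 8-bit colours actually present in the image (an 8-bit image has
#' at most 16.7 million distinct colours, typically far fewer, so caching by
#' unique colour is the dominant speedup).
#'
#' @param image H x W x 3 numeric array in `[0, 1]` (or integers 0..255).
#' @param model a `reconstruction_model`.
#' @return An object of class `hyperspectral_cube`: list with `values`
#'   (H x W x 401 array, clamped non-negative), `grid`, `height`, `width`.
#' @export
reconstruct_cube <- function(image, model) {
  img <- as_rgb_image(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  flat <- matrix(img, h * w, 3)
  codes <- as.integer(round(flat[, 1] * 255)) * 65536L +
    as.integer(round(flat[, 2] * 255)) * 256L +
    as.integer(round(flat[, 3] * 255))
  uniq <- !duplicated(codes)
  ucolor <- flat[uniq, , drop = FALSE]
  spectra_u <- reconstruct_spectrum(ucolor, model)
  idx <- match(codes, codes[uniq])
  cube_vals <- array(spectra_u[idx, , drop = FALSE], dim = c(h, w, model$grid$n))
  hyperspectral_cube(cube_vals, model$grid)
}

#' Hyperspectral cube container
#'
#' @param values H x W x 401 array of reflectance (clamped non-negative).
#' @param grid the shared grid.
#' @return An object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(values, grid = spectral_grid()) {
  d <- dim(values)
  if (length(d) != 3 || d[3] != grid$n)
    stop(sprintf("cube must be H x W x %d", grid$n))
  if (any(values < 0)) values <- pmax(values, 0)
  structure(list(values = values, grid = grid,
                 height = d[1], width = d[2]),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  cat(sprintf("<hyperspectral_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              x$height, x$width, x$grid$n, x$grid$start_nm, x$grid$end_nm))
  invisible(x)
}

# Validate / coerce an RGB image array to [0,1] doubles.
as_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an H x W x 3 array")
  if (is.integer(image) || max(image) > 1 + 1e-9) {
    if (any(image < 0) || any(image > 255)) stop("8-bit image values must be 0..255")
    image <- image / 255
  }
  if (any(image < -1e-9) || any(image > 1 + 1e-9)) stop("image values must be in [0, 1]")
  storage.mode(image) <- "double"
  pmin(pmax(image, 0), 1)
}

#' Serialize / restore a reconstruction model as JSON
#'
#' The JSON holds the grid, mean spectrum, component vectors,
#' explained-variance ratios, monomial exponents and regression coefficients
#' -- everything needed to reconstruct spectra later. The colorimetric tables
#' are not embedded: the standard shipped constants are re-attached on read.
#'
#' @param model a `reconstruction_model`.
#' @param path file to write / read.
#' @return `read_reconstruction_model()` returns the restored model.
#' @export
write_reconstruction_model <- function(model, path) {
  obj <- list(
    grid = unclass(model$grid)[c("start_nm", "end_nm", "step_nm")],
    mean_spectrum = model$basis$mean_spectrum,
    components = model$basis$components,
    explained_variance_ratio = model$basis$explained_variance_ratio,
    monomials = model$expansion$monomials,
    coefficients = model$coefficients,
    training_rmse = model$training_rmse
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reconstruction_model
#' @export
read_reconstruction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- spectral_grid(obj$grid$start_nm, obj$grid$end_nm, obj$grid$step_nm)
  basis <- structure(
    list(mean_spectrum = as.numeric(obj$mean_spectrum),
         components = matrix(as.numeric(obj$components),
                             nrow = nrow(obj$components)),
         explained_variance_ratio = as.numeric(obj$explained_variance_ratio),
         grid = grid),
    class = "spectral_basis")
  structure(
    list(basis = basis,
         expansion = feature_expansion(obj$monomials),
         coefficients = matrix(as.numeric(obj$coefficients),
                               nrow = nrow(obj$coefficients)),
         training_rmse = obj$training_rmse,
         illuminant = default_illuminant(),
         observer = default_cmf(),
         grid = grid),
    class = "reconstruction_model")
}
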