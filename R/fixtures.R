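#' Spectrum recipe
#'
#' A generative description of a reflectance class: a flat (or sloped)
#' baseline minus Gaussian absorption dips plus white Gaussian noise,
#' clamped non-negative. The default dip placement mimics hemoglobin
#' absorption -- a strong Soret-band dip near 420 nm and a broader
#' oxy-hemoglobin dip near 545 nm -- which is the physical contrast that the
#' 405--435 and 525--555 nm windows exploit.
#'
#' @param baseline_level baseline reflectance (scalar), or length-401 vector
#'   for sloped baselines.
#' @param absorption_features list of `c(center_nm, width_nm, depth)`
#'   triples; each subtracts `depth * exp(-(l - center)^2 / (2 width^2))`.
#' @param noise_sd standard deviation of per-channel Gaussian noise.
#' @param grid the shared grid.
#' @return An object of class `spectrum_recipe`.
#' @export
spectrum_recipe <- function(baseline_level = 0.6,
                            absorption_features = list(c(420, 15, 0.35),
                                                       c(545, 20, 0.20)),
                            noise_sd = 0.01,
                            grid = spectral_grid()) {
  if (!length(baseline_level) %in% c(1, grid$n))
    stop("baseline_level must be a scalar or a full-grid vector")
  if (any(baseline_level < 0)) stop("baseline must be non-negative")
  base_min <- min(baseline_level)
  for (f in absorption_features) {
    if (length(f) != 3) stop("absorption features are (center_nm, width_nm, depth) triples")
    if (f[1] < grid$start_nm || f[1] > grid$end_nm) stop("dip centre off the grid")
    if (f[3] < 0 || f[3] > base_min)
      stop("dip depth must lie in [0, baseline_level]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(baseline_level = baseline_level,
                 absorption_features = absorption_features,
                 noise_sd = noise_sd, grid = grid),
            class = "spectrum_recipe")
}

# Deterministic (noise-free) spectrum of a recipe.
recipe_mean_spectrum <- function(recipe) {
  wl <- grid_wavelengths(recipe$grid)
  s <- rep(recipe$baseline_level, length.out = recipe$grid$n)
  for (f in recipe$absorption_features)
    s <- s - f[3] * exp(-(wl - f[1])^2 / (2 * f[2]^2))
  pmax(s, 0)
}

#' Generate class spectra from a recipe
#'
#' Draws `n` spectra: recipe mean plus independent Gaussian channel noise,
#' clamped non-negative. Bit-reproducible given the seed.
#'
#' @param recipe a `spectrum_recipe`.
#' @param n number of spectra.
#' @param class_label label for the resulting [class_spectrum_set()].
#' @param seed integer seed.
#' @return A `class_spectrum_set` with `n` spectra.
#' @export
make_class_spectra <- function(recipe, n, class_label = "class", seed = 1) {
  stopifnot(inherits(recipe, "spectrum_recipe"))
  if (n < 1) stop("n must be at least 1")
  mu <- recipe_mean_spectrum(recipe)
  S <- with_seed(seed, {
    noise <- if (recipe$noise_sd > 0)
      matrix(stats::rnorm(n * recipe$grid$n, sd = recipe$noise_sd),
             n, recipe$grid$n)
    else matrix(0, n, recipe$grid$n)
    pmax(matrix(mu, n, recipe$grid$n, byrow = TRUE) + noise, 0)
  })
  class_spectrum_set(class_label, S, recipe$grid)
}

#' Default lesion-class recipes
#'
#' Three synthetic classes mimicking the qualitative spectral structure of
#' the lesion types: two vascular classes with hemoglobin-like dips at
#' 420 nm (depth 0.35, width 15) and 545 nm (depth 0.20, width 20) at
#' different strengths, and a keratosis-like class with a melanin-style
#' sloped baseline and no hemoglobin dips.
#'
#' @param noise_sd per-channel noise level passed to each recipe.
#' @param grid the shared grid.
#' @return Named list of three `spectrum_recipe` objects (BCC, SCC, SK).
#' @export
default_class_recipes <- function(noise_sd = 0.01, grid = spectral_grid()) {
  wl <- grid_wavelengths(grid)
  melanin <- 0.25 + 0.45 * (wl - 380) / 400   # sloped, no dips
  list(
    BCC = spectrum_recipe(0.62, list(c(420, 15, 0.35), c(545, 20, 0.20)),
                          noise_sd, grid),
    SCC = spectrum_recipe(0.55, list(c(420, 15, 0.18), c(545, 20, 0.32)),
                          noise_sd, grid),
    SK = spectrum_recipe(melanin, list(), noise_sd, grid)
  )
}

#' Scene recipe and renderer
#'
#' A scene is a square canvas of background skin with elliptical lesions.
#' `render_scene()` draws a per-pixel spectrum from the corresponding recipe
#' (background or lesion), renders RGB through the colorimetric forward
#' model, and returns the RGB image, the ground-truth annotation (tight
#' ellipse bounding boxes) and the ground-truth hyperspectral cube.
#'
#' @param canvas edge length in pixels.
#' @param lesions list of lesion descriptors: each a list with
#'   `class_label`, `center = c(x, y)`, `axes = c(a, b)` (semi-axes in
#'   pixels) and `recipe` (a `spectrum_recipe`).
#' @param background_recipe `spectrum_recipe` for non-lesion pixels.
#' @param seed integer seed.
#' @param grid the shared grid.
#' @return An object of class `scene_recipe`.
#' @export
scene_recipe <- function(canvas = 64,
                         lesions,
                         background_recipe = spectrum_recipe(
                           0.55, list(c(420, 15, 0.10), c(545, 20, 0.06))),
                         seed = 1,
                         grid = spectral_grid()) {
  if (length(lesions) < 1) stop("at least one lesion required")
  for (l in lesions) {
    if (!all(c("class_label", "center", "axes", "recipe") %in% names(l)))
      stop("each lesion needs class_label, center, axes, recipe")
    if (any(l$center - l$axes < 0) || any(l$center + l$axes > canvas))
      stop("lesion ellipse extends outside the canvas")
  }
  structure(list(canvas = as.integer(canvas), lesions = lesions,
                 background_recipe = background_recipe, seed = seed,
                 grid = grid),
            class = "scene_recipe")
}

#' @rdname scene_recipe
#' @param recipe a `scene_recipe`.
#' @param illum,observer forward-model tables.
#' @return `render_scene()`: list with `image` (H x W x 3 sRGB array),
#'   `annotation` (an `annotated_image` carrying the image), `cube`
#'   (ground-truth `hyperspectral_cube`) and `class_map` (H x W integer
#'   matrix, 0 = background, i = i-th lesion).
#' @export
render_scene <- function(recipe, illum = default_illuminant(),
                         observer = default_cmf()) {
  stopifnot(inherits(recipe, "scene_recipe"))
  n <- recipe$canvas
  grid <- recipe$grid
  # pixel centres: x = column - 0.5, y = row - 0.5 (0-based pixel coords)
  xs <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  ys <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)
  class_map <- matrix(0L, n, n)
  for (i in seq_along(recipe$lesions)) {
    l <- recipe$lesions[[i]]
    inside <- ((xs - l$center[1]) / l$axes[1])^2 +
      ((ys - l$center[2]) / l$axes[2])^2 <= 1
    class_map[inside] <- i
  }
  flat <- matrix(0, n * n, grid$n)
  regions <- c(list(recipe$background_recipe),
               lapply(recipe$lesions, `[[`, "recipe"))
  with_seed(recipe$seed, {
    for (r in seq_along(regions)) {
      sel <- which(as.vector(class_map) == r - 1L)
      if (length(sel) == 0) next
      rec <- regions[[r]]
      mu <- recipe_mean_spectrum(rec)
      noise <- if (rec$noise_sd > 0)
        matrix(stats::rnorm(length(sel) * grid$n, sd = rec$noise_sd),
               length(sel), grid$n)
      else 0
      flat[sel, ] <- pmax(matrix(mu, length(sel), grid$n, byrow = TRUE) + noise, 0)
    }
  })
  cube <- hyperspectral_cube(array(flat, c(n, n, grid$n)), grid)
  xyz <- spectrum_to_xyz(flat, illum, observer)
  rgb_flat <- xyz_to_srgb(xyz)
  # quantize to 8 bits: scenes emulate what an 8-bit camera records
  img <- array(round(rgb_flat * 255) / 255, c(n, n, 3))
  boxes <- do.call(rbind, lapply(recipe$lesions, function(l) data.frame(
    class_label = l$class_label,
    xmin = l$center[1] - l$axes[1], ymin = l$center[2] - l$axes[2],
    xmax = l$center[1] + l$axes[1], ymax = l$center[2] + l$axes[2])))
  ann <- annotated_image(sprintf("scene_seed%d", recipe$seed), n, n, boxes,
                         image = img)
  list(image = img, annotation = ann, cube = cube, class_map = class_map)
}

#' Synthetic calibration set
#'
#' Stands in for an unmeasured colour-target: `n` smooth, diverse,
#' skin-plausible reflectance spectra. Spectra are built from a fixed
#' 8-function smooth dictionary (constant, melanin-like slope, the two
#' hemoglobin dips, a broad red bump, a sigmoid edge and two low-amplitude
#' cosine textures) whose coefficients are smooth functions of three latent
#' variables, so the set lies near a low-dimensional manifold: a 6-component
#' PCA explains over 99 percent of its variance while at least 6 components
#' remain non-negligible -- the regime in which colour-to-spectrum
#' regression is well posed.
#'
#' @param n number of spectra (at least 12; default 24).
#' @param seed integer seed.
#' @param grid the shared grid.
#' @return n x 401 matrix of reflectance spectra.
#' @export
make_calibration_set <- function(n = 24, seed = 1134, grid = spectral_grid()) {
  if (n < 12) stop("n must be at least 12")
  wl <- grid_wavelengths(grid)
  t <- (wl - 380) / 400
  dip1 <- exp(-(wl - 420)^2 / (2 * 15^2))
  dip2 <- exp(-(wl - 545)^2 / (2 * 20^2))
  bump <- exp(-(wl - 630)^2 / (2 * 60^2))
  edge <- 1 / (1 + exp(-(wl - 580) / 25))
  cos1 <- cos(2 * pi * t)
  cos2 <- cos(4 * pi * t)
  with_seed(seed, {
    # three latent axes: u = brightness, v = melanin-like slope, w = total
    # hemoglobin; the Soret/Q depth ratio is fixed up to a mild
    # brightness-linked oxygenation tilt, as in lightly pigmented skin
    u <- stats::runif(n); v <- stats::runif(n); w <- stats::runif(n)
    S <- matrix(0, n, grid$n)
    for (i in seq_len(n)) {
      s <- (0.25 + 0.45 * u[i]) +
        0.30 * (v[i] - 0.5) * t -
        0.40 * w[i] * dip1 -
        0.24 * w[i] * (0.6 + 0.4 * u[i]) * dip2 +
        0.12 * u[i] * v[i] * bump +
        0.10 * (u[i] - v[i]) * edge +
        0.020 * (u[i] * w[i] - 0.25) * cos1 +
        0.012 * (v[i] * w[i] - 0.25) * cos2
      S[i, ] <- pmin(pmax(s, 0.01), REFLECTANCE_MAX)
    }
    S
  })
}

#' Materialize detections realizing a target confusion matrix
#'
#' Inverse of [match_and_count()]: for any valid extended confusion matrix
#' it constructs ground truths and detections whose evaluation under the
#' default thresholds reproduces the matrix cell for cell. Each counted unit
#' gets its own 64 x 64 box on a non-overlapping grid (one image per unit),
#' so greedy matching is unambiguous: a lesion-lesion cell `(p, t)` yields a
#' perfectly overlapping pair (IoU 1, confidence 0.9); `(p, background)` a
#' detection on empty canvas; `(background, t)` an unmatched ground truth.
#'
#' @param m an `extended_confusion_matrix` (background-background must be 0).
#' @param geometry_seed seed reserved for future jittered layouts (the
#'   default grid layout is deterministic).
#' @return List with `detections` and `ground_truth` data.frames.
#' @export
detections_from_matrix <- function(m, geometry_seed = 1) {
  stopifnot(inherits(m, "extended_confusion_matrix"))
  K <- length(m$class_labels)
  counts <- m$counts
  # one unit (own image, fixed 64 x 64 box) per counted event, vectorized
  cell_p <- rep(rep(seq_len(K + 1), K + 1), as.vector(counts))
  cell_t <- rep(rep(seq_len(K + 1), each = K + 1), as.vector(counts))
  n_units <- length(cell_p)
  img <- sprintf("unit%05d", seq_len(n_units))
  has_det <- cell_p <= K
  has_gt <- cell_t <= K
  dets <- if (any(has_det)) as_detections(data.frame(
    image_id = img[has_det], class_index = cell_p[has_det] - 1L,
    confidence = 0.9, xmin = 10, ymin = 10, xmax = 74, ymax = 74))
  else empty_detections()
  gts <- if (any(has_gt)) as_ground_truth(data.frame(
    image_id = img[has_gt], class_index = cell_t[has_gt] - 1L,
    xmin = 10, ymin = 10, xmax = 74, ymax = 74))
  else empty_ground_truth()
  list(detections = dets, ground_truth = gts)
}

#' The printed reference confusion matrices
#'
#' The two published 3-class extended confusion matrices (RGB-trained and
#' narrow-band-trained detector on the same 384-image validation set) used
#' throughout the tests: row order BCC, SCC, SK, background-FN; column order
#' BCC, SCC, SK, background-FP.
#'
#' @param which `"rgb"` or `"hsi"`.
#' @return An `extended_confusion_matrix`.
#' @export
reference_confusion_matrix <- function(which = c("rgb", "hsi")) {
  which <- match.arg(which)
  counts <- if (which == "rgb") rbind(
    c(133, 7, 8, 45),
    c(6, 66, 0, 27),
    c(6, 1, 102, 54),
    c(23, 16, 16, 0)
  ) else rbind(
    c(102, 4, 19, 74),
    c(17, 72, 0, 10),
    c(6, 0, 100, 55),
    c(43, 14, 7, 0)
  )
  extended_confusion_matrix(counts, c("BCC", "SCC", "SK"))
}
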