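# Shared helpers for the test suite. Everything is generated in code; no
# binary fixtures.

GRID <- spectral_grid()
WL <- grid_wavelengths(GRID)

# n random smooth spectra (random Fourier series, shifted positive)
random_smooth_spectra <- function(n, seed = 1, n_terms = 4) {
  with_seed_test(seed, {
    t(vapply(seq_len(n), function(i) {
      tt <- (WL - 380) / 400
      s <- rep(stats::runif(1, 0.3, 0.7), length(WL))
      for (j in seq_len(n_terms))
        s <- s + stats::rnorm(1, sd = 0.08 / j) * cos(j * pi * tt + stats::runif(1, 0, 2 * pi))
      pmin(pmax(s, 0.01), 1.4)
    }, numeric(length(WL))))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random valid box in [0, lim]^2
random_box <- function(lim = 10) {
  x <- sort(stats::runif(2, 0, lim))
  y <- sort(stats::runif(2, 0, lim))
  while (x[1] == x[2]) x <- sort(stats::runif(2, 0, lim))
  while (y[1] == y[2]) y <- sort(stats::runif(2, 0, lim))
  c(x[1], y[1], x[2], y[2])
}

# random valid extended confusion matrix
random_confusion <- function(K = 3, max_count = 200, seed = NULL) {
  gen <- function() {
    counts <- matrix(sample(0:max_count, (K + 1)^2, replace = TRUE), K + 1, K + 1)
    counts[K + 1, K + 1] <- 0L
    extended_confusion_matrix(counts, paste0("C", seq_len(K)))
  }
  if (is.null(seed)) gen() else with_seed_test(seed, gen())
}

# fraction of a selected window covered by the designed window [lo, hi]
window_overlap <- function(w, lo, hi) {
  max(0, min(w$hi_nm, hi) - max(w$lo_nm, lo) + 1) / (w$hi_nm - w$lo_nm + 1)
}

# small standard scene used across tests
test_scene <- function(class_label = "BCC", canvas = 40, seed = 1134) {
  recipes <- default_class_recipes()
  scene_recipe(
    canvas = canvas,
    lesions = list(list(class_label = class_label,
                        center = c(canvas / 2, canvas / 2),
                        axes = c(canvas / 4, canvas / 6),
                        recipe = recipes[[class_label]])),
    seed = derive_seed(seed, class_label))
}
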