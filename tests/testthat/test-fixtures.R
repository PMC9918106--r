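test_that("make_class_spectra follows its recipe deterministically", {
  # noise-free: identical spectra with the designed dip
  rec <- spectrum_recipe(0.6, list(c(420, 15, 0.3)), noise_sd = 0)
  s <- make_class_spectra(rec, 3, "x", seed = 1)
  expect_equal(nrow(s$spectra), 3)
  expect_equal(s$spectra[1, ], s$spectra[2, ])
  expect_equal(WL[which.min(s$spectra[1, ])], 420)
  expect_equal(min(s$spectra[1, ]), 0.3, tolerance = 1e-9)
  # determinism
  rec2 <- spectrum_recipe(0.6, list(c(420, 15, 0.3)), noise_sd = 0.02)
  a <- make_class_spectra(rec2, 5, "x", seed = 7)
  b <- make_class_spectra(rec2, 5, "x", seed = 7)
  expect_identical(a$spectra, b$spectra)
  c <- make_class_spectra(rec2, 5, "x", seed = 8)
  expect_false(identical(a$spectra, c$spectra))
  # invalid recipes rejected
  expect_error(spectrum_recipe(0.2, list(c(420, 15, 0.3))), "depth")
  expect_error(spectrum_recipe(0.6, list(c(900, 15, 0.3))), "off the grid")
  expect_error(spectrum_recipe(-0.1), "non-negative")
  expect_error(make_class_spectra(rec, 0), "at least 1")
})

test_that("generated spectra satisfy the shared-type invariants", {
  recipes <- default_class_recipes()
  for (nm in names(recipes)) {
    s <- make_class_spectra(recipes[[nm]], 5, nm, seed = 11)
    expect_equal(ncol(s$spectra), 401)
    expect_true(all(s$spectra >= 0))
    expect_true(all(s$spectra <= 1.5))
    expect_equal(s$mean_spectrum, colMeans(s$spectra))
  }
})

test_that("render_scene places boxes by ellipse extent and composes the forward model", {
  recipes <- default_class_recipes()
  rec <- scene_recipe(canvas = 160,
                      lesions = list(list(class_label = "BCC",
                                          center = c(100, 100), axes = c(40, 20),
                                          recipe = recipes$BCC)),
                      seed = 5)
  sc <- render_scene(rec)
  expect_equal(as.numeric(sc$annotation$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(60, 80, 140, 120))
  expect_equal(dim(sc$image), c(160, 160, 3))
  expect_equal(sc$cube$grid$n, 401L)
  # zero-contrast scene: constant RGB, boxes still emitted
  flat_rec <- spectrum_recipe(0.5, list(), noise_sd = 0)
  z <- render_scene(scene_recipe(canvas = 16,
    lesions = list(list(class_label = "BCC", center = c(8, 8), axes = c(4, 4),
                        recipe = flat_rec)),
    background_recipe = flat_rec, seed = 1))
  expect_equal(diff(range(z$image)), 0)
  expect_equal(nrow(z$annotation$boxes), 1)
  # rendered background equals the quantized forward model of its spectrum
  bg_direct <- xyz_to_srgb(spectrum_to_xyz(recipe_mean_spectrum(flat_rec)))
  expect_equal(z$image[1, 1, ], round(unname(bg_direct[1:3]) * 255) / 255)
  # bit-reproducible given the seed
  s1 <- render_scene(test_scene("SCC", canvas = 24))
  s2 <- render_scene(test_scene("SCC", canvas = 24))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$cube$values, s2$cube$values)
  expect_error(scene_recipe(canvas = 20, lesions = list(
    list(class_label = "a", center = c(5, 5), axes = c(10, 10),
         recipe = flat_rec))), "outside the canvas")
})

test_that("calibration set has the documented low-dimensional structure", {
  calib <- make_calibration_set(24, seed = 1134)
  expect_equal(dim(calib), c(24, 401))
  expect_true(all(calib >= 0 & calib <= 1.5))
  sv <- svd(scale(calib, scale = FALSE))$d
  evr <- sv^2 / sum(sv^2)
  expect_gte(sum(evr[1:6]), 0.99)
  expect_gte(sum(evr > 1e-6), 6)  # at least 6 non-negligible components
  other <- make_calibration_set(24, seed = 99)
  expect_false(identical(calib, other))
  sv2 <- svd(scale(other, scale = FALSE))$d
  expect_gte(sum((sv2^2 / sum(sv2^2))[1:6]), 0.99)  # same summary structure
  expect_error(make_calibration_set(6), "at least 12")
})

test_that("detections_from_matrix realizes diagonal and reference matrices", {
  # 3-class diagonal (5, 4, 6): 15 perfect pairs
  d <- extended_confusion_matrix(diag(c(5, 4, 6, 0)), c("A", "B", "C"))
  pair <- detections_from_matrix(d)
  expect_equal(nrow(pair$detections), 15)
  expect_equal(nrow(pair$ground_truth), 15)
  m2 <- match_and_count(pair$detections, pair$ground_truth,
                        class_labels = d$class_labels)
  expect_identical(m2$counts, d$counts)
  # reference matrix round trip with the published trace
  rgb <- reference_confusion_matrix("rgb")
  p2 <- detections_from_matrix(rgb)
  m3 <- match_and_count(p2$detections, p2$ground_truth,
                        class_labels = rgb$class_labels)
  expect_identical(m3$counts, rgb$counts)
  expect_equal(sum(diag(m3$counts)[1:3]), 301L)
  # background-background > 0 is rejected at construction
  bad <- diag(c(1, 1, 1, 0)); bad[4, 4] <- 2
  expect_error(extended_confusion_matrix(bad, c("A", "B", "C")),
               "background-background")
})

test_that("derive_seed fans out deterministic independent streams", {
  expect_identical(derive_seed(1, "a"), derive_seed(1, "a"))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  s <- derive_seed(2147483646, "calibration")
  expect_true(s >= 0 && s < 2^31)
})

test_that("rendered scene reconstructs within tolerance on the calibration manifold", {
  # the BCC-like class and the skin background lie on the calibration
  # manifold; at least 95% of pixels must reconstruct below 0.05 RMSE
  calib <- make_calibration_set(24, seed = derive_seed(1134, "calibration"))
  model <- fit_reconstruction_model(calib, k = 6)
  sc <- render_scene(test_scene("BCC", canvas = 40, seed = 1134))
  cube <- reconstruct_cube(sc$image, model)
  n_px <- sc$cube$height * sc$cube$width
  rmse <- sqrt(rowMeans((matrix(sc$cube$values, n_px, 401) -
                           matrix(cube$values, n_px, 401))^2))
  expect_gte(mean(rmse < 0.05), 0.95)
})

test_that("end-to-end pipeline recovers the designed windows from reconstructions", {
  calib <- make_calibration_set(24, seed = derive_seed(1134, "calibration"))
  model <- fit_reconstruction_model(calib, k = 6)
  roi <- list()
  for (cl in c("BCC", "SCC")) {
    sc <- render_scene(test_scene(cl, canvas = 40, seed = 1134))
    cube <- reconstruct_cube(sc$image, model)
    box <- as.numeric(sc$annotation$boxes[1, c("xmin", "ymin", "xmax", "ymax")])
    roi[[cl]] <- roi_mean_spectrum(cube, box)
  }
  sets <- list(class_spectrum_set("BCC", roi$BCC),
               class_spectrum_set("SCC", roi$SCC))
  wins <- select_windows(band_separation(sets), 31, 2)
  expect_gte(max(vapply(wins, window_overlap, 0, 405, 435)), 0.5)
  expect_gte(max(vapply(wins, window_overlap, 0, 525, 555)), 0.5)
})
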