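test_that("iou and giou match hand arithmetic", {
  b <- c(0, 0, 2, 2)
  expect_equal(iou(b, b), 1)
  expect_equal(giou(b, b), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  # disjoint with enclosing area 3, union 2
  expect_equal(giou(c(0, 0, 1, 1), c(2, 0, 3, 1)), -1 / 3)
  expect_error(iou(c(2, 0, 1, 1), b), "invalid box")
  # giou <= iou always
  with_seed_test(81, {
    for (i in 1:50) {
      a <- random_box(); c <- random_box()
      expect_lte(giou(a, c), iou(a, c) + 1e-12)
      expect_gt(giou(a, c), -1)
    }
  })
})

test_that("match_and_count handles perfect, empty and thresholded cases", {
  labels <- c("BCC", "SCC", "SK")
  gts <- as_ground_truth(data.frame(
    image_id = c("i1", "i1", "i2"), class_index = c(0L, 1L, 2L),
    xmin = c(0, 50, 0), ymin = c(0, 50, 0), xmax = c(10, 70, 20), ymax = c(10, 70, 20)))
  perfect <- cbind(gts[, 1:2], confidence = 0.9, gts[, 3:6])
  m <- match_and_count(perfect, gts, class_labels = labels)
  expect_equal(unname(diag(m$counts)), c(1L, 1L, 1L, 0L))
  expect_equal(sum(m$counts), 3L)
  # no detections: every ground truth lands in the background row
  m0 <- match_and_count(empty_detections(), gts, class_labels = labels)
  expect_equal(unname(m0$counts[4, 1:3]), c(1L, 1L, 1L))
  expect_equal(sum(m0$counts), 3L)
  # below-confidence detections are discarded
  weak <- perfect; weak$confidence <- 0.1
  mw <- match_and_count(weak, gts, class_labels = labels)
  expect_equal(mw$counts, m0$counts)
  expect_error(match_and_count(perfect, gts, iou_threshold = 1.5,
                               class_labels = labels), "\\(0, 1\\)")
  bad <- perfect; bad$class_index <- 5L
  expect_error(match_and_count(bad, gts, class_labels = labels), "0..K-1")
})

test_that("greedy matching prefers high IoU then earlier ground truth", {
  labels <- c("A", "B")
  # two ground truths; one detection overlapping both, more with the second
  gts <- as_ground_truth(data.frame(
    image_id = "i", class_index = c(0L, 1L),
    xmin = c(0, 4), ymin = 0, xmax = c(10, 14), ymax = 10))
  det <- as_detections(data.frame(
    image_id = "i", class_index = 0L, confidence = 0.9,
    xmin = 3, ymin = 0, xmax = 13, ymax = 10))
  m <- match_and_count(det, gts, iou_threshold = 0.2, class_labels = labels)
  expect_equal(m$counts[1, 2], 1L)  # matched the true-B box (higher IoU)
  expect_equal(m$counts[3, 1], 1L)  # true-A box missed
  # exact tie: earlier ground truth wins
  gts2 <- as_ground_truth(data.frame(
    image_id = "i", class_index = c(1L, 0L),
    xmin = c(0, 6), ymin = 0, xmax = c(10, 16), ymax = 10))
  det2 <- as_detections(data.frame(
    image_id = "i", class_index = 0L, confidence = 0.9,
    xmin = 3, ymin = 0, xmax = 13, ymax = 10))
  m2 <- match_and_count(det2, gts2, iou_threshold = 0.2, class_labels = labels)
  expect_equal(m2$counts[1, 2], 1L)  # tie broken toward gt index 1 (class B)
})

test_that("raising the confidence threshold never raises lesion-row counts", {
  m <- random_confusion(3, max_count = 30, seed = 83)
  pair <- detections_from_matrix(m)
  # jitter confidences deterministically so thresholds bite
  pair$detections$confidence <- with_seed_test(82,
    stats::runif(nrow(pair$detections), 0.3, 1))
  lo <- match_and_count(pair$detections, pair$ground_truth,
                        class_labels = m$class_labels,
                        confidence_threshold = 0.3)
  hi <- match_and_count(pair$detections, pair$ground_truth,
                        class_labels = m$class_labels,
                        confidence_threshold = 0.6)
  expect_true(all(hi$counts[1:3, ] <= lo$counts[1:3, ]))
})

test_that("conservation: column and row sums count ground truths and detections", {
  m <- random_confusion(3, max_count = 50, seed = 84)
  pair <- detections_from_matrix(m)
  m2 <- match_and_count(pair$detections, pair$ground_truth,
                        class_labels = m$class_labels)
  for (c in 1:3) {
    expect_equal(sum(m2$counts[, c]),
                 sum(pair$ground_truth$class_index == c - 1))
    expect_equal(sum(m2$counts[c, ]),
                 sum(pair$detections$class_index == c - 1))
  }
})

test_that("class_metrics on the identity matrix is all ones", {
  m <- extended_confusion_matrix(diag(c(5, 5, 5, 0)), c("A", "B", "C"))
  mt <- class_metrics(m)
  expect_equal(mt$precision, rep(1, 4))
  expect_equal(mt$recall, rep(1, 4))
  expect_equal(mt$specificity, rep(1, 4))
  expect_equal(mt$f1, rep(1, 4))
  expect_equal(mt$accuracy[1], 1)
  expect_equal(attr(mt, "correct_count"), 15L)
})

test_that("reference matrices yield the published trace and BCC precision", {
  rgb <- reference_confusion_matrix("rgb")
  mt <- class_metrics(rgb)
  expect_equal(attr(mt, "correct_count"), 301L)
  expect_equal(attr(mt, "total_ground_truth"), 384L)
  bcc <- mt[mt$class == "BCC", ]
  expect_equal(round(bcc$precision, 3), 0.899)  # 133 / 148
  expect_equal(bcc$recall, 133 / 168)
  expect_equal(class_metrics(rgb)$accuracy[1], 301 / 384)
  hsi <- reference_confusion_matrix("hsi")
  expect_equal(attr(class_metrics(hsi), "correct_count"), 274L)
  # include-background convention widens the denominator
  mt_inc <- class_metrics(rgb, "include-background")
  expect_equal(mt_inc[mt_inc$class == "BCC", "precision"], 133 / 193)
})

test_that("zero denominators surface as NA, never 0", {
  counts <- rbind(c(0, 0, 0), c(0, 5, 0), c(3, 0, 0))  # class A never predicted
  m <- extended_confusion_matrix(counts, c("A", "B"))
  mt <- class_metrics(m)
  expect_true(is.na(mt[mt$class == "A", "precision"]))
  expect_true(is.na(mt[mt$class == "A", "f1"]))
  expect_false(is.na(mt[mt$class == "B", "precision"]))
})

test_that("f1_from_pr matches the published class rows", {
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(round(f1_from_pr(0.899, 0.747), 3), 0.816)
  expect_equal(round(f1_from_pr(0.746, 0.794), 3), 0.769)
  expect_true(is.na(f1_from_pr(0, 0)))
})

test_that("extended_confusion_matrix validates its contract", {
  expect_error(extended_confusion_matrix(matrix(1, 4, 4), c("A", "B", "C")),
               "background-background")
  expect_error(extended_confusion_matrix(matrix(-1, 4, 4), c("A", "B", "C")),
               "non-negative")
  expect_error(extended_confusion_matrix(matrix(0, 3, 3), c("A", "B", "C")),
               "K \\+ 1")
})

test_that("detections and metrics CSV round-trips preserve records", {
  m <- reference_confusion_matrix("rgb")
  pair <- detections_from_matrix(m)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(pair$detections, f1)
  write_ground_truth_csv(pair$ground_truth, f2)
  expect_equal(read_detections_csv(f1), pair$detections)
  expect_equal(read_ground_truth_csv(f2), pair$ground_truth)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(m, f3)
  back <- utils::read.csv(f3, row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(m$counts) + 0)
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(class_metrics(m), f4)
  mt <- utils::read.csv(f4)
  expect_equal(mt$correct_count[1], 301L)
})
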