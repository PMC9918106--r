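boxes_df <- function(...) {
  m <- rbind(...)
  data.frame(class_label = m[, 1], xmin = as.numeric(m[, 2]),
             ymin = as.numeric(m[, 3]), xmax = as.numeric(m[, 4]),
             ymax = as.numeric(m[, 5]))
}

test_that("annotated_image enforces box invariants", {
  expect_error(annotated_image("a", 100, 100,
                               boxes_df(c("x", 10, 10, 5, 20))), "violate")
  expect_error(annotated_image("a", 100, 100,
                               boxes_df(c("x", 10, 10, 120, 20))), "violate")
  expect_error(annotated_image("a", 100, 100, boxes_df(c("zz", 1, 1, 5, 5)),
                               class_list = c("a", "b")), "class list")
  it <- annotated_image("a", 100, 100, boxes_df(c("x", 0, 0, 100, 100)))
  expect_s3_class(it, "annotated_image")
})

test_that("resize_with_boxes scales per axis and drops degenerate boxes", {
  it640 <- annotated_image("a", 640, 640, boxes_df(c("x", 100, 100, 300, 300)))
  r <- resize_with_boxes(it640, 640)
  expect_equal(r$boxes[, 2:5], it640$boxes[, 2:5])

  it <- annotated_image("a", 1280, 1280, boxes_df(c("x", 100, 100, 300, 300)))
  r <- resize_with_boxes(it, 640)
  expect_equal(as.numeric(r$boxes[1, 2:5]), c(50, 50, 150, 150))

  wide <- annotated_image("a", 1280, 640, boxes_df(c("x", 100, 100, 300, 300)))
  rw <- resize_with_boxes(wide, 640)
  expect_equal(as.numeric(rw$boxes[1, 2:5]), c(50, 100, 150, 300))

  tiny <- annotated_image("a", 1280, 1280, boxes_df(c("x", 100, 100, 101, 101)))
  expect_warning(rt <- resize_with_boxes(tiny, 640), "degenerate")
  expect_equal(nrow(rt$boxes), 0)
  expect_error(resize_with_boxes(it640, 16), "at least 32")
})

test_that("letterbox resize preserves aspect ratio and offsets boxes", {
  img <- array(0.5, c(100, 200, 3))
  it <- annotated_image("a", 200, 100, boxes_df(c("x", 0, 0, 200, 100)),
                        image = img)
  r <- resize_with_boxes(it, 640, letterbox = TRUE)
  expect_equal(dim(r$image), c(640, 640, 3))
  # 200x100 -> 640x320, centred vertically at offset 160
  expect_equal(as.numeric(r$boxes[1, 2:5]), c(0, 160, 640, 480))
})

test_that("voc_to_yolo and yolo_to_voc are exact inverses", {
  expect_equal(unname(voc_to_yolo(c(0, 0, 640, 640), 640, 640)),
               c(0.5, 0.5, 1, 1))
  expect_equal(unname(voc_to_yolo(c(160, 160, 480, 480), 640, 640)),
               c(0.5, 0.5, 0.5, 0.5))
  expect_error(voc_to_yolo(c(100, 100, 50, 200), 640, 640), "inverted")
  with_seed_test(71, {
    for (i in 1:20) {
      b <- round(random_box(480))
      if (b[1] == b[3] || b[2] == b[4]) next
      y <- voc_to_yolo(b, 640, 480)
      expect_equal(unname(yolo_to_voc(y, 640, 480)), unname(b), tolerance = 0.5)
    }
  })
})

test_that("split_dataset stratifies with the documented rounding", {
  mk <- function(cl, n) lapply(seq_len(n), function(i)
    annotated_image(paste0(cl, i), 64, 64, boxes_df(c(cl, 1, 1, 10, 10))))
  items <- c(mk("BCC", 654), mk("SCC", 336), mk("SK", 480))
  sp <- split_dataset(items, 0.8, seed = 7)
  lab <- function(set) table(vapply(set, function(it) it$boxes$class_label[1], ""))
  tr <- lab(sp$train)
  expect_equal(as.integer(tr[c("BCC", "SCC", "SK")]), c(523, 269, 384))
  expect_equal(length(sp$train) + length(sp$test), length(items))
  ids <- c(vapply(sp$train, `[[`, "", "image_id"),
           vapply(sp$test, `[[`, "", "image_id"))
  expect_equal(anyDuplicated(ids), 0L)

  # determinism and seed sensitivity
  items10 <- mk("BCC", 10)
  s1 <- split_dataset(items10, 0.8, seed = 1)
  expect_length(s1$train, 8); expect_length(s1$test, 2)
  s1b <- split_dataset(items10, 0.8, seed = 1)
  expect_identical(vapply(s1$train, `[[`, "", "image_id"),
                   vapply(s1b$train, `[[`, "", "image_id"))
  seeds <- vapply(1:20, function(sd) paste(sort(vapply(
    split_dataset(items10, 0.8, seed = sd)$train, `[[`, "", "image_id")),
    collapse = ","), "")
  expect_gt(length(unique(seeds)), 1)  # membership varies across seeds
  expect_error(split_dataset(items10, 0.8), "seed")
  expect_error(split_dataset(items10, 1.2, seed = 1), "\\(0, 1\\)")
  expect_error(split_dataset(c(items10, mk("SCC", 1)), 0.8, seed = 1),
               "at least 2")
})

test_that("VOC XML round-trips through the 1-based inclusive dialect", {
  it <- annotated_image("img1.png", 640, 480,
                        boxes_df(c("BCC", 10, 20, 110, 220),
                                 c("SK", 0, 0, 640, 480)))
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(it, path)
  back <- read_voc_xml(path)
  expect_equal(back$width, 640L)
  expect_equal(back$height, 480L)
  expect_equal(back$boxes$xmin, it$boxes$xmin)
  expect_equal(back$boxes$xmax, it$boxes$xmax)
  expect_equal(back$boxes$ymin, it$boxes$ymin)
  expect_equal(back$boxes$ymax, it$boxes$ymax)
  expect_equal(back$boxes$class_label, it$boxes$class_label)
  # raw XML uses 1-based xmin
  xml <- xml2::read_xml(path)
  expect_equal(xml2::xml_text(xml2::xml_find_first(xml, "//bndbox/xmin")), "11")
})

test_that("YOLO txt labels satisfy the coordinate invariants and round-trip", {
  classes <- c("BCC", "SCC", "SK")
  it <- annotated_image("img", 640, 640,
                        boxes_df(c("SCC", 160, 160, 480, 480),
                                 c("BCC", 0, 0, 640, 640)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_yolo_txt(it, path, classes)
  lines <- readLines(path)
  expect_equal(lines[1], "1 0.500000 0.500000 0.500000 0.500000")
  df <- read_yolo_txt(path)
  expect_equal(df$class_index, c(1L, 0L))
  expect_true(all(df$cx > 0 & df$cx <= 1 & df$w > 0 & df$w <= 1))
  expect_true(all(df$cx - df$w / 2 >= -1e-6 & df$cx + df$w / 2 <= 1 + 1e-6))
  # labels for every generated scene satisfy the invariants too
  sc <- render_scene(test_scene("SCC", canvas = 32))
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_yolo_txt(sc$annotation, p2, classes)
  df2 <- read_yolo_txt(p2)
  expect_true(all(df2[, 2:5] > 0 & df2[, 2:5] <= 1))
  expect_error(write_yolo_txt(it, path, c("A", "B")), "missing from class_list")
})

test_that("class-list files define index order", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_class_list(c("BCC", "SCC", "SK"), path)
  expect_equal(read_class_list(path), c("BCC", "SCC", "SK"))
})
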