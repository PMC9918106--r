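#' Annotated image container
#'
#' An image identifier, its pixel dimensions, and its bounding boxes in the
#' internal convention: 0-based, half-open `[xmin, xmax) x [ymin, ymax)`
#' pixel coordinates with `0 <= xmin < xmax <= width` (and likewise for y).
#'
#' @param image_id character identifier.
#' @param width,height image size in pixels.
#' @param boxes data.frame with columns `class_label`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (may have zero rows).
#' @param class_list optional character vector restricting legal labels.
#' @param image optional H x W x 3 pixel array carried alongside.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, width, height, boxes,
                            class_list = NULL, image = NULL) {
  stopifnot(length(image_id) == 1, width >= 1, height >= 1)
  need <- c("class_label", "xmin", "ymin", "xmax", "ymax")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop("boxes must be a data.frame with columns ", paste(need, collapse = ", "))
  if (nrow(boxes) > 0) {
    with(boxes, {
      if (any(xmin < 0) || any(ymin < 0) || any(xmax > width) || any(ymax > height) ||
          any(xmin >= xmax) || any(ymin >= ymax))
        stop("box coordinates violate 0 <= min < max <= size")
    })
    if (!is.null(class_list) && !all(boxes$class_label %in% class_list))
      stop("box class labels outside the configured class list")
  }
  if (!is.null(image)) {
    image <- as_rgb_image(image)
    if (!all(dim(image)[1:2] == c(height, width)))
      stop("image array dimensions disagree with width/height")
  }
  structure(list(image_id = as.character(image_id), width = as.integer(width),
                 height = as.integer(height),
                 boxes = boxes[, need, drop = FALSE],
                 class_list = class_list, image = image),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %s: %d x %d, %d boxes%s\n",
              x$image_id, x$width, x$height, nrow(x$boxes),
              if (is.null(x$image)) " (no pixels)" else ""))
  invisible(x)
}

# Bilinear resize of an H x W (x C) numeric array.
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (length(d) == 2) img <- array(img, c(d, 1))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  # sample at pixel centres
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, nc))
  for (k in seq_len(nc)) {
    p <- img[, , k]
    a <- p[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- p[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    cc <- p[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    dd <- p[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    wa <- (1 - fy) %o% (1 - fx); wb <- (1 - fy) %o% fx
    wc <- fy %o% (1 - fx); wd <- fy %o% fx
    out[, , k] <- wa * matrix(a, out_h) + wb * matrix(b, out_h) +
      wc * matrix(cc, out_h) + wd * matrix(dd, out_h)
  }
  if (length(d) == 2) out[, , 1] else out
}

#' Resize an annotated image to a square canvas
#'
#' Direct (anisotropic) resampling to `target x target` pixels; box
#' coordinates are scaled by the same per-axis factors and rounded to
#' integers. A box whose area collapses to zero after rounding is dropped
#' with a warning. Letterboxing (aspect-preserving resize with padding) is
#' available as an option since one-stage detectors often use it internally.
#'
#' @param item an `annotated_image`.
#' @param target output edge length in pixels (default 640).
#' @param letterbox if TRUE, preserve aspect ratio and pad with `pad_value`.
#' @param pad_value gray level used for letterbox padding.
#' @return The resized `annotated_image`.
#' @export
resize_with_boxes <- function(item, target = 640, letterbox = FALSE,
                              pad_value = 0.5) {
  stopifnot(inherits(item, "annotated_image"))
  if (target < 32) stop("target size must be at least 32 pixels")
  target <- as.integer(target)
  if (letterbox) {
    s <- min(target / item$width, target / item$height)
    new_w <- max(1L, as.integer(round(item$width * s)))
    new_h <- max(1L, as.integer(round(item$height * s)))
    off_x <- (target - new_w) %/% 2L
    off_y <- (target - new_h) %/% 2L
    sx <- new_w / item$width; sy <- new_h / item$height
  } else {
    sx <- target / item$width; sy <- target / item$height
    off_x <- off_y <- 0L
    new_w <- new_h <- target
  }
  b <- item$boxes
  if (nrow(b) > 0) {
    b$xmin <- round(b$xmin * sx) + off_x
    b$xmax <- round(b$xmax * sx) + off_x
    b$ymin <- round(b$ymin * sy) + off_y
    b$ymax <- round(b$ymax * sy) + off_y
    degenerate <- b$xmax <= b$xmin | b$ymax <= b$ymin
    if (any(degenerate)) {
      warning(sprintf("dropped %d degenerate box(es) after resizing %s",
                      sum(degenerate), item$image_id))
      b <- b[!degenerate, , drop = FALSE]
    }
    b$xmax <- pmin(b$xmax, target); b$ymax <- pmin(b$ymax, target)
  }
  img <- NULL
  if (!is.null(item$image)) {
    resized <- resize_bilinear(item$image, new_h, new_w)
    if (letterbox) {
      img <- array(pad_value, c(target, target, 3))
      img[off_y + seq_len(new_h), off_x + seq_len(new_w), ] <- resized
    } else img <- resized
  }
  annotated_image(item$image_id, target, target, b, item$class_list, img)
}

#' Convert boxes between VOC-pixel and YOLO-normalized form
#'
#' YOLO labels store the box centre and size normalized by the image
#' dimensions: `cx = (xmin + xmax) / 2 / W`, `w = (xmax - xmin) / W`, and
#' likewise for y/h. `yolo_to_voc()` inverts the mapping back to pixels
#' (round-trip accurate to under half a pixel).
#'
#' @param box length-4 numeric `c(xmin, ymin, xmax, ymax)` (internal
#'   convention) or a data.frame of such boxes.
#' @param image_width,image_height image size in pixels.
#' @return `voc_to_yolo()`: named numeric `c(cx, cy, w, h)` (or a matrix);
#'   all coordinates in `(0, 1]`.
#' @export
voc_to_yolo <- function(box, image_width, image_height) {
  B <- if (is.data.frame(box)) as.matrix(box[, c("xmin", "ymin", "xmax", "ymax")])
  else matrix(box, ncol = 4)
  if (any(B[, 3] <= B[, 1]) || any(B[, 4] <= B[, 2])) stop("inverted box")
  out <- cbind(cx = (B[, 1] + B[, 3]) / 2 / image_width,
               cy = (B[, 2] + B[, 4]) / 2 / image_height,
               w = (B[, 3] - B[, 1]) / image_width,
               h = (B[, 4] - B[, 2]) / image_height)
  if (any(out <= 0) || any(out > 1 + 1e-6))
    stop("normalized coordinates left (0, 1]")
  if (nrow(out) == 1 && !is.data.frame(box)) out[1, ] else out
}

#' @rdname voc_to_yolo
#' @param yolo length-4 numeric `c(cx, cy, w, h)` or a matrix.
#' @export
yolo_to_voc <- function(yolo, image_width, image_height) {
  Y <- if (is.matrix(yolo)) yolo else matrix(yolo, ncol = 4)
  out <- cbind(xmin = (Y[, 1] - Y[, 3] / 2) * image_width,
               ymin = (Y[, 2] - Y[, 4] / 2) * image_height,
               xmax = (Y[, 1] + Y[, 3] / 2) * image_width,
               ymax = (Y[, 2] + Y[, 4] / 2) * image_height)
  if (nrow(out) == 1 && !is.matrix(yolo)) out[1, ] else out
}

#' Stratified train/test split
#'
#' Splits annotated images into train and test sets stratified by each
#' image's majority box class: per class, `round(train_fraction * n_class)`
#' items go to training. Deterministic given the seed; disjoint and
#' exhaustive by construction.
#'
#' @param items list of `annotated_image` objects.
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.8).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return List with elements `train` and `test` (lists of items).
#' @export
split_dataset <- function(items, train_fraction = 0.8, seed) {
  if (missing(seed)) stop("seed is required for a reproducible split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  labels <- vapply(items, majority_class, "")
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs at least 2 items to stratify: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in sort(names(counts))) {
      idx <- which(labels == cl)
      n_train <- round(train_fraction * length(idx))
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  list(train = items[sort(train_idx)],
       test = items[sort(setdiff(seq_along(items), train_idx))])
}

majority_class <- function(item) {
  if (nrow(item$boxes) == 0) return("(background)")
  tab <- table(item$boxes$class_label)
  names(tab)[which.max(tab)]  # ties -> alphabetically first
}

#' Read / write Pascal-VOC XML annotations
#'
#' VOC XML stores 1-based inclusive pixel coordinates (the dialect emitted by
#' common annotation tools); on read they are converted to the internal
#' 0-based half-open convention (`xmin - 1`, `xmax` unchanged), and the
#' writer emits the same dialect back.
#'
#' @param path XML file path.
#' @param class_list optional label whitelist.
#' @return `read_voc_xml()`: an `annotated_image` (without pixels).
#' @export
read_voc_xml <- function(path, class_list = NULL) {
  doc <- xml2::read_xml(path)
  num <- function(node, xp) as.numeric(xml2::xml_text(xml2::xml_find_first(node, xp)))
  w <- num(doc, ".//size/width"); h <- num(doc, ".//size/height")
  id <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- do.call(rbind, lapply(objs, function(o) data.frame(
    class_label = xml2::xml_text(xml2::xml_find_first(o, "./name")),
    xmin = num(o, "./bndbox/xmin") - 1,
    ymin = num(o, "./bndbox/ymin") - 1,
    xmax = num(o, "./bndbox/xmax"),
    ymax = num(o, "./bndbox/ymax"))))
  if (is.null(boxes))
    boxes <- data.frame(class_label = character(0), xmin = numeric(0),
                        ymin = numeric(0), xmax = numeric(0), ymax = numeric(0))
  annotated_image(id, w, h, boxes, class_list)
}

#' @rdname read_voc_xml
#' @param item an `annotated_image`.
#' @export
write_voc_xml <- function(item, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", item$image_id)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(item$width))
  xml2::xml_add_child(size, "height", as.character(item$height))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(item$boxes))) {
    b <- item$boxes[i, ]
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$class_label)
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(as.integer(b$xmin + 1)))
    xml2::xml_add_child(bb, "ymin", as.character(as.integer(b$ymin + 1)))
    xml2::xml_add_child(bb, "xmax", as.character(as.integer(b$xmax)))
    xml2::xml_add_child(bb, "ymax", as.character(as.integer(b$ymax)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write YOLO txt labels
#'
#' One line per box: `class_index cx cy w h`, 0-based class indices, six
#' fixed decimals, coordinates normalized by the image size.
#'
#' @param item an `annotated_image`.
#' @param path txt file path.
#' @param class_list character vector; its order defines the class indices.
#' @return `read_yolo_txt()`: data.frame with `class_index, cx, cy, w, h`.
#' @export
write_yolo_txt <- function(item, path, class_list) {
  lines <- character(0)
  if (nrow(item$boxes) > 0) {
    idx <- match(item$boxes$class_label, class_list) - 1L
    if (anyNA(idx)) stop("box class label missing from class_list")
    Y <- voc_to_yolo(item$boxes, item$width, item$height)
    Y <- if (is.matrix(Y)) Y else matrix(Y, ncol = 4)
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", idx, Y[, 1], Y[, 2], Y[, 3], Y[, 4])
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_txt
#' @export
read_yolo_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(class_index = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  parts <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(class_index = as.integer(parts[, 1]), cx = parts[, 2],
             cy = parts[, 3], w = parts[, 4], h = parts[, 5])
}

#' Read / write a class-list file
#'
#' One label per line; line order defines the 0-based class indices used in
#' YOLO labels.
#'
#' @param path file path.
#' @param class_list character vector of labels.
#' @return `read_class_list()`: character vector.
#' @export
read_class_list <- function(path) {
  cl <- trimws(readLines(path))
  cl[nzchar(cl)]
}

#' @rdname read_class_list
#' @export
write_class_list <- function(class_list, path) {
  writeLines(class_list, path)
  invisible(path)
}
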