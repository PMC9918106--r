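# Boxes are length-4 numerics c(xmin, ymin, xmax, ymax), 0-based half-open.
validate_box <- function(box) {
  b <- as.numeric(box)
  if (length(b) != 4 || anyNA(b) || b[1] >= b[3] || b[2] >= b[4])
    stop("invalid box: need xmin < xmax and ymin < ymax")
  b
}

box_area <- function(b) (b[3] - b[1]) * (b[4] - b[2])

#' Intersection over union of two boxes
#'
#' @param a,b length-4 boxes `c(xmin, ymin, xmax, ymax)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Generalized IoU of two boxes
#'
#' `GIoU = IoU - (A_c - U) / A_c`, where `A_c` is the area of the smallest
#' axis-aligned box enclosing both and `U` the union area. Values lie in
#' `(-1, 1]`, equal 1 exactly for identical boxes, and never exceed the IoU.
#'
#' @param a,b length-4 boxes.
#' @return GIoU value in `(-1, 1]`.
#' @export
giou <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- box_area(a) + box_area(b) - inter
  enc <- (max(a[3], b[3]) - min(a[1], b[1])) * (max(a[4], b[4]) - min(a[2], b[2]))
  inter / union - (enc - union) / enc
}

#' Detection and ground-truth records
#'
#' Detections and ground truths are plain data.frames. Detections carry
#' `image_id`, `class_index` (0-based), `confidence` in `[0, 1]` and box
#' columns `xmin, ymin, xmax, ymax`; ground truths the same minus
#' `confidence`. These constructors validate and normalize column order.
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame.
#' @export
as_detections <- function(df) {
  need <- c("image_id", "class_index", "confidence", "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(df))) stop("detections need columns ", paste(need, collapse = ", "))
  if (any(df$confidence < 0 | df$confidence > 1)) stop("confidence must be in [0, 1]")
  if (any(df$xmin >= df$xmax | df$ymin >= df$ymax)) stop("invalid detection box")
  df[, need, drop = FALSE]
}

#' @rdname as_detections
#' @export
as_ground_truth <- function(df) {
  need <- c("image_id", "class_index", "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(df))) stop("ground truth needs columns ", paste(need, collapse = ", "))
  if (any(df$xmin >= df$xmax | df$ymin >= df$ymax)) stop("invalid ground-truth box")
  df[, need, drop = FALSE]
}

empty_detections <- function() {
  as_detections(data.frame(image_id = character(0), class_index = integer(0),
                           confidence = numeric(0), xmin = numeric(0),
                           ymin = numeric(0), xmax = numeric(0), ymax = numeric(0)))
}

empty_ground_truth <- function() {
  as_ground_truth(data.frame(image_id = character(0), class_index = integer(0),
                             xmin = numeric(0), ymin = numeric(0),
                             xmax = numeric(0), ymax = numeric(0)))
}

#' Extended confusion matrix with background row and column
#'
#' A `(K + 1) x (K + 1)` count matrix for detection evaluation. Rows are the
#' predicted class, columns the true class. The last column ("background FP")
#' counts detections matched to no ground truth; the last row
#' ("background FN") counts ground truths matched by no detection. The
#' background-background cell is undefined for detection and fixed at 0.
#'
#' @param counts `(K + 1) x (K + 1)` non-negative integer matrix.
#' @param class_labels character vector of K lesion class names.
#' @return An object of class `extended_confusion_matrix`.
#' @export
extended_confusion_matrix <- function(counts, class_labels) {
  K <- length(class_labels)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == K + 1)) stop("counts must be (K + 1) x (K + 1)")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  if (counts[K + 1, K + 1] != 0) stop("background-background cell must be 0")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(predicted = c(class_labels, "background"),
                           true = c(class_labels, "background"))
  structure(list(counts = counts, class_labels = class_labels),
            class = "extended_confusion_matrix")
}

#' @export
print.extended_confusion_matrix <- function(x, ...) {
  K <- length(x$class_labels)
  cat("Extended confusion matrix (rows = predicted, columns = true)\n")
  disp <- x$counts
  rownames(disp)[K + 1] <- "Background FN"
  colnames(disp)[K + 1] <- "Background FP"
  print(disp)
  cat(sprintf("correct (trace over lesion classes): %d\n",
              sum(diag(x$counts)[seq_len(K)])))
  invisible(x)
}

#' Match detections to ground truth and count
#'
#' Per image: detections below `confidence_threshold` are discarded; the
#' remaining detections are matched greedily in order of descending
#' confidence to not-yet-matched ground truths with `IoU >=
#' iou_threshold`, preferring the highest IoU (ties broken toward the
#' earlier ground-truth index). Matching is class-agnostic: a matched pair
#' increments cell `(predicted class, true class)`; an unmatched detection
#' increments `(predicted class, background)`; an unmatched ground truth
#' increments `(background, true class)`.
#'
#' Defaults (IoU 0.45, confidence 0.25) follow the de-facto conventions of
#' one-stage-detector confusion-matrix tooling.
#'
#' @param dets detections data.frame (see [as_detections()]).
#' @param gts ground-truth data.frame (see [as_ground_truth()]).
#' @param iou_threshold minimum IoU for a match, in (0, 1).
#' @param confidence_threshold minimum detection confidence, in (0, 1).
#' @param class_labels character vector naming the K lesion classes;
#'   `class_index` values must lie in `0..K-1`.
#' @return An `extended_confusion_matrix`.
#' @export
match_and_count <- function(dets, gts, iou_threshold = 0.45,
                            confidence_threshold = 0.25, class_labels) {
  dets <- as_detections(dets)
  gts <- as_ground_truth(gts)
  if (iou_threshold <= 0 || iou_threshold >= 1 ||
      confidence_threshold <= 0 || confidence_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  K <- length(class_labels)
  if (nrow(dets) && (min(dets$class_index) < 0 || max(dets$class_index) >= K))
    stop("detection class_index outside 0..K-1")
  if (nrow(gts) && (min(gts$class_index) < 0 || max(gts$class_index) >= K))
    stop("ground-truth class_index outside 0..K-1")
  counts <- matrix(0L, K + 1, K + 1)
  dets <- dets[dets$confidence >= confidence_threshold, , drop = FALSE]
  # plain vectors/matrices (data-frame row access is too slow per image)
  d_box <- as.matrix(dets[, c("xmin", "ymin", "xmax", "ymax")])
  d_cls <- as.integer(dets$class_index)
  d_conf <- dets$confidence
  g_box <- as.matrix(gts[, c("xmin", "ymin", "xmax", "ymax")])
  g_cls <- as.integer(gts$class_index)
  images <- union(unique(dets$image_id), unique(gts$image_id))
  d_by <- split(seq_len(nrow(dets)), factor(dets$image_id, levels = images))
  g_by <- split(seq_len(nrow(gts)), factor(gts$image_id, levels = images))
  for (img in images) {
    di <- d_by[[img]]
    gi <- g_by[[img]]
    di <- di[order(-d_conf[di])]
    g_matched <- rep(FALSE, length(gi))
    for (i in di) {
      a <- d_box[i, ]
      best_j <- 0L; best_iou <- -1
      for (jj in seq_along(gi)) {
        if (g_matched[jj]) next
        b <- g_box[gi[jj], ]
        iw <- min(a[3], b[3]) - max(a[1], b[1])
        ih <- min(a[4], b[4]) - max(a[2], b[2])
        if (iw <= 0 || ih <= 0) next
        inter <- iw * ih
        v <- inter / ((a[3] - a[1]) * (a[4] - a[2]) +
                        (b[3] - b[1]) * (b[4] - b[2]) - inter)
        if (v >= iou_threshold && v > best_iou + 1e-12) {
          best_iou <- v; best_j <- jj
        }
      }
      p <- d_cls[i] + 1L
      if (best_j > 0L) {
        g_matched[best_j] <- TRUE
        t <- g_cls[gi[best_j]] + 1L
        counts[p, t] <- counts[p, t] + 1L
      } else {
        counts[p, K + 1] <- counts[p, K + 1] + 1L
      }
    }
    for (jj in which(!g_matched)) {
      t <- g_cls[gi[jj]] + 1L
      counts[K + 1, t] <- counts[K + 1, t] + 1L
    }
  }
  extended_confusion_matrix(counts, class_labels)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; `NA` (an explicit undefined marker) when
#' `P + R = 0`. Rounding to 3 decimals is a presentation concern and is left
#' to the caller.
#'
#' @param precision,recall fractions in `[0, 1]`.
#' @return The F1 score, or `NA` if undefined.
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Per-class and pooled detection metrics
#'
#' From an extended confusion matrix with rows-as-predicted, for lesion
#' class `c`:
#' \describe{
#'   \item{TP}{the diagonal cell `m[c, c]`.}
#'   \item{FP}{row sum over other lesion columns (convention
#'     `"exclude-background"`, default) or additionally the background-FP
#'     cell (`"include-background"`).}
#'   \item{FN}{column sum over all other rows (including background FN).}
#'   \item{TN}{total counted cells minus TP, FP and FN.}
#' }
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), specificity = TN/(TN+FP),
#' F1 = 2PR/(P+R). Overall accuracy = sum of diagonal cells divided by the
#' total over true-lesion columns (i.e. the number of ground-truth
#' instances), and `correct_count` is the diagonal sum itself. Any division
#' by zero yields `NA`, never a silent 0. Pooled ("All") precision, recall,
#' specificity and F1 are unweighted macro-averages over classes.
#'
#' @param m an `extended_confusion_matrix`.
#' @param precision_convention `"exclude-background"` or
#'   `"include-background"`.
#' @return An object of class `metrics_table`: data.frame with one row per
#'   class plus an `"All"` row, columns `class, precision, recall,
#'   specificity, f1, accuracy`; attributes `correct_count` and
#'   `total_ground_truth`.
#' @export
class_metrics <- function(m, precision_convention = c("exclude-background",
                                                      "include-background")) {
  precision_convention <- match.arg(precision_convention)
  stopifnot(inherits(m, "extended_confusion_matrix"))
  counts <- m$counts
  K <- length(m$class_labels)
  total <- sum(counts)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  rows <- lapply(seq_len(K), function(c) {
    tp <- counts[c, c]
    fp_lesion <- sum(counts[c, seq_len(K)]) - tp
    fp <- if (precision_convention == "include-background")
      fp_lesion + counts[c, K + 1] else fp_lesion
    fn <- sum(counts[, c]) - tp
    tn <- total - tp - fp - fn
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    data.frame(class = m$class_labels[c],
               precision = p, recall = r,
               specificity = safe_div(tn, tn + fp),
               f1 = f1_from_pr(p, r))
  })
  per_class <- do.call(rbind, rows)
  correct <- sum(diag(counts)[seq_len(K)])
  n_gt <- sum(counts[, seq_len(K)])
  accuracy <- if (n_gt > 0) correct / n_gt else NA_real_
  pooled <- data.frame(class = "All",
                       precision = mean(per_class$precision),
                       recall = mean(per_class$recall),
                       specificity = mean(per_class$specificity),
                       f1 = mean(per_class$f1))
  out <- rbind(pooled, per_class)
  out$accuracy <- c(accuracy, rep(NA_real_, K))
  structure(out, class = c("metrics_table", "data.frame"),
            correct_count = correct, total_ground_truth = n_gt,
            precision_convention = precision_convention)
}

#' @export
print.metrics_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("correct_count: %d of %d ground-truth instances (%s precision)\n",
              attr(x, "correct_count"), attr(x, "total_ground_truth"),
              attr(x, "precision_convention")))
  invisible(x)
}

#' Detections CSV input/output
#'
#' Plain CSV with columns `image_id, class_index, confidence, xmin, ymin,
#' xmax, ymax` (ground truth: the same without `confidence`).
#'
#' @param dets,gts data.frames (see [as_detections()]).
#' @param path CSV file path.
#' @return Readers return the validated data.frame.
#' @export
write_detections_csv <- function(dets, path) {
  utils::write.csv(as_detections(dets), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) as_detections(utils::read.csv(path))

#' @rdname write_detections_csv
#' @export
write_ground_truth_csv <- function(gts, path) {
  utils::write.csv(as_ground_truth(gts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_ground_truth_csv <- function(path) as_ground_truth(utils::read.csv(path))

#' Export an extended confusion matrix / metrics table as CSV
#'
#' @param m an `extended_confusion_matrix`.
#' @param metrics a `metrics_table`.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(m, path) {
  utils::write.csv(m$counts, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- as.data.frame(metrics)
  df$correct_count <- c(attr(metrics, "correct_count"),
                        rep(NA, nrow(df) - 1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
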