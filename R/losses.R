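#' Loss configuration
#'
#' Holds the confidence weight for object-free cells (`lambda_noobj`) and the
#' log-clamp floor `epsilon` that keeps the cross-entropy terms finite at
#' probabilities 0 and 1.
#'
#' @param lambda_noobj non-negative weight applied to the no-object
#'   confidence term (default 0.5, the conventional choice).
#' @param epsilon log-clamp floor, in `(0, 1e-3)`.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_noobj = 0.5, epsilon = 1e-7) {
  if (lambda_noobj < 0) stop("lambda_noobj must be non-negative")
  if (epsilon <= 0 || epsilon >= 1e-3) stop("epsilon must lie in (0, 1e-3)")
  structure(list(lambda_noobj = lambda_noobj, epsilon = epsilon),
            class = "loss_config")
}

#' Grid-cell assignments for loss evaluation
#'
#' One assignment records, for grid cell `i` and candidate box `j`: the
#' object indicator, predicted and target boxes, predicted and target
#' confidences, and per-class predicted/target probability vectors. This is
#' the minimal information the three loss terms consume; no network or
#' anchor machinery is involved.
#'
#' @param grid_index cell index `i` (0-based).
#' @param box_index box slot `j` within the cell (0-based).
#' @param has_object 1 if an object is assigned to this slot, else 0.
#' @param predicted_box,target_box length-4 boxes (may be `NULL` when
#'   `has_object = 0`).
#' @param predicted_confidence,target_confidence values in `[0, 1]`.
#' @param predicted_class_probs,target_class_probs per-class vectors in
#'   `[0, 1]` (targets are 0/1); may be `NULL` when `has_object = 0`.
#' @return An object of class `cell_assignment`.
#' @export
cell_assignment <- function(grid_index, box_index, has_object,
                            predicted_box = NULL, target_box = NULL,
                            predicted_confidence = 0, target_confidence = 0,
                            predicted_class_probs = NULL,
                            target_class_probs = NULL) {
  if (!has_object %in% c(0, 1)) stop("has_object must be 0 or 1")
  for (v in c(predicted_confidence, target_confidence,
              predicted_class_probs, target_class_probs))
    if (any(v < 0 | v > 1)) stop("probabilities must lie in [0, 1]")
  if (has_object == 1) {
    predicted_box <- validate_box(predicted_box)
    target_box <- validate_box(target_box)
  }
  structure(list(grid_index = grid_index, box_index = box_index,
                 has_object = has_object,
                 predicted_box = predicted_box, target_box = target_box,
                 predicted_confidence = predicted_confidence,
                 target_confidence = target_confidence,
                 predicted_class_probs = predicted_class_probs,
                 target_class_probs = target_class_probs),
            class = "cell_assignment")
}

clamp01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

bce <- function(target, predicted, eps) {
  p <- clamp01(predicted, eps)
  -(target * log(p) + (1 - target) * log(1 - p))
}

#' Bounding-box (GIoU) loss
#'
#' Sum over object-bearing assignments of `1 - GIoU(predicted, target)`,
#' i.e. `1 - IoU + (A_c - U)/A_c`. Object-free assignments contribute
#' nothing. Zero exactly when every predicted box equals its target.
#'
#' @param assignments list of `cell_assignment` objects.
#' @return Non-negative numeric loss.
#' @export
giou_loss <- function(assignments) {
  total <- 0
  for (a in assignments) {
    if (a$has_object == 1)
      total <- total + (1 - giou(a$predicted_box, a$target_box))
  }
  total
}

#' Confidence (objectness) loss
#'
#' Binary cross-entropy between predicted and target confidence over
#' object-bearing assignments, plus `lambda_noobj` times the same
#' cross-entropy over object-free assignments. Log arguments are clamped to
#' `[epsilon, 1 - epsilon]`.
#'
#' @param assignments list of `cell_assignment` objects.
#' @param config a `loss_config`.
#' @return Non-negative numeric loss.
#' @export
confidence_loss <- function(assignments, config = loss_config()) {
  total <- 0
  for (a in assignments) {
    term <- bce(a$target_confidence, a$predicted_confidence, config$epsilon)
    total <- total + if (a$has_object == 1) term else config$lambda_noobj * term
  }
  total
}

#' Classification loss
#'
#' Sum over object-bearing assignments and over classes of the binary
#' cross-entropy between target (0/1) and predicted class probabilities,
#' with the same epsilon clamp. The per-class independent-BCE form is the
#' standard one-stage-detector classification term; it is gated by the
#' object indicator.
#'
#' @param assignments list of `cell_assignment` objects.
#' @param config a `loss_config`.
#' @param n_classes expected class-vector length; defaults to the first
#'   object cell's length. A mismatched vector is an error.
#' @return Non-negative numeric loss.
#' @export
classification_loss <- function(assignments, config = loss_config(),
                                n_classes = NULL) {
  total <- 0
  for (a in assignments) {
    if (a$has_object != 1) next
    p <- a$predicted_class_probs
    t <- a$target_class_probs
    if (is.null(p) || is.null(t)) stop("object cell lacks class probability vectors")
    if (is.null(n_classes)) n_classes <- length(t)
    if (length(p) != n_classes || length(t) != n_classes)
      stop("class probability vector length mismatch")
    total <- total + sum(bce(t, p, config$epsilon))
  }
  total
}

#' Read loss assignments from a JSON fixture
#'
#' The fixture schema is a JSON array of objects with fields `grid_index`,
#' `box_index`, `has_object`, and (for object cells) `predicted_box`,
#' `target_box` (4-element arrays), `predicted_confidence`,
#' `target_confidence`, `predicted_class_probs`, `target_class_probs`.
#'
#' @param path JSON file path.
#' @return List of `cell_assignment` objects.
#' @export
read_assignments_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) cell_assignment(
    grid_index = r$grid_index %||% 0,
    box_index = r$box_index %||% 0,
    has_object = r$has_object,
    predicted_box = if (!is.null(r$predicted_box)) unlist(r$predicted_box),
    target_box = if (!is.null(r$target_box)) unlist(r$target_box),
    predicted_confidence = r$predicted_confidence %||% 0,
    target_confidence = r$target_confidence %||% 0,
    predicted_class_probs = if (!is.null(r$predicted_class_probs))
      unlist(r$predicted_class_probs),
    target_class_probs = if (!is.null(r$target_class_probs))
      unlist(r$target_class_probs)))
}
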