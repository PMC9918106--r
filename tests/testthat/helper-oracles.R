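# Independent naive oracles for the loss terms, coded separately from the
# implementation (shared by the module tests and the acceptance suite).

oracle_giou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  ac <- (max(a[3], b[3]) - min(a[1], b[1])) * (max(a[4], b[4]) - min(a[2], b[2]))
  inter / u - (ac - u) / ac
}

oracle_losses <- function(assignments, lambda = 0.5, eps = 1e-7) {
  cl <- function(p) min(max(p, eps), 1 - eps)
  lg <- lconf <- lcls <- 0
  for (a in assignments) {
    if (a$has_object == 1) {
      lg <- lg + 1 - oracle_giou(a$predicted_box, a$target_box)
      lconf <- lconf - (a$target_confidence * log(cl(a$predicted_confidence)) +
        (1 - a$target_confidence) * log(1 - cl(a$predicted_confidence)))
      for (c in seq_along(a$target_class_probs)) {
        p <- cl(a$predicted_class_probs[c]); t <- a$target_class_probs[c]
        lcls <- lcls - (t * log(p) + (1 - t) * log(1 - p))
      }
    } else {
      lconf <- lconf - lambda * (a$target_confidence * log(cl(a$predicted_confidence)) +
        (1 - a$target_confidence) * log(1 - cl(a$predicted_confidence)))
    }
  }
  list(giou = lg, conf = lconf, cls = lcls)
}

random_assignment <- function(i, n_classes = 3) {
  obj <- stats::runif(1) < 0.6
  tcls <- rep(0, n_classes); tcls[sample(n_classes, 1)] <- 1
  cell_assignment(
    grid_index = i, box_index = 0, has_object = as.integer(obj),
    predicted_box = if (obj) random_box(), target_box = if (obj) random_box(),
    predicted_confidence = stats::runif(1), target_confidence = as.integer(obj),
    predicted_class_probs = if (obj) stats::runif(n_classes),
    target_class_probs = if (obj) tcls)
}
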