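# Three-class patch classification. The deep-network stage of full-scale
# pipelines is represented by a contract -- predict_proba() rows sum to 1,
# deterministic, batch-order independent -- and fulfilled by a reference
# classifier: a multinomial logistic model on patch summary statistics
# (mean intensity, channel means, dark-blob density). All downstream
# computation depends only on the probability map, so any backend honoring
# the contract can be swapped in.

patch_classes <- c("tumor", "non_malignant", "white")

#' Summary features of a `[0, 1]`-scaled RGB patch
#'
#' Mean intensity, per-channel means, and the dark-pixel fraction (pixels
#' with intensity below 0.5), a proxy for nuclear blob density.
#'
#' @param patch array h x w x 3 with values in `[0, 1]`.
#' @return Named numeric vector of length 5.
#' @export
patch_summary_features <- function(patch) {
  if (length(dim(patch)) != 3L || dim(patch)[3L] != 3L)
    stop("patch must be an h x w x 3 array")
  if (max(patch) > 1 + 1e-9 || min(patch) < -1e-9)
    stop("patch must be scaled to [0, 1] (divide by 255)")
  inten <- (patch[, , 1L] + patch[, , 2L] + patch[, , 3L]) / 3
  c(mean_intensity = mean(inten),
    mean_r = mean(patch[, , 1L]),
    mean_g = mean(patch[, , 2L]),
    mean_b = mean(patch[, , 3L]),
    dark_frac = mean(inten < 0.5))
}

patch_feature_matrix <- function(patches) {
  t(vapply(patches, patch_summary_features, numeric(5L)))
}

#' Fit the reference patch classifier
#'
#' Multinomial logistic regression (with a small ridge penalty for
#' numerical stability on separable classes) on the [patch_summary_features()]
#' of the training patches.
#'
#' @param patches list of `[0, 1]`-scaled h x w x 3 arrays.
#' @param labels class label per patch; all three classes
#'   (tumor, non_malignant, white) must be present.
#' @return Object of class `"patch_classifier"`.
#' @export
fit_reference_classifier <- function(patches, labels) {
  labels <- factor(as.character(labels), levels = patch_classes)
  if (any(is.na(labels))) stop("labels must be tumor/non_malignant/white")
  if (any(table(labels) == 0L))
    stop("every class needs at least one training example")
  x <- patch_feature_matrix(patches)
  df <- data.frame(label = labels, x)
  fit <- nnet::multinom(label ~ ., data = df, trace = FALSE,
                        decay = 1e-3, maxit = 500)
  structure(list(fit = fit, classes = patch_classes,
                 feature_names = colnames(x)), class = "patch_classifier")
}

#' Predict 3-class probabilities for patches
#'
#' Contract: one row per patch, columns in the fixed order
#' (tumor, non_malignant, white), rows sum to 1, deterministic given the
#' model, and independent of batch order.
#'
#' @param model a [fit_reference_classifier()] result.
#' @param patches list of `[0, 1]`-scaled h x w x 3 arrays.
#' @return Numeric matrix n x 3.
#' @export
predict_proba <- function(model, patches) {
  stopifnot(inherits(model, "patch_classifier"))
  x <- patch_feature_matrix(patches)
  p <- stats::predict(model$fit, newdata = data.frame(x), type = "probs")
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  p <- p[, patch_classes, drop = FALSE]
  p <- p / rowSums(p)
  dimnames(p) <- list(NULL, patch_classes)
  p
}

#' Assemble patch predictions into a class-probability map
#'
#' Tissue cells of the grid receive their predicted probability rows in
#' row-major cell order; non-tissue cells are folded into the white class
#' with probability row (0, 0, 1), since white is the empty-region category
#' and only tissue patches are predicted.
#'
#' @param grid a [tile_grid()] result.
#' @param predictions matrix with one row per tissue cell (row-major order),
#'   class order (tumor, non_malignant, white).
#' @return Object of class `"class_prob_map"`: list with `probs`
#'   (n_rows x n_cols x 3 array) and `classes`.
#' @export
assemble_probability_map <- function(grid, predictions) {
  stopifnot(inherits(grid, "patch_grid"))
  tis <- which(t(grid$tissue))          # row-major order of tissue cells
  predictions <- as.matrix(predictions)
  if (nrow(predictions) != length(tis))
    stop("need exactly one prediction per tissue cell (",
         length(tis), " expected, ", nrow(predictions), " given)")
  probs <- array(0, c(grid$n_rows, grid$n_cols, 3L))
  probs[, , 3L] <- 1                    # default: white with probability 1
  if (length(tis)) {
    rows <- (tis - 1L) %/% grid$n_cols + 1L
    cols <- (tis - 1L) %% grid$n_cols + 1L
    for (k in 1:3) probs[cbind(rows, cols, k)] <- predictions[, k]
  }
  structure(list(probs = probs, classes = patch_classes),
            class = "class_prob_map")
}

#' Argmax label map from a probability map
#'
#' Per cell, the class with the highest probability; exact ties are broken
#' by the fixed priority tumor > non_malignant > white.
#'
#' @param prob_map a [assemble_probability_map()] result or a
#'   rows x cols x 3 array.
#' @return Object of class `"label_map"` with integer labels
#'   (0 = tumor, 1 = non_malignant, 2 = white).
#' @export
label_map_from_probs <- function(prob_map) {
  probs <- if (inherits(prob_map, "class_prob_map")) prob_map$probs else prob_map
  nr <- dim(probs)[1L]; nc <- dim(probs)[2L]
  flat <- cbind(as.vector(probs[, , 1L]), as.vector(probs[, , 2L]),
                as.vector(probs[, , 3L]))
  lab <- matrix(max.col(flat, ties.method = "first") - 1L, nr, nc)
  structure(list(labels = lab, classes = patch_classes,
                 truth = NULL, rim = NA_integer_), class = "label_map")
}

#' Classification accuracy and confusion matrix
#'
#' @param predicted,truth equal-length label vectors (or label matrices).
#' @return List with `overall`, `per_class` (named by class) and
#'   `confusion` (rows = truth, cols = predicted).
#' @export
evaluate_accuracy <- function(predicted, truth) {
  p <- as.character(unlist(predicted)); t <- as.character(unlist(truth))
  if (length(p) == 0L) stop("empty input")
  if (length(p) != length(t)) stop("length mismatch")
  lev <- union(patch_classes, union(unique(t), unique(p)))
  cm <- table(truth = factor(t, lev), predicted = factor(p, lev))
  per <- diag(cm) / rowSums(cm)
  list(overall = sum(diag(cm)) / length(t),
       per_class = per[rowSums(cm) > 0],
       confusion = cm)
}

#' Harvest labeled patches from a rendered slide
#'
#' Cuts a rendered slide back into per-cell patches, scaled to `[0, 1]`,
#' with their ground-truth class labels -- the training material for the
#' reference classifier.
#'
#' @param image rendered slide (0..255 array).
#' @param label_map the label map it was rendered from.
#' @param patch_size pixels per cell.
#' @return List with `patches` (list of arrays) and `labels` (character).
#' @export
harvest_patches <- function(image, label_map, patch_size) {
  labels <- as_label_matrix(label_map)
  grid <- tile_grid(dim(image)[1:2], patch_size)
  stopifnot(grid$n_rows == nrow(labels), grid$n_cols == ncol(labels))
  patches <- list(); labs <- character(0)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      patches[[length(patches) + 1L]] <- grid_patch(image, grid, i, j) / 255
      labs <- c(labs, patch_classes[labels[i, j] + 1L])
    }
  }
  list(patches = patches, labels = labs)
}
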