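# Pixel-level slide preparation: Otsu tissue masking, non-overlapping patch
# grids, the white-patch rule, stratified dataset splitting and flip
# augmentation. Images are numeric arrays height x width x 3 on the 0..255
# scale; patches are scaled to [0, 1] by dividing by 255 only at the
# classifier boundary.

#' Otsu threshold of a grayscale vector/matrix
#'
#' Exhaustive scan over the 256 integer candidate thresholds t: pixels are
#' split into (<= t) and (> t) classes and t* maximizes the between-class
#' variance; the smallest maximizer is returned.
#'
#' @param gray numeric values on the 0..255 scale.
#' @return Integer threshold in 0..255.
#' @export
otsu_threshold <- function(gray) {
  g <- pmin(pmax(as.integer(round(gray)), 0L), 255L)
  h <- tabulate(g + 1L, 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[256L]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mt - m0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  as.integer(which.max(bcv) - 1L)
}

#' Tissue mask of an RGB slide image
#'
#' Grayscale is the mean of the three channels; Otsu's threshold splits
#' tissue (darker, <= t*) from the near-white glass background; a binary
#' closing followed by an opening with a disk of `morph_radius` pixels
#' removes speckle and fills small gaps.
#'
#' @param image numeric array height x width x 3 (0..255) or a grayscale
#'   matrix.
#' @param morph_radius disk radius in pixels; 0 disables morphology.
#' @return Object of class `"tissue_mask"`: list with `mask` (logical
#'   matrix), `threshold` and `morph_radius`. A constant image yields an
#'   empty mask with a warning.
#' @export
tissue_mask <- function(image, morph_radius = 1) {
  gray <- if (length(dim(image)) == 3L) {
    (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  } else {
    as.matrix(image)
  }
  if (length(gray) == 0L) stop("image is empty")
  if (diff(range(gray)) == 0) {
    warning("constant image: returning empty tissue mask")
    return(structure(list(mask = matrix(FALSE, nrow(gray), ncol(gray)),
                          threshold = NA_integer_,
                          morph_radius = morph_radius),
                     class = "tissue_mask"))
  }
  t_star <- otsu_threshold(gray)
  mask <- gray <= t_star
  mask <- binary_opening(binary_closing(mask, morph_radius), morph_radius)
  structure(list(mask = mask, threshold = t_star,
                 morph_radius = morph_radius), class = "tissue_mask")
}

#' Non-overlapping patch grid over an image
#'
#' Cell (i, j) (1-based here) covers the half-open pixel window
#' rows ((i-1)s, is], cols ((j-1)s, js]; trailing remainder pixels at the
#' right/bottom edges are dropped. A cell is flagged tissue when more than
#' `tissue_frac` of its pixels are tissue (default 0: any tissue pixel).
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param patch_size window side s in pixels (>= 1).
#' @param mask optional [tissue_mask()] (or logical matrix) at image
#'   resolution.
#' @param tissue_frac fraction threshold (strict >).
#' @return Object of class `"patch_grid"`: `patch_size`, `n_rows`,
#'   `n_cols`, `tissue` (logical n_rows x n_cols matrix). A patch size
#'   exceeding an image dimension gives an empty grid with a warning.
#' @export
tile_grid <- function(image_shape, patch_size, mask = NULL, tissue_frac = 0) {
  s <- as.integer(patch_size)
  if (s < 1L) stop("patch_size must be >= 1")
  n_rows <- image_shape[1L] %/% s
  n_cols <- image_shape[2L] %/% s
  if (n_rows == 0L || n_cols == 0L) {
    warning("patch_size exceeds an image dimension: empty grid")
    n_rows <- n_cols <- 0L
  }
  tissue <- matrix(TRUE, n_rows, n_cols)
  if (!is.null(mask) && n_rows > 0L) {
    m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
    for (i in seq_len(n_rows)) {
      for (j in seq_len(n_cols)) {
        w <- m[(i - 1L) * s + seq_len(s), (j - 1L) * s + seq_len(s)]
        tissue[i, j] <- mean(w) > tissue_frac
      }
    }
  }
  structure(list(patch_size = s, n_rows = n_rows, n_cols = n_cols,
                 tissue = tissue), class = "patch_grid")
}

#' Extract the pixel patch of one grid cell
#' @param image numeric array height x width x (3).
#' @param grid a [tile_grid()] result.
#' @param i,j cell row/column (1-based).
#' @return The patch as an array/matrix on the input scale.
#' @export
grid_patch <- function(image, grid, i, j) {
  s <- grid$patch_size
  rows <- (i - 1L) * s + seq_len(s)
  cols <- (j - 1L) * s + seq_len(s)
  if (length(dim(image)) == 3L) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' White-patch rule
#'
#' A patch is white iff the mean over all its pixels and channels is
#' strictly greater than the threshold.
#'
#' @param patch numeric array/matrix on the 0..255 scale.
#' @param threshold intensity threshold (default 200; the exact value used
#'   on real slides is calibrated from sample images).
#' @return Logical flag.
#' @export
is_white_patch <- function(patch, threshold = 200) {
  if (length(patch) == 0L) stop("patch is empty")
  mean(patch) > threshold
}

#' Stratified train/validation/test allocation
#'
#' Per class c with n_c items: n_train = round-half-up(f_train * n_c),
#' n_test = floor(f_test * n_c), n_val = n_c - n_train - n_test. This
#' rounding convention conserves totals exactly (e.g. class counts
#' 2139/2475/730 under fractions 0.72/0.08/0.20 give totals 3848/428/1068).
#'
#' @param class_counts named integer vector of per-class item counts.
#' @param fractions `c(train, val, test)`, summing to 1.
#' @return Data frame with class, n, n_train, n_val, n_test.
#' @export
stratified_split <- function(class_counts, fractions = c(0.72, 0.08, 0.20)) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(class_counts < 0)) stop("counts must be >= 0")
  n <- as.integer(class_counts)
  n_train <- as.integer(floor(fractions[1L] * n + 0.5))   # half-up
  n_test <- as.integer(floor(fractions[3L] * n))
  n_val <- n - n_train - n_test
  if (any(n_val < 0)) stop("negative validation residual; check fractions")
  data.frame(class = if (is.null(names(class_counts)))
    as.character(seq_along(n)) else names(class_counts),
    n = n, n_train = n_train, n_val = n_val, n_test = n_test,
    stringsAsFactors = FALSE)
}

#' Assign items to splits by seeded shuffle within class
#'
#' @param labels class label per item.
#' @param fractions passed to [stratified_split()].
#' @param seed shuffle seed.
#' @return Factor with levels train/val/test aligned with `labels`.
#' @export
assign_split <- function(labels, fractions = c(0.72, 0.08, 0.20), seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  alloc <- stratified_split(as.integer(counts), fractions)
  alloc$class <- names(counts)
  out <- character(length(labels))
  with_seed(seed, {
    for (k in seq_len(nrow(alloc))) {
      idx <- which(labels == alloc$class[k])
      idx <- idx[sample.int(length(idx))]
      a <- alloc[k, ]
      out[idx[seq_len(a$n_train)]] <- "train"
      if (a$n_val > 0L) out[idx[a$n_train + seq_len(a$n_val)]] <- "val"
      if (a$n_test > 0L) out[idx[a$n_train + a$n_val + seq_len(a$n_test)]] <- "test"
    }
  })
  factor(out, levels = c("train", "val", "test"))
}

#' Horizontal/vertical flip augmentation
#'
#' Returns the four dihedral images under axis flips: identity, horizontal
#' flip (columns reversed), vertical flip (rows reversed), and both (a 180
#' degree rotation).
#'
#' @param patch matrix or height x width x channels array.
#' @return List of 4 patches named identity, flip_h, flip_v, flip_hv.
#' @export
augment_flips <- function(patch) {
  flip <- function(p, rows, cols) {
    if (length(dim(p)) == 3L) {
      p[if (rows) rev(seq_len(dim(p)[1L])) else seq_len(dim(p)[1L]),
        if (cols) rev(seq_len(dim(p)[2L])) else seq_len(dim(p)[2L]), ,
        drop = FALSE]
    } else {
      p[if (rows) rev(seq_len(nrow(p))) else seq_len(nrow(p)),
        if (cols) rev(seq_len(ncol(p))) else seq_len(ncol(p)), drop = FALSE]
    }
  }
  list(identity = patch, flip_h = flip(patch, FALSE, TRUE),
       flip_v = flip(patch, TRUE, FALSE), flip_hv = flip(patch, TRUE, TRUE))
}
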