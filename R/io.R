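# Plain-text artifact formats: numeric matrices as whitespace-separated
# text with JSON sidecars, label maps as integer matrices, slides as PNG.
# Text-first storage keeps every artifact diffable and language-portable.

#' Write / read a numeric matrix as plain text
#' @param m matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_txt <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write a label map as an integer matrix text file
#'
#' Codes: 0 = tumor, 1 = non_malignant, 2 = white, as everywhere in the
#' package.
#' @param label_map `label_map` object or integer matrix.
#' @param path file path.
#' @export
write_label_map <- function(label_map, path) {
  write_matrix_txt(as_label_matrix(label_map), path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- read_matrix_txt(path)
  storage.mode(m) <- "integer"
  structure(list(labels = m, classes = patch_classes, truth = NULL,
                 rim = NA_integer_), class = "label_map")
}

#' Write a class-probability map as three matrices plus a JSON sidecar
#'
#' One numeric matrix text file per class (suffix `_tumor.txt`,
#' `_non_malignant.txt`, `_white.txt`) and a `.json` sidecar recording the
#' class order and provenance.
#'
#' @param prob_map `class_prob_map` object.
#' @param stem path stem (no extension).
#' @param patch_size,source recorded in the sidecar.
#' @export
write_prob_map <- function(prob_map, stem, patch_size = NA, source = NA) {
  probs <- if (inherits(prob_map, "class_prob_map")) prob_map$probs else prob_map
  for (k in seq_along(patch_classes))
    write_matrix_txt(probs[, , k], paste0(stem, "_", patch_classes[k], ".txt"))
  jsonlite::write_json(list(classes = patch_classes,
                            patch_size = patch_size, source = source,
                            n_rows = dim(probs)[1L], n_cols = dim(probs)[2L]),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_prob_map
#' @export
read_prob_map <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  probs <- array(0, c(side$n_rows, side$n_cols, 3L))
  for (k in seq_along(patch_classes))
    probs[, , k] <- read_matrix_txt(paste0(stem, "_", patch_classes[k], ".txt"))
  structure(list(probs = probs, classes = patch_classes),
            class = "class_prob_map")
}

#' Write a rendered slide as PNG
#' @param image numeric array height x width x 3 on 0..255.
#' @param path file path.
#' @export
write_slide_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_slide_png
#' @export
read_slide_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] > 3L) img <- img[, , 1:3]
  img * 255
}
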