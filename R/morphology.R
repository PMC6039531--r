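# Segmentation of tissue samples and tumor regions from heatmap label maps.
# Everything is measured at heatmap-cell resolution (1 cell = one image
# patch). 8-connectivity is used for both tumor regions and holes; the
# checkerboard paradoxes this dual-8 convention admits are exercised in the
# test suite rather than papered over.

label_codes <- c(tumor = 0L, non_malignant = 1L, white = 2L)

as_label_matrix <- function(label_map) {
  if (inherits(label_map, "label_map")) label_map$labels else label_map
}

#' Segment tissue samples from a label map
#'
#' Tissue cells are those labeled tumor or non-malignant. A radius-1 binary
#' closing bridges 1-cell classification gaps, then 8-connected components
#' are found and components with area strictly smaller than half the largest
#' area are removed (areas measured after closing, before filtering).
#'
#' @param label_map a `label_map` object or integer label matrix
#'   (0 = tumor, 1 = non-malignant, 2 = white).
#' @param closing_radius radius of the closing disk; 0 disables it.
#' @return List of tissue regions, each a list with `id`, `cells`
#'   (row/col matrix in row-major order) and `area`; empty list (with a
#'   warning) when the map holds no tissue.
#' @export
segment_tissue_regions <- function(label_map, closing_radius = 1) {
  labels <- as_label_matrix(label_map)
  tissue <- labels == label_codes[["tumor"]] |
    labels == label_codes[["non_malignant"]]
  if (!any(tissue)) {
    warning("label map contains no tissue cells")
    return(list())
  }
  tissue <- binary_closing(tissue, closing_radius)
  cc <- connected_components(tissue, 8)
  keep <- which(!(cc$sizes < 0.5 * max(cc$sizes)))   # strict: < half dropped
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    id <- keep[i]
    out[[i]] <- list(id = i, cells = component_cells(cc$labels, id),
                     area = cc$sizes[id])
  }
  out
}

#' Extract tumor regions within one tissue sample
#'
#' 8-connected components of tumor-labeled cells restricted to the tissue
#' region. The largest component is flagged as the main tumor region; ties
#' are broken by the earlier first cell in row-major order (which is the
#' component discovery order).
#'
#' @param tissue one element of [segment_tissue_regions()].
#' @param label_map the label map the tissue came from.
#' @return List (possibly empty) of tumor regions: `id`, `tissue_id`,
#'   `cells`, `area`, `is_main`.
#' @export
extract_tumor_regions <- function(tissue, label_map) {
  labels <- as_label_matrix(label_map)
  inside <- matrix(FALSE, nrow(labels), ncol(labels))
  inside[tissue$cells] <- TRUE
  tum <- inside & labels == label_codes[["tumor"]]
  cc <- connected_components(tum, 8)
  if (cc$n == 0L) return(list())
  main <- which.max(cc$sizes)          # first max = earliest row-major
  lapply(seq_len(cc$n), function(id) {
    list(id = id, tissue_id = tissue$id,
         cells = component_cells(cc$labels, id),
         area = cc$sizes[id], is_main = id == main)
  })
}

#' Find holes of a region
#'
#' Holes are 8-connected components of background cells within the region's
#' bounding box padded by one cell that are not 8-connected to the pad
#' frame. Under this (paper-faithful) dual-8 convention a diagonal
#' "checkerboard" gap leaks to the outside and is not a hole.
#'
#' @param region a region list with a `cells` matrix, or the matrix itself.
#' @return List with `n_holes`, `hole_areas` and `total_hole_area`.
#' @export
find_holes <- function(region) {
  cells <- if (is.matrix(region)) region else region$cells
  if (is.null(cells) || nrow(cells) == 0L) stop("region is empty")
  m <- cells_to_mask(cells, pad = 1L)
  cc <- connected_components(!m, 8)
  if (cc$n == 0L) return(list(n_holes = 0L, hole_areas = integer(0),
                              total_hole_area = 0L))
  nr <- nrow(m); nc <- ncol(m)
  frame <- unique(c(cc$labels[1L, ], cc$labels[nr, ],
                    cc$labels[, 1L], cc$labels[, nc]))
  frame <- frame[frame > 0L]
  hole_ids <- setdiff(seq_len(cc$n), frame)
  areas <- cc$sizes[hole_ids]
  list(n_holes = length(hole_ids), hole_areas = areas,
       total_hole_area = sum(areas))
}
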