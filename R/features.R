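# The 22 shape and boundary descriptors computed per tissue sample from
# tumor regions on the heatmap grid, and their aggregation to patient level.
#
# Conventions (all exactly testable on cell grids):
#  * perimeter: crack length — the number of unit cell edges adjacent to
#    exactly one region cell (4-neighbourhood exposure count);
#  * convex area: number of cell centers inside or on the convex hull of the
#    4 corner points of every region cell;
#  * ellipse: central second moments of cell centers, axes 4*sqrt(eigenvalue);
#  * P^2/A: perimeter^2 / area; >= 16 for any region, = 16 exactly for squares
#    (the discrete isoperimetric bound under the crack convention).

#' Crack perimeter of a region
#'
#' Counts unit cell edges exposed to the background, i.e. edges adjacent to
#' exactly one region cell.
#'
#' @param region a region list with a `cells` row/col matrix, or the matrix
#'   itself, or a logical mask matrix.
#' @return Edge count (a 1-cell region has perimeter 4; an s x s square 4s).
#' @export
crack_perimeter <- function(region) {
  m <- region_mask(region)
  if (!any(m)) stop("region is empty")
  m <- pad_mask(m, 1L)
  sum(m & !shift_mat(m, 1L, 0L)) + sum(m & !shift_mat(m, -1L, 0L)) +
    sum(m & !shift_mat(m, 0L, 1L)) + sum(m & !shift_mat(m, 0L, -1L))
}

region_mask <- function(region) {
  if (is.logical(region) && is.matrix(region)) return(region)
  cells <- if (is.matrix(region)) region else region$cells
  if (is.null(cells) || nrow(cells) == 0L) stop("region is empty")
  cells_to_mask(cells)
}

region_cells <- function(region) {
  if (is.logical(region) && is.matrix(region)) return(which(region, arr.ind = TRUE))
  if (is.matrix(region)) region else region$cells
}

#' Convex area of a region
#'
#' The convex hull is taken over the 4 corner points of every region cell;
#' the convex area is the number of cells whose centers lie inside or on
#' that hull.
#'
#' @inheritParams crack_perimeter
#' @return Cell count (equals the area for convex regions).
#' @export
convex_area <- function(region) {
  cells <- region_cells(region)
  if (nrow(cells) == 0L) stop("region is empty")
  corners <- rbind(
    cbind(cells[, 1L] - 0.5, cells[, 2L] - 0.5),
    cbind(cells[, 1L] - 0.5, cells[, 2L] + 0.5),
    cbind(cells[, 1L] + 0.5, cells[, 2L] - 0.5),
    cbind(cells[, 1L] + 0.5, cells[, 2L] + 0.5))
  corners <- unique(corners)
  h <- grDevices::chull(corners[, 2L], corners[, 1L])   # x = col, y = row
  hull <- corners[h, , drop = FALSE]                    # clockwise in (x,y)
  rs <- seq(ceiling(min(hull[, 1L])), floor(max(hull[, 1L])))
  cs <- seq(ceiling(min(hull[, 2L])), floor(max(hull[, 2L])))
  pts <- cbind(rep(rs, length(cs)), rep(cs, each = length(rs)))
  # a point is inside a convex polygon iff every edge cross product has the
  # same sign (within tolerance for points on an edge)
  all_le <- rep(TRUE, nrow(pts)); all_ge <- rep(TRUE, nrow(pts))
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    cr <- (b[2L] - a[2L]) * (pts[, 1L] - a[1L]) -
      (b[1L] - a[1L]) * (pts[, 2L] - a[2L])
    all_le <- all_le & cr <= 1e-9
    all_ge <- all_ge & cr >= -1e-9
  }
  sum(all_le | all_ge)
}

#' Moment-equivalent ellipse of a region
#'
#' Central second moments of the cell centers define a covariance matrix;
#' the axis lengths are 4 times the square roots of its eigenvalues (so a
#' region of cells uniform along a line of length n has major axis
#' 4*sqrt((n^2-1)/12)). Eccentricity is sqrt(1 - (minor/major)^2), defined 0
#' for a degenerate (single-cell) region. Orientation is the angle between
#' the major axis and the X (column) axis, measured with y upwards, in
#' (-pi/2, pi/2], ties toward 0.
#'
#' @inheritParams crack_perimeter
#' @return List with `major_axis`, `minor_axis`, `eccentricity`,
#'   `orientation`.
#' @export
ellipse_moments <- function(region) {
  cells <- region_cells(region)
  n <- nrow(cells)
  if (n == 0L) stop("region is empty")
  if (n == 1L)
    return(list(major_axis = 0, minor_axis = 0, eccentricity = 0,
                orientation = 0))
  x <- cells[, 2L]; y <- -cells[, 1L]          # y upwards
  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2); cyy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L, 2L), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  major <- 4 * sqrt(lam[1L]); minor <- 4 * sqrt(lam[2L])
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  if (abs(lam[1L] - lam[2L]) < 1e-12) {
    ang <- 0                                   # isotropic: tie toward 0
  } else {
    v <- e$vectors[, 1L]
    ang <- atan2(v[2L], v[1L])
    if (ang > pi / 2) ang <- ang - pi
    if (ang <= -pi / 2) ang <- ang + pi
  }
  list(major_axis = major, minor_axis = minor, eccentricity = ecc,
       orientation = ang)
}

#' Full geometry of one region
#'
#' @inheritParams crack_perimeter
#' @param holes optional result of [find_holes()]; computed when `NULL`.
#' @return List with `area`, `perimeter`, `convex_area`, `filled_area`,
#'   `n_holes`, `major_axis`, `minor_axis`, `eccentricity`, `orientation`,
#'   `extent`, `solidity`, `pa_ratio`.
#' @export
region_geometry <- function(region, holes = NULL) {
  cells <- region_cells(region)
  if (nrow(cells) == 0L) stop("region is empty")
  if (is.null(holes)) holes <- find_holes(cells)
  area <- nrow(cells)
  per <- crack_perimeter(cells)
  ca <- convex_area(cells)
  em <- ellipse_moments(cells)
  bb_h <- diff(range(cells[, 1L])) + 1L
  bb_w <- diff(range(cells[, 2L])) + 1L
  list(area = area, perimeter = per, convex_area = ca,
       filled_area = area + holes$total_hole_area,
       n_holes = holes$n_holes,
       major_axis = em$major_axis, minor_axis = em$minor_axis,
       eccentricity = em$eccentricity, orientation = em$orientation,
       extent = area / (bb_h * bb_w), solidity = area / ca,
       pa_ratio = per^2 / area)
}

#' Canonical names of the 22 features
#'
#' Fixed order: region count; sums over all tumor regions of area, perimeter,
#' convex area, filled area, hole count, major and minor axis; P^2/A of all
#' regions (computed as (sum perimeter)^2 / (sum area)); then the
#' main-region block.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() {
  c("n_regions", "area_sum", "perimeter_sum", "convex_area_sum",
    "filled_area_sum", "n_holes_sum", "major_axis_sum", "minor_axis_sum",
    "pa_ratio_all", "area_main", "convex_area_main", "eccentricity_main",
    "n_holes_main", "extent_main", "filled_area_main", "major_axis_main",
    "minor_axis_main", "orientation_main", "perimeter_main", "solidity_main",
    "tumor_prob_main", "pa_ratio_main")
}

#' Reporting scales of the 22 features
#'
#' Unit constants applied before the Cox stages so hazard ratios are
#' reported per the stated unit: most size features per 1000 heatmap cells,
#' hole counts per 100, main-region axes per 100, mean tumor probability per
#' 0.10, P^2/A ratios per 1000; unitless shape indices (eccentricity,
#' extent, solidity) and the orientation angle are unscaled.
#'
#' @return Named numeric vector aligned with [feature_names()].
#' @export
feature_scales <- function() {
  c(n_regions = 1000, area_sum = 1000, perimeter_sum = 1000,
    convex_area_sum = 1000, filled_area_sum = 1000, n_holes_sum = 100,
    major_axis_sum = 1000, minor_axis_sum = 1000, pa_ratio_all = 1000,
    area_main = 1000, convex_area_main = 1000, eccentricity_main = 1,
    n_holes_main = 100, extent_main = 1, filled_area_main = 1000,
    major_axis_main = 100, minor_axis_main = 100, orientation_main = 1,
    perimeter_main = 1000, solidity_main = 1, tumor_prob_main = 0.1,
    pa_ratio_main = 1000)
}

#' Apply the reporting scales to a raw feature matrix
#'
#' @param features matrix or data frame with [feature_names()] columns.
#' @return Matrix of features divided by their unit constants.
#' @export
scale_features <- function(features) {
  features <- as.matrix(features)
  sc <- feature_scales()
  miss <- setdiff(colnames(features), names(sc))
  if (length(miss)) stop("unknown feature columns: ", paste(miss, collapse = ", "))
  sweep(features, 2L, sc[colnames(features)], "/")
}

#' The 22-feature vector of one tissue sample
#'
#' Sum features run over all tumor regions of the tissue sample;
#' `pa_ratio_all` is (sum perimeter)^2 / (sum area); the main-region block
#' describes the largest tumor region, including the mean predicted tumor
#' probability over its cells.
#'
#' @param tissue one element of [segment_tissue_regions()].
#' @param tumor_regions result of [extract_tumor_regions()] for it.
#' @param prob_map class-probability array (rows x cols x 3, class order
#'   tumor, non-malignant, white), or `NULL` to skip the probability feature
#'   (it is then `NA`).
#' @return Named numeric vector of length 22, or `NULL` (with a warning)
#'   when the tissue sample has no tumor regions.
#' @export
tissue_feature_vector <- function(tissue, tumor_regions, prob_map = NULL) {
  if (length(tumor_regions) == 0L) {
    warning("tissue sample ", tissue$id, " has no tumor regions; skipped")
    return(NULL)
  }
  geo <- lapply(tumor_regions, region_geometry)
  main_i <- which(vapply(tumor_regions, `[[`, logical(1), "is_main"))[1L]
  g_main <- geo[[main_i]]
  s <- function(f) sum(vapply(geo, `[[`, numeric(1), f))
  tp <- NA_real_
  if (!is.null(prob_map)) {
    pm <- if (inherits(prob_map, "class_prob_map")) prob_map$probs else prob_map
    cells <- tumor_regions[[main_i]]$cells
    tp <- mean(pm[cbind(cells[, 1L], cells[, 2L], 1L)])
  }
  v <- c(length(tumor_regions), s("area"), s("perimeter"), s("convex_area"),
         s("filled_area"), s("n_holes"), s("major_axis"), s("minor_axis"),
         s("perimeter")^2 / s("area"),
         g_main$area, g_main$convex_area, g_main$eccentricity,
         g_main$n_holes, g_main$extent, g_main$filled_area,
         g_main$major_axis, g_main$minor_axis, g_main$orientation,
         g_main$perimeter, g_main$solidity, tp, g_main$pa_ratio)
  stats::setNames(v, feature_names())
}

#' Feature vectors for every tissue sample of a slide
#'
#' Segments tissue samples and tumor regions from a label map and computes
#' the 22-feature vector per tissue sample. When no probability map is
#' given, the ground-truth labels stand in (tumor probability 1 on
#' tumor-labeled cells).
#'
#' @param label_map `label_map` object or integer label matrix.
#' @param prob_map optional class-probability array.
#' @param closing_radius passed to [segment_tissue_regions()].
#' @return List of feature vectors (tissue samples without tumor are
#'   dropped with a warning).
#' @export
slide_feature_vectors <- function(label_map, prob_map = NULL,
                                  closing_radius = 1) {
  labels <- as_label_matrix(label_map)
  if (is.null(prob_map)) {
    pm <- array(0, c(nrow(labels), ncol(labels), 3L))
    pm[, , 1L][labels == label_codes[["tumor"]]] <- 1
    pm[, , 2L][labels == label_codes[["non_malignant"]]] <- 1
    pm[, , 3L][labels == label_codes[["white"]]] <- 1
    prob_map <- pm
  }
  tissues <- segment_tissue_regions(labels, closing_radius)
  out <- list()
  for (t in tissues) {
    tr <- extract_tumor_regions(t, labels)
    if (length(tr) == 0L) {
      warning("tissue sample ", t$id, " has no tumor regions; skipped")
      next
    }
    out[[length(out) + 1L]] <- tissue_feature_vector(t, tr, prob_map)
  }
  out
}

#' Average tissue-sample feature vectors to patient level
#'
#' Unweighted arithmetic mean, feature-wise, across all tissue samples of
#' all of a patient's slides.
#'
#' @param vectors list of 22-feature vectors.
#' @return Named numeric vector of length 22, or `NULL` with a warning when
#'   the list is empty (the patient is excluded).
#' @export
patient_aggregate <- function(vectors) {
  vectors <- Filter(Negate(is.null), vectors)
  if (length(vectors) == 0L) {
    warning("no tissue feature vectors; patient excluded")
    return(NULL)
  }
  colMeans(do.call(rbind, vectors))
}
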