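# Binary-grid primitives shared by the synthetic generator, tissue masking and
# region morphology. Grids are logical matrices; rows index the image y axis
# (downwards), columns the x axis. All neighbourhood work is done at this
# level so that the same conventions (8-connectivity, row-major discovery
# order) hold everywhere.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, making generators pure functions of their seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Shift a matrix by (dr, dc), filling vacated cells
#' @keywords internal
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq(max(1L, 1L + dr), min(nr, nr + dr))
  cs <- seq(max(1L, 1L + dc), min(nc, nc + dc))
  if (length(rs) > 0 && length(cs) > 0) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Offsets of a structuring element: Euclidean disk or Chebyshev square.
se_offsets <- function(radius, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  r <- as.integer(radius)
  if (r < 0L) stop("radius must be >= 0")
  g <- expand.grid(dr = -r:r, dc = -r:r)
  if (shape == "disk") g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Binary dilation / erosion on a logical matrix
#'
#' @param mask logical matrix.
#' @param radius structuring-element radius in cells; 0 is a no-op.
#' @param shape `"disk"` (Euclidean) or `"square"` (Chebyshev).
#' @return Logical matrix of the same shape.
#' @keywords internal
binary_dilate <- function(mask, radius, shape = "disk") {
  if (radius == 0) return(mask)
  offs <- se_offsets(radius, shape)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mat(mask, offs[i, 1L], offs[i, 2L], fill = FALSE)
  out
}

#' @rdname binary_dilate
#' @keywords internal
binary_erode <- function(mask, radius, shape = "disk") {
  if (radius == 0) return(mask)
  offs <- se_offsets(radius, shape)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mat(mask, offs[i, 1L], offs[i, 2L], fill = FALSE)
  out
}

# Pad before closing/opening so the border is not treated as background.
pad_mask <- function(mask, r, fill = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(fill, nr + 2L * r, nc + 2L * r)
  out[r + seq_len(nr), r + seq_len(nc)] <- mask
  out
}

unpad_mask <- function(mask, r) {
  nr <- nrow(mask) - 2L * r; nc <- ncol(mask) - 2L * r
  mask[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
}

#' Morphological closing then opening
#' @keywords internal
binary_closing <- function(mask, radius, shape = "disk") {
  if (radius == 0) return(mask)
  r <- as.integer(ceiling(radius))
  m <- pad_mask(mask, r)
  unpad_mask(binary_erode(binary_dilate(m, radius, shape), radius, shape), r)
}

#' @rdname binary_closing
#' @keywords internal
binary_opening <- function(mask, radius, shape = "disk") {
  if (radius == 0) return(mask)
  r <- as.integer(ceiling(radius))
  m <- pad_mask(mask, r)
  unpad_mask(binary_dilate(binary_erode(m, radius, shape), radius, shape), r)
}

#' Connected-component labeling of a binary grid
#'
#' Labels maximal connected foreground components under 4- or 8-connectivity.
#' Components are numbered 1..n in row-major discovery order: the component
#' whose first cell (scanning rows top to bottom, then columns left to right)
#' comes first receives label 1, and so on, so labeling is deterministic.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param connectivity 4 or 8.
#' @return A list with `labels` (integer matrix, 0 = background), `n`
#'   (component count) and `sizes` (integer vector of component areas).
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
#' connected_components(m, 8)$n  # 1: diagonal cells touch under 8-connectivity
#' connected_components(m, 4)$n  # 2
#' @export
connected_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask & !is.na(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(list(labels = lab, n = 0L, sizes = integer(0)))
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  pos <- which(mask)
  rr0 <- (pos - 1L) %% nr; cc0 <- (pos - 1L) %/% nr
  seeds <- pos[order(rr0, cc0)]            # row-major scan order
  k <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    k <- k + 1L
    lab[s] <- k
    frontier <- s
    while (length(frontier)) {
      fr <- (frontier - 1L) %% nr + 1L
      fc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        r2 <- fr + offs[i, 1L]; c2 <- fc + offs[i, 2L]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (!any(ok)) next
        ii <- (c2[ok] - 1L) * nr + r2[ok]
        ii <- ii[mask[ii] & lab[ii] == 0L]
        if (length(ii)) {
          lab[ii] <- k
          nxt <- c(nxt, ii)
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(labels = lab, n = k, sizes = tabulate(lab[lab > 0L], k))
}

# Cells (row, col matrix) of a labeled component, in row-major order.
component_cells <- function(labels, id) {
  pos <- which(labels == id)
  nr <- nrow(labels)
  cells <- cbind(row = (pos - 1L) %% nr + 1L, col = (pos - 1L) %/% nr + 1L)
  cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
}

# Rebuild a local logical mask from cell coordinates; pad adds a frame.
cells_to_mask <- function(cells, pad = 0L) {
  r0 <- min(cells[, 1L]); c0 <- min(cells[, 2L])
  nr <- max(cells[, 1L]) - r0 + 1L + 2L * pad
  nc <- max(cells[, 2L]) - c0 + 1L + 2L * pad
  m <- matrix(FALSE, nr, nc)
  m[cbind(cells[, 1L] - r0 + 1L + pad, cells[, 2L] - c0 + 1L + pad)] <- TRUE
  m
}
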