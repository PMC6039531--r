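# Independent oracles and fixture builders. Each oracle uses a different
# algorithm from the implementation it checks.

# Connected-component labeling by iterative minimum-label propagation
# (vs the package's BFS).
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  shift_inf <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- seq(max(1, 1 + dr), min(nr, nr + dr))
    cs <- seq(max(1, 1 + dc), min(nc, nc + dc))
    if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift_inf(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[mask]))
  labels <- matrix(0L, nr, nc)
  for (i in seq_along(ids)) labels[lab == ids[i]] <- i
  list(labels = labels, n = length(ids),
       sizes = as.integer(table(factor(labels[labels > 0],
                                       levels = seq_along(ids)))))
}

# Hole/filled-area oracle: flood the background from the padded frame;
# anything unreachable is hole.
oracle_holes <- function(cells) {
  m <- cells_to_mask(cells, pad = 1L)
  bg <- oracle_label(!m, 8)
  frame_ids <- unique(c(bg$labels[1, ], bg$labels[nrow(m), ],
                        bg$labels[, 1], bg$labels[, ncol(m)]))
  frame_ids <- frame_ids[frame_ids > 0]
  hole_ids <- setdiff(seq_len(bg$n), frame_ids)
  list(n_holes = length(hole_ids), total = sum(bg$sizes[hole_ids]))
}

# Convex-area oracle: hull polygon over cell corners, point-in-polygon via
# pracma::inpolygon (a different inside test than the implementation's
# half-plane checks).
oracle_convex_area <- function(cells) {
  corners <- unique(rbind(
    cbind(cells[, 1] - 0.5, cells[, 2] - 0.5),
    cbind(cells[, 1] - 0.5, cells[, 2] + 0.5),
    cbind(cells[, 1] + 0.5, cells[, 2] - 0.5),
    cbind(cells[, 1] + 0.5, cells[, 2] + 0.5)))
  h <- grDevices::chull(corners[, 2], corners[, 1])
  xp <- corners[h, 2]; yp <- corners[h, 1]
  rs <- seq(ceiling(min(yp)), floor(max(yp)))
  cs <- seq(ceiling(min(xp)), floor(max(xp)))
  pts <- cbind(rep(rs, length(cs)), rep(cs, each = length(rs)))
  sum(pracma::inpolygon(pts[, 2], pts[, 1], xp, yp, boundary = TRUE))
}

# Exhaustive-scan Otsu oracle: direct between-class variance per threshold.
oracle_otsu <- function(gray) {
  g <- pmin(pmax(as.integer(round(gray)), 0L), 255L)
  best <- -1; best_t <- 0L
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) v <- 0
    else {
      w0 <- length(lo) / length(g); w1 <- 1 - w0
      v <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t
}

# Brute-force partial likelihood for a single covariate, no ties.
oracle_cox_beta <- function(x, time, event) {
  pl <- function(b) {
    s <- 0
    for (i in order(time)) {
      if (event[i] == 0) next
      rs <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    s
  }
  stats::optimize(pl, c(-6, 6), maximum = TRUE, tol = 1e-9)$maximum
}

# Random blobby test mask: union of a few disks plus salt noise; returns a
# non-empty cell matrix of its largest 8-connected component.
random_region_cells <- function(seed, size = 14) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (b in seq_len(sample(1:3, 1))) {
    cy <- runif(1, 3, size - 2); cx <- runif(1, 3, size - 2)
    r <- runif(1, 1.5, size / 3)
    yy <- matrix(rep(seq_len(size), size), size, size)
    xx <- t(yy)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  m[cbind(sample(size, 5, TRUE), sample(size, 5, TRUE))] <- TRUE
  cc <- connected_components(m, 8)
  component_cells(cc$labels, which.max(cc$sizes))
}

# Rotate region cells by 90 degrees: (r, c) -> (c, max_r - r + 1).
rotate_cells_90 <- function(cells) {
  cbind(row = cells[, 2], col = max(cells[, 1]) - cells[, 1] + 1)
}

# Rendered, labeled patches for classifier tests: slides are generated
# until every class has at least n patches, then trimmed per class.
make_patch_set <- function(n_per_class, seed, patch_size = 24) {
  patches <- list(); labels <- character(0)
  s <- 0
  while (s < 50 &&
         (length(labels) == 0 ||
          min(table(factor(labels,
                           levels = c("tumor", "non_malignant", "white")))) <
          n_per_class)) {
    s <- s + 1
    mk <- gen_tumor_mask(shape_spec(6, roughness = 0.3, n_satellites = 1,
                                    seed = seed + s))
    lm <- gen_label_map(mk)
    img <- render_slide(lm, patch_size, seed = seed * 1000 + s)
    h <- harvest_patches(img, lm, patch_size)
    patches <- c(patches, h$patches)
    labels <- c(labels, h$labels)
  }
  keep <- unlist(lapply(split(seq_along(labels), labels),
                        function(ix) ix[seq_len(min(n_per_class, length(ix)))]))
  list(patches = patches[keep], labels = labels[keep])
}
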