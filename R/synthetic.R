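# Synthetic cohort generator: tumor masks with controllable boundary
# roughness, holes and satellite specks; multi-sample label maps; textured
# slide rendering; and proportional-hazards survival outcomes driven by the
# true shape features. Everything is a pure function of its seed, so the
# downstream pipeline can be tested against exact ground truth.

#' Specify a synthetic tumor shape
#'
#' The tumor body is a star-convex region with boundary radius
#' r(theta) = base_radius * (1 + sum_k a_k cos(k*theta + phi_k)), rasterized
#' on a cell grid, with the column axis stretched by `aspect`. Harmonic
#' amplitudes |a_k| scale linearly with `roughness`, so larger roughness
#' yields a longer, more irregular boundary. Optional 1-cell holes are
#' punched strictly in the interior, and satellite specks (tumor spread
#' through air spaces, which typically occupy a single heatmap cell) are
#' placed near, but disjoint from, the body.
#'
#' @param base_radius mean boundary radius in cells (>= 2).
#' @param aspect elongation of the column (x) axis, >= 1.
#' @param roughness radial perturbation amplitude, >= 0; 0 gives a smooth
#'   ellipse (a disk when `aspect = 1`).
#' @param n_harmonics number of boundary harmonics (k = 2 .. n_harmonics + 1).
#' @param n_holes number of 1-cell interior holes.
#' @param n_satellites number of 1-cell satellite specks.
#' @param seed integer seed; identical specs give identical masks.
#' @return An object of class `"shape_spec"`.
#' @export
shape_spec <- function(base_radius, aspect = 1, roughness = 0, n_harmonics = 6,
                       n_holes = 0, n_satellites = 0, seed = 1) {
  if (base_radius < 2) stop("base_radius must be >= 2")
  if (aspect < 1) stop("aspect must be >= 1")
  if (roughness < 0) stop("roughness must be >= 0")
  if (n_harmonics < 0 || n_holes < 0 || n_satellites < 0)
    stop("counts must be >= 0")
  structure(list(base_radius = base_radius, aspect = aspect,
                 roughness = roughness, n_harmonics = as.integer(n_harmonics),
                 n_holes = as.integer(n_holes),
                 n_satellites = as.integer(n_satellites),
                 seed = as.integer(seed)),
            class = "shape_spec")
}

# Sample candidate cells one by one, keeping a Chebyshev spacing >= 2 so the
# chosen 1-cell features stay 8-disconnected from each other.
sample_spaced_cells <- function(cand, n, what) {
  chosen <- matrix(0L, 0L, 2L)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    if (nrow(chosen) == n) break
    p <- cand[i, ]
    if (nrow(chosen) == 0L ||
        all(pmax(abs(chosen[, 1L] - p[1L]), abs(chosen[, 2L] - p[2L])) >= 2L))
      chosen <- rbind(chosen, p)
  }
  if (nrow(chosen) < n)
    stop("shape too small to host ", n, " ", what)
  chosen
}

#' Generate a binary tumor mask from a shape specification
#'
#' @param spec a [shape_spec()].
#' @return An object of class `"tumor_mask"`: a list with `mask` (logical
#'   matrix, body with holes punched plus satellites), `body_cells`,
#'   `hole_cells`, `satellite_cells` (row/col matrices) and `spec`.
#' @examples
#' m <- gen_tumor_mask(shape_spec(5, seed = 7))
#' sum(m$mask)  # area of a rasterized disk of radius 5
#' @export
gen_tumor_mask <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  with_seed(spec$seed, {
    ks <- if (spec$n_harmonics > 0L) 1L + seq_len(spec$n_harmonics) else integer(0)
    amp <- spec$roughness * stats::runif(length(ks), 0.3, 1) / ks
    if (length(amp) && sum(amp) > 0.85) amp <- amp * 0.85 / sum(amp)
    phi <- stats::runif(length(ks), 0, 2 * pi)

    rmax <- spec$base_radius * spec$aspect * (1 + sum(amp))
    margin <- 6L                       # room for the satellite ring
    half <- as.integer(ceiling(rmax)) + margin
    n <- 2L * half + 1L
    ctr <- half + 1L
    dy <- matrix(rep(seq_len(n) - ctr, n), n, n)            # rows
    dx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)     # cols
    ex <- dx / spec$aspect
    rad <- sqrt(ex^2 + dy^2)
    theta <- atan2(dy, ex)
    lim <- spec$base_radius * (1 + Reduce(`+`, Map(function(a, k, p)
      a * cos(k * theta + p), amp, ks, phi), accumulate = FALSE,
      init = matrix(0, n, n)))
    body <- rad <= lim
    if (!any(body)) stop("degenerate shape spec: empty mask")
    cc <- connected_components(body, 8)
    if (cc$n > 1L) body <- cc$labels == which.max(cc$sizes)

    # interior cells: full 8-neighbourhood inside the body
    interior <- binary_erode(body, 1, "square")
    holes <- matrix(0L, 0L, 2L)
    if (spec$n_holes > 0L) {
      cand <- which(interior, arr.ind = TRUE)
      holes <- sample_spaced_cells(cand, spec$n_holes, "holes")
      body[holes] <- FALSE
    }

    sats <- matrix(0L, 0L, 2L)
    if (spec$n_satellites > 0L) {
      near <- binary_dilate(body, 4, "square")
      clear <- !binary_dilate(body, 1, "square")
      cand <- which(near & clear, arr.ind = TRUE)
      keep <- cand[, 1L] > 1L & cand[, 1L] < n & cand[, 2L] > 1L & cand[, 2L] < n
      sats <- sample_spaced_cells(cand[keep, , drop = FALSE],
                                  spec$n_satellites, "satellites")
    }

    mask <- body
    if (nrow(sats)) mask[sats] <- TRUE
    structure(list(mask = mask, body_cells = which(body, arr.ind = TRUE),
                   hole_cells = holes, satellite_cells = sats, spec = spec),
              class = "tumor_mask")
  })
}

#' Compose tumor masks into a multi-sample slide label map
#'
#' Each tumor mask becomes one tissue sample: the tumor cells (body plus
#' satellites) are dilated by `rim` cells (Chebyshev) into a surrounding
#' non-malignant rim, and samples are laid out on a white canvas with at
#' least a 1-cell white margin (default layout leaves a 3-cell gap so
#' samples remain disconnected after radius-1 closing downstream).
#'
#' @param masks list of [gen_tumor_mask()] results (possibly empty).
#' @param canvas optional `c(n_rows, n_cols)`; computed from the layout when
#'   `NULL`. An empty `masks` list with a canvas gives an all-white map.
#' @param rim non-malignant rim width in cells.
#' @return An object of class `"label_map"`: list with `labels` (integer
#'   matrix, 0 = tumor, 1 = non-malignant, 2 = white), `classes`, and
#'   `truth` (a data frame of per-sample ground truth: expected tumor region
#'   count, tumor area, hole count).
#' @export
gen_label_map <- function(masks, canvas = NULL, rim = 2L) {
  if (inherits(masks, "tumor_mask")) masks <- list(masks)
  classes <- c("tumor", "non_malignant", "white")
  gap <- 3L
  foot <- lapply(masks, function(m) {
    tum <- m$mask
    tis <- binary_dilate(tum, rim, "square")
    cells <- which(tis, arr.ind = TRUE)
    r0 <- min(cells[, 1L]); c0 <- min(cells[, 2L])
    list(tum = tum[r0:max(cells[, 1L]), c0:max(cells[, 2L]), drop = FALSE],
         tis = tis[r0:max(cells[, 1L]), c0:max(cells[, 2L]), drop = FALSE],
         m = m)
  })
  hts <- vapply(foot, function(f) nrow(f$tis), 0L)
  wds <- vapply(foot, function(f) ncol(f$tis), 0L)
  if (length(foot)) {
    per_row <- max(1L, floor(sqrt(length(foot))))
    rows <- split(seq_along(foot), ceiling(seq_along(foot) / per_row))
    need_w <- max(vapply(rows, function(ix) sum(wds[ix]) + gap * (length(ix) - 1L), 0L)) + 2L
    need_h <- sum(vapply(rows, function(ix) max(hts[ix]), 0L)) + gap * (length(rows) - 1L) + 2L
  } else {
    need_h <- need_w <- 4L
  }
  if (is.null(canvas)) canvas <- c(need_h, need_w)
  if (canvas[1L] < need_h || canvas[2L] < need_w)
    stop("shapes do not fit the canvas with a 1-cell white margin")
  lab <- matrix(2L, canvas[1L], canvas[2L])
  truth <- data.frame(sample_id = integer(0), n_tumor_regions = integer(0),
                      tumor_area = integer(0), n_holes = integer(0))
  if (length(foot)) {
    r_off <- 2L
    sid <- 0L
    for (ix in rows) {
      c_off <- 2L
      for (i in ix) {
        f <- foot[[i]]
        rr <- r_off + seq_len(nrow(f$tis)) - 1L
        cc <- c_off + seq_len(ncol(f$tis)) - 1L
        if (any(lab[rr, cc] != 2L)) stop("tissue samples overlap")
        sub <- lab[rr, cc]
        sub[f$tis] <- 1L
        sub[f$tum] <- 0L
        lab[rr, cc] <- sub
        sid <- sid + 1L
        truth <- rbind(truth, data.frame(
          sample_id = sid,
          n_tumor_regions = 1L + nrow(f$m$satellite_cells),
          tumor_area = sum(f$tum),
          n_holes = nrow(f$m$hole_cells)))
        c_off <- c_off + ncol(f$tis) + gap
      }
      r_off <- r_off + max(hts[ix]) + gap
    }
  }
  structure(list(labels = lab, classes = classes, truth = truth,
                 rim = as.integer(rim)), class = "label_map")
}

# Texture parameters per class. Tumor patches carry dense dark-purple blobs
# (blue > red), non-malignant patches sparse pink blobs (red > blue), white
# patches near-saturated background; class-conditional statistics are
# separable by a nearest-centroid rule on (mean intensity, blue - red).
patch_palette <- list(
  tumor = list(bg = c(215, 175, 205), blob = c(95, 45, 135),
               density = 12, rad = c(1 / 14, 1 / 7)),
  non_malignant = list(bg = c(235, 195, 210), blob = c(205, 115, 160),
                       density = 4, rad = c(1 / 14, 1 / 8)),
  white = list(bg = c(247, 247, 247))
)

render_patch <- function(class, ps, xx, yy) {
  p <- patch_palette[[class]]
  arr <- array(0, c(ps, ps, 3L))
  if (class == "white") {
    base <- stats::runif(1, 244, 250)
    for (ch in 1:3)
      arr[, , ch] <- base + stats::rnorm(ps * ps, 0, 1.5)
  } else {
    for (ch in 1:3)
      arr[, , ch] <- p$bg[ch] + stats::rnorm(ps * ps, 0, 4)
    n_blobs <- stats::rpois(1, p$density * (ps / 32)^2) + 1L
    for (b in seq_len(n_blobs)) {
      cy <- stats::runif(1, 1, ps); cx <- stats::runif(1, 1, ps)
      rad <- stats::runif(1, p$rad[1L], p$rad[2L]) * ps
      hit <- (yy - cy)^2 + (xx - cx)^2 <= rad^2
      if (!any(hit)) next
      shade <- stats::runif(1, 0.9, 1.1)
      for (ch in 1:3) {
        m <- arr[, , ch]
        m[hit] <- p$blob[ch] * shade
        arr[, , ch] <- m
      }
    }
  }
  pmin(pmax(arr, 0), 255)
}

#' Render a label map to an RGB slide image
#'
#' Each heatmap cell becomes a `patch_size`-pixel square texture whose color
#' statistics depend on its class, emulating 40X H&E appearance at desk
#' scale: white cells render near-saturated (mean intensity above any
#' sensible white threshold), tumor cells dense dark-purple blobs,
#' non-malignant cells sparse pink blobs.
#'
#' @param label_map a [gen_label_map()] result or an integer label matrix.
#' @param patch_size pixels per cell side (>= 8); default 32 for speed, 300
#'   mirrors full-scale slides.
#' @param seed integer seed; rendering is bit-reproducible.
#' @return Numeric array height x width x 3 with values in 0..255.
#' @export
render_slide <- function(label_map, patch_size = 32L, seed = 1L) {
  labels <- if (inherits(label_map, "label_map")) label_map$labels else label_map
  ps <- as.integer(patch_size)
  if (ps < 8L) stop("patch_size must be >= 8")
  nr <- nrow(labels); nc <- ncol(labels)
  classes <- c("tumor", "non_malignant", "white")
  img <- array(0, c(nr * ps, nc * ps, 3L))
  yy <- matrix(rep(seq_len(ps), ps), ps, ps)
  xx <- t(yy)
  with_seed(seed, {
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        cl <- classes[labels[i, j] + 1L]
        img[(i - 1L) * ps + seq_len(ps), (j - 1L) * ps + seq_len(ps), ] <-
          render_patch(cl, ps, xx, yy)
      }
    }
  })
  img
}

#' Simulate survival outcomes from a proportional-hazards model
#'
#' Event times follow T = -log(U) / (h0 * exp(x' beta)) with U ~ Uniform(0,1).
#' Censoring is exponential with its rate solved numerically so that the
#' expected censored fraction equals `censor_rate` (closed-form inversion is
#' unavailable once covariates are heterogeneous); `censor_rate = 0` yields
#' no censoring.
#'
#' @param features numeric matrix, n patients x p features.
#' @param beta length-p log-hazard coefficient vector.
#' @param baseline_hazard h0 in 1/day, > 0.
#' @param censor_rate expected censored fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return Data frame with `time` (days) and `event` (1 = death observed).
#' @export
gen_survival <- function(features, beta, baseline_hazard = 1e-3,
                         censor_rate = 0.3, seed = 1L) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  if (ncol(features) != length(beta))
    stop("beta length does not match feature count")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  h <- baseline_hazard * exp(as.vector(features %*% beta))
  with_seed(seed, {
    t_event <- -log(stats::runif(nrow(features))) / h
    if (censor_rate == 0) {
      time <- t_event
      event <- rep(1L, length(time))
    } else {
      # P(censored_i) = c / (c + h_i) for exponential censoring at rate c
      f <- function(logc) mean(exp(logc) / (exp(logc) + h)) - censor_rate
      logc <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
      t_cens <- stats::rexp(nrow(features), exp(logc))
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    data.frame(time = time, event = event)
  })
}

#' Specify a synthetic patient cohort
#'
#' Shape parameters are drawn uniformly from the given ranges per tissue
#' sample; hole and satellite counts are Poisson (capped so every shape can
#' host them). Survival is proportional-hazards with log-hazard
#' `z' beta`, where `z` are the within-cohort standardized (z-scored),
#' Table-2-scaled driver features named by `beta` — i.e. effect sizes are
#' stated per standard deviation, the way prognostic effects are usually
#' quoted.
#'
#' @param n_patients number of patients (>= 2).
#' @param tissues_per_image tissue samples per slide.
#' @param base_radius,aspect,roughness length-2 ranges for [shape_spec()].
#' @param n_harmonics harmonics per shape.
#' @param hole_rate,satellite_rate Poisson means for holes / satellites.
#' @param beta named per-SD log-hazard vector over feature names (see
#'   [feature_names()]).
#' @param baseline_hazard,censor_rate,seed passed to the survival generator.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients, tissues_per_image = 1L,
                        base_radius = c(6, 14), aspect = c(1, 2),
                        roughness = c(0, 0.6), n_harmonics = 6L,
                        hole_rate = 1.5, satellite_rate = 1,
                        beta = c(pa_ratio_main = 0.8, area_sum = 0.5),
                        baseline_hazard = 1e-3, censor_rate = 0.35,
                        seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 tissues_per_image = as.integer(tissues_per_image),
                 base_radius = base_radius, aspect = aspect,
                 roughness = roughness, n_harmonics = as.integer(n_harmonics),
                 hole_rate = hole_rate, satellite_rate = satellite_rate,
                 beta = beta, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a full cohort with ground-truth features and survival
#'
#' Generates per-patient label maps, computes the 22 shape features from the
#' ground-truth maps (tumor probability 1 on tumor cells), averages them to
#' patient level, and draws survival times whose hazard is driven by the
#' standardized driver features named in `spec$beta`. Clinical covariates
#' (age, sex, smoking, stage) are drawn independently of the hazard, so they
#' act as prognostic noise.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `"synthetic_cohort"`: list with `clinical`
#'   (patient_id, time_days, event, age, sex, smoking, stage), `features`
#'   (n x 22 matrix, raw scale), `label_maps` (list of [gen_label_map()]
#'   objects per patient) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    label_maps <- vector("list", n)
    feats <- matrix(NA_real_, n, length(feature_names()),
                    dimnames = list(sprintf("P%04d", seq_len(n)), feature_names()))
    for (i in seq_len(n)) {
      masks <- lapply(seq_len(spec$tissues_per_image), function(j) {
        r <- stats::runif(1, spec$base_radius[1L], spec$base_radius[2L])
        gen_tumor_mask(shape_spec(
          base_radius = r,
          aspect = stats::runif(1, spec$aspect[1L], spec$aspect[2L]),
          roughness = stats::runif(1, spec$roughness[1L], spec$roughness[2L]),
          n_harmonics = spec$n_harmonics,
          n_holes = min(stats::rpois(1, spec$hole_rate), 4L),
          n_satellites = min(stats::rpois(1, spec$satellite_rate), 3L),
          seed = sample.int(.Machine$integer.max, 1L)))
      })
      lm <- gen_label_map(masks)
      label_maps[[i]] <- lm
      vecs <- slide_feature_vectors(lm)
      feats[i, ] <- patient_aggregate(vecs)
    }
    scaled <- scale_features(feats)
    drivers <- names(spec$beta)
    if (!all(drivers %in% colnames(scaled)))
      stop("beta names must be feature names")
    z <- scale(scaled[, drivers, drop = FALSE])
    surv <- gen_survival(z, spec$beta, spec$baseline_hazard,
                         spec$censor_rate,
                         seed = sample.int(.Machine$integer.max, 1L))
    clinical <- data.frame(
      patient_id = rownames(feats),
      time_days = surv$time,
      event = surv$event,
      age = round(stats::rnorm(n, 65, 8)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      smoking = sample(c("ever", "never"), n, replace = TRUE,
                       prob = c(0.6, 0.4)),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.60, 0.20, 0.13, 0.07)),
      stringsAsFactors = FALSE)
    structure(list(clinical = clinical, features = feats,
                   label_maps = label_maps, spec = spec),
              class = "synthetic_cohort")
  })
}
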