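test_that("smooth round spec rasterizes to a simply connected disk, deterministically", {
  sp <- shape_spec(6, aspect = 1, roughness = 0, n_holes = 0, seed = 11)
  m1 <- gen_tumor_mask(sp)
  m2 <- gen_tumor_mask(sp)
  expect_identical(m1$mask, m2$mask)
  expect_equal(find_holes(which(m1$mask, arr.ind = TRUE))$n_holes, 0L)
  expect_equal(connected_components(m1$mask, 8)$n, 1L)
  # disk of radius 6: area close to pi * 36
  expect_gt(sum(m1$mask), pi * 36 * 0.85)
  expect_lt(sum(m1$mask), pi * 36 * 1.15)
})

test_that("holes are interior and satellites disjoint 1-cell specks", {
  m <- gen_tumor_mask(shape_spec(8, n_holes = 3, n_satellites = 2, seed = 5))
  body_cells <- which(m$mask, arr.ind = TRUE)
  hl <- find_holes(m$body_cells)
  expect_equal(hl$n_holes, 3L)
  expect_equal(hl$total_hole_area, 3L)
  cc <- connected_components(m$mask, 8)
  expect_equal(cc$n, 3L)                       # body + 2 satellites
  expect_equal(sort(cc$sizes)[1:2], c(1L, 1L)) # satellites are single cells
  # degenerate spec: too small to host many holes
  expect_error(gen_tumor_mask(shape_spec(2, n_holes = 25, seed = 1)),
               "host")
})

test_that("boundary roughness increases crack P2/A on average", {
  pa <- function(rough) {
    vapply(1:20, function(s) {
      m <- gen_tumor_mask(shape_spec(8, roughness = rough, seed = s))
      cells <- which(m$mask, arr.ind = TRUE)
      crack_perimeter(cells)^2 / nrow(cells)
    }, numeric(1))
  }
  expect_gt(mean(pa(0.5)), mean(pa(0)))
})

test_that("label maps carry exact ground truth through the region pipeline", {
  m <- gen_tumor_mask(shape_spec(7, n_satellites = 3, seed = 9))
  lm <- gen_label_map(m)
  tis <- segment_tissue_regions(lm)
  expect_length(tis, 1L)
  tum <- extract_tumor_regions(tis[[1]], lm)
  expect_length(tum, lm$truth$n_tumor_regions)   # body + 3 satellites = 4
  expect_equal(sum(vapply(tum, `[[`, numeric(1), "area")),
               lm$truth$tumor_area)
  # empty spec list with a canvas gives an all-white map
  lw <- gen_label_map(list(), canvas = c(6, 6))
  expect_true(all(lw$labels == 2L))
  # canvas too small errors
  expect_error(gen_label_map(m, canvas = c(4, 4)), "fit")
})

test_that("rendering separates classes and is bit-reproducible", {
  m <- gen_tumor_mask(shape_spec(5, seed = 2))
  lm <- gen_label_map(m)
  img1 <- render_slide(lm, 16, seed = 4)
  img2 <- render_slide(lm, 16, seed = 4)
  expect_identical(img1, img2)
  expect_error(render_slide(lm, 4), "patch_size")

  ps <- make_patch_set(60, seed = 300, patch_size = 16)
  means <- vapply(ps$patches, mean, numeric(1)) * 255
  # white cells render above the default white threshold
  expect_true(all(means[ps$labels == "white"] > 200))
  # nearest-centroid on (mean intensity, blue - red) separates tumor from
  # non-malignant patches
  feat <- t(vapply(ps$patches, function(p)
    c(mean(p), mean(p[, , 3]) - mean(p[, , 1])), numeric(2)))
  tn <- ps$labels %in% c("tumor", "non_malignant")
  x <- feat[tn, ]; y <- ps$labels[tn]
  cen <- rbind(colMeans(x[y == "tumor", ]), colMeans(x[y == "non_malignant", ]))
  pred <- c("tumor", "non_malignant")[
    max.col(-as.matrix(stats::dist(rbind(cen, x)))[-(1:2), 1:2])]
  expect_gt(mean(pred == y), 0.9)
})

test_that("survival generator honors its contract", {
  X <- matrix(rnorm(200), 100, 2)
  expect_error(gen_survival(X, beta = c(1, 2, 3)), "length")
  s0 <- gen_survival(X, c(0.5, -0.5), censor_rate = 0, seed = 3)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$time > 0))
  expect_identical(s0, gen_survival(X, c(0.5, -0.5), censor_rate = 0, seed = 3))
  # censoring calibration: empirical censored fraction near target
  s4 <- gen_survival(matrix(rnorm(4000), 4000, 1), 0.8,
                     censor_rate = 0.4, seed = 8)
  expect_lt(abs(mean(1 - s4$event) - 0.4), 0.05)
})

test_that("null hazard gives uniform log-rank p over seeds", {
  reps <- 200
  p <- vapply(seq_len(reps), function(s) {
    x <- with_seed(s * 7 + 1, rnorm(60))
    sv <- gen_survival(matrix(x), 0, censor_rate = 0, seed = s)
    grp <- ifelse(x > median(x), "hi", "lo")
    logrank(grp, sv$time, sv$event)$p
  }, numeric(1))
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
})

test_that("true-risk halves show the hazard ratio the model implies", {
  n <- 1000
  x <- with_seed(21, rnorm(n))
  sv <- gen_survival(matrix(x), 0.8, censor_rate = 0.2, seed = 22)
  hi <- x > median(x)
  emp <- cox_fit(matrix(as.numeric(hi)), sv$time, sv$event)$table$hr
  expected <- exp(0.8 * (mean(x[hi]) - mean(x[!hi])))
  expect_lt(abs(emp - expected) / expected, 0.2)
})

test_that("simulate_cohort is reproducible and carries valid clinical data", {
  sp <- cohort_spec(n_patients = 12, seed = 31)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a$features, b$features)
  expect_identical(a$clinical, b$clinical)
  expect_true(all(a$clinical$time_days > 0))
  expect_true(all(a$clinical$event %in% 0:1))
  expect_true(all(a$clinical$stage %in% c("I", "II", "III", "IV")))
  expect_equal(nrow(a$features), 12L)
  expect_equal(colnames(a$features), feature_names())
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(10, censor_rate = 1.2), "censor_rate")
})
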