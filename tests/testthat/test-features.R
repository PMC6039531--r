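test_that("crack perimeter matches hand counts", {
  expect_equal(crack_perimeter(cbind(1, 1)), 4)
  sq3 <- as.matrix(expand.grid(row = 1:3, col = 1:3))
  expect_equal(crack_perimeter(sq3), 12)
  donut <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  donut <- donut[!(donut[, 1] == 3 & donut[, 2] == 3), ]
  expect_equal(crack_perimeter(donut), 24)     # outer 20 + inner 4
  expect_equal(crack_perimeter(cbind(1, 1:7)), 16)
})

test_that("convex area handles hand-derived cases", {
  sq3 <- as.matrix(expand.grid(row = 1:3, col = 1:3))
  expect_equal(convex_area(sq3), 9)
  # L-tromino: center of the missing cell lies on the hull edge
  expect_equal(convex_area(rbind(c(1, 1), c(2, 1), c(2, 2))), 4)
  expect_equal(convex_area(cbind(1, 1:7)), 7)
})

test_that("moment ellipse matches the closed-form cases", {
  em <- ellipse_moments(cbind(1, 1:7))
  expect_equal(em$major_axis, 8)               # 4 * sqrt((49 - 1) / 12)
  expect_equal(em$minor_axis, 0)
  expect_equal(em$eccentricity, 1)
  expect_equal(em$orientation, 0)
  sq3 <- as.matrix(expand.grid(row = 1:3, col = 1:3))
  em2 <- ellipse_moments(sq3)
  expect_equal(em2$major_axis, 4 * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(em2$major_axis, em2$minor_axis)
  expect_equal(em2$eccentricity, 0)
  expect_equal(em2$orientation, 0)             # isotropic tie toward 0
  em3 <- ellipse_moments(cbind(1, 1))
  expect_equal(unlist(em3), c(major_axis = 0, minor_axis = 0,
                              eccentricity = 0, orientation = 0))
  # vertical bar: orientation at the principal-interval boundary pi/2
  em4 <- ellipse_moments(cbind(1:7, 1))
  expect_equal(em4$orientation, pi / 2)
})

test_that("region geometry combines the primitives correctly", {
  g <- region_geometry(cbind(1, 1:7))
  expect_equal(g$extent, 1)
  expect_equal(g$solidity, 1)
  expect_equal(g$pa_ratio, 16^2 / 7)
  donut <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  donut <- donut[!(donut[, 1] == 3 & donut[, 2] == 3), ]
  g2 <- region_geometry(donut)
  expect_equal(g2$area, 24)
  expect_equal(g2$filled_area, 25)
  expect_equal(g2$n_holes, 1L)
  expect_equal(g2$extent, 24 / 25)
  for (s in c(1, 3, 6)) {
    sq <- as.matrix(expand.grid(row = 1:s, col = 1:s))
    expect_equal(region_geometry(sq)$pa_ratio, 16)
  }
})

test_that("geometry agrees with brute-force oracles on random masks", {
  for (seed in 1:40) {
    cells <- random_region_cells(seed)
    g <- region_geometry(cells)
    o <- oracle_holes(cells)
    expect_equal(g$area, nrow(cells))
    expect_equal(g$n_holes, o$n_holes)
    expect_equal(g$filled_area, nrow(cells) + o$total)
    expect_equal(g$convex_area, oracle_convex_area(cells))
    bb <- (diff(range(cells[, 1])) + 1) * (diff(range(cells[, 2])) + 1)
    expect_equal(g$extent, nrow(cells) / bb)
    expect_gte(g$pa_ratio, 16)
  }
})

test_that("moment and count features are invariant under 90-degree rotation", {
  for (seed in c(3, 17, 42)) {
    cells <- random_region_cells(seed)
    rot <- rotate_cells_90(cells)
    g <- region_geometry(cells); gr <- region_geometry(rot)
    for (f in c("area", "perimeter", "n_holes", "convex_area", "filled_area",
                "extent", "solidity", "pa_ratio"))
      expect_equal(gr[[f]], g[[f]])
    expect_equal(gr$major_axis, g$major_axis, tolerance = 1e-9)
    expect_equal(gr$minor_axis, g$minor_axis, tolerance = 1e-9)
    expect_equal(gr$eccentricity, g$eccentricity, tolerance = 1e-9)
    # orientation rotates by pi/2 within the principal interval
    if (g$eccentricity > 1e-6) {
      d <- (gr$orientation - g$orientation) %% pi
      expect_lt(min(abs(d - pi / 2), abs(d - pi / 2 - pi), abs(d + pi / 2 - pi)),
                1e-6)
    }
  }
})

test_that("tissue feature vectors assemble sums and main-region values", {
  lab <- matrix(2L, 16, 24)
  lab[2:15, 2:23] <- 1L
  lab[3:10, 3:7] <- 0L                   # main body, 40 cells
  lab[13, 5] <- 0L; lab[13, 10] <- 0L    # two satellites
  tis <- segment_tissue_regions(lab, closing_radius = 0)
  tum <- extract_tumor_regions(tis[[1]], lab)
  pm <- array(0, c(16, 24, 3)); pm[, , 1][lab == 0L] <- 0.8
  v <- tissue_feature_vector(tis[[1]], tum, pm)
  expect_named(v, feature_names())
  expect_equal(unname(v["n_regions"]), 3)
  expect_equal(unname(v["area_sum"]), 42)
  expect_equal(unname(v["area_main"]), 40)
  expect_equal(unname(v["tumor_prob_main"]), 0.8)
  expect_equal(unname(v["pa_ratio_all"]),
               unname(v["perimeter_sum"])^2 / unname(v["area_sum"]))
  # single-region tissue: sums equal main values
  lab1 <- matrix(2L, 10, 10); lab1[2:9, 2:9] <- 1L; lab1[4:6, 4:6] <- 0L
  tis1 <- segment_tissue_regions(lab1, closing_radius = 0)
  tum1 <- extract_tumor_regions(tis1[[1]], lab1)
  v1 <- tissue_feature_vector(tis1[[1]], tum1, NULL)
  expect_equal(unname(v1["n_regions"]), 1)
  expect_equal(unname(v1["area_sum"]), unname(v1["area_main"]))
  expect_equal(unname(v1["perimeter_sum"]), unname(v1["perimeter_main"]))
  # no tumor regions: NULL with warning
  expect_warning(v0 <- tissue_feature_vector(tis1[[1]], list(), NULL),
                 "no tumor regions")
  expect_null(v0)
})

test_that("patient aggregation is an unweighted permutation-invariant mean", {
  a <- setNames(rep(10, 22), feature_names())
  b <- setNames(rep(20, 22), feature_names())
  expect_equal(unname(patient_aggregate(list(a))["area_sum"]), 10)
  m <- patient_aggregate(list(a, b))
  expect_equal(unname(m["area_sum"]), 15)
  expect_equal(patient_aggregate(list(b, a)), m)
  expect_warning(expect_null(patient_aggregate(list())), "excluded")
})

test_that("reporting scales divide by the Table-style unit constants", {
  f <- matrix(1000, 1, 22, dimnames = list(NULL, feature_names()))
  s <- scale_features(f)
  expect_equal(unname(s[1, "area_sum"]), 1)
  expect_equal(unname(s[1, "n_holes_sum"]), 10)
  expect_equal(unname(s[1, "tumor_prob_main"]), 10000)
  expect_equal(unname(s[1, "eccentricity_main"]), 1000)
  expect_error(scale_features(matrix(1, 1, 1, dimnames = list(NULL, "bogus"))),
               "unknown feature")
})
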