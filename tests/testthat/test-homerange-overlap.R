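test_that("the utilization distribution is a normalized density", {
  set.seed(1)
  pts <- cbind(rnorm(40, 3000, 400), rnorm(40, 2500, 400))
  ud <- kde_ud(pts, h = 200, resolution = 50)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-9)
  expect_true(all(ud$mass >= 0))
  # translation equivariance
  ud2 <- kde_ud(pts + 1000, h = 200, resolution = 50)
  expect_equal(ud2$mass, ud$mass, tolerance = 1e-9)
  expect_equal(ud2$x, ud$x + 1000)
  expect_error(kde_ud(pts[1:4, ]), "at least 5")
})

test_that("a single-point UD matches the Gaussian closed form", {
  pt <- cbind(1234.5, 987.6)[rep(1, 5), ]
  h <- 200
  ud <- kde_ud(pt, h = h, resolution = 25)
  # mass within radius R of the point is 1 - exp(-R^2 / 2h^2)
  px <- expand.grid(x = ud$x, y = ud$y)
  rr <- sqrt((px$x - 1234.5)^2 + (px$y - 987.6)^2)
  for (R in c(150, 300, 450)) {
    expect_equal(sum(ud$mass[rr <= R]), 1 - exp(-R^2 / (2 * h^2)),
                 tolerance = 0.01)
  }
})

test_that("volume contours nest and capture the requested mass", {
  set.seed(2)
  pts <- cbind(rnorm(60, 0, 500), rnorm(60, 0, 300))
  ud <- kde_ud(pts, h = 200, resolution = 50)
  c50 <- volume_contour(ud, 0.5)
  c90 <- volume_contour(ud, 0.9)
  expect_lt(c50$area_km2, c90$area_km2)
  expect_true(all(c90$mask[c50$mask]))  # 50% region inside 90% region
  for (cc in list(c50, c90)) {
    expect_gte(cc$mass_captured, cc$level)
    expect_lte(cc$mass_captured, cc$level + max(ud$mass))
  }
  expect_error(volume_contour(ud, 1.2), "level")
})

test_that("two far-apart clusters give a two-component home range", {
  set.seed(3)
  pts <- rbind(cbind(rnorm(30, 0, 150), rnorm(30, 0, 150)),
               cbind(rnorm(30, 6000, 150), rnorm(30, 0, 150)))
  ud <- kde_ud(pts, h = 200, resolution = 50)
  c90 <- volume_contour(ud, 0.9)
  expect_equal(n_components(c90$mask), 2)
})

test_that("overlap percentages follow set geometry", {
  # build contours directly from masks on a shared raster
  mk <- function(mask) structure(
    list(mask = mask, level = 0.9, area_km2 = sum(mask) * 0.0025,
         mass_captured = 0.9, x = seq(25, 5000, 50), y = seq(25, 5000, 50),
         resolution = 50), class = "range_contour")
  base <- matrix(FALSE, 100, 100)
  sq <- base; sq[11:50, 11:50] <- TRUE          # 40 x 40 px square
  right <- base; right[31:50, 11:50] <- TRUE    # right half of the square
  off <- base; off[61:90, 61:90] <- TRUE        # disjoint square

  rep1 <- overlap_report(list(A = mk(sq), B = mk(sq)))
  expect_equal(rep1$pct_overlap, c(100, 100))
  expect_equal(rep1$exclusive_km2, c(0, 0))

  rep2 <- overlap_report(list(A = mk(sq), B = mk(off)))
  expect_equal(rep2$pct_overlap, c(0, 0))
  expect_equal(rep2$exclusive_km2, rep2$area_km2)

  rep3 <- overlap_report(list(A = mk(sq), B = mk(right)))
  expect_equal(rep3$pct_overlap, c(50, 100))
  pw <- attr(rep3, "pairwise")
  expect_equal(pw["A", "B"], 50)
  expect_equal(pw["B", "A"], 100)
  # shared areas are symmetric even though percentages are not
  expect_equal(rep3$shared_km2[1], rep3$shared_km2[2])

  expect_error(overlap_report(list(A = mk(sq))), "at least 2")
  expect_error(overlap_report(list(A = mk(sq), B = mk(base))), "degenerate")
})

test_that("area-weighted energy density averages cell intersections", {
  g2 <- make_grid(0, 0, 500, 2, 1)
  mk <- function(cols) {
    mask <- matrix(FALSE, 20, 10)
    mask[cols, ] <- TRUE
    structure(list(mask = mask, level = 0.9,
                   area_km2 = sum(mask) * 0.0025, mass_captured = 0.9,
                   x = seq(25, 1000, 50), y = seq(25, 500, 50),
                   resolution = 50), class = "range_contour")
  }
  f_uniform <- energy_field(g2, matrix(7, 2, 1))
  expect_equal(weighted_energy_density(mk(1:20), f_uniform), 7)
  # half the region over a 2-cell, half over a 4-cell -> 3
  f24 <- energy_field(g2, matrix(c(2, 4), 2, 1))
  expect_equal(weighted_energy_density(mk(6:15), f24), 3)
  # additivity: value is the area-weighted mean of disjoint pieces
  v_left <- weighted_energy_density(mk(6:10), f24)
  v_right <- weighted_energy_density(mk(11:15), f24)
  expect_equal(weighted_energy_density(mk(6:15), f24),
               (v_left + v_right) / 2)
  # fully masked region errors
  f_mask <- energy_field(g2, matrix(c(NA, 4), 2, 1))
  expect_error(weighted_energy_density(mk(1:5), f_mask), "without food data")
})

test_that("region difference supports core-vs-rest comparisons", {
  set.seed(4)
  pts <- cbind(rnorm(50, 0, 400), rnorm(50, 0, 400))
  ud <- kde_ud(pts, h = 200, resolution = 50)
  hr <- volume_contour(ud, 0.9); core <- volume_contour(ud, 0.5)
  rest <- region_difference(hr, core)
  expect_equal(rest$area_km2, hr$area_km2 - core$area_km2, tolerance = 1e-9)
  expect_false(any(rest$mask & core$mask))
})

test_that("subsampling sensitivity is deterministic and anchored at 1.0", {
  set.seed(5)
  pts <- cbind(rnorm(80, 0, 500), rnorm(80, 0, 500))
  s1 <- subsample_sensitivity(pts, fractions = c(0.5, 1), n_rep = 10, seed = 3)
  s2 <- subsample_sensitivity(pts, fractions = c(0.5, 1), n_rep = 10, seed = 3)
  expect_identical(s1, s2)
  full <- volume_contour(kde_ud(pts, 200, 50), 0.9)$area_km2
  expect_equal(s1$mean_km2[s1$fraction == 1], full)
  expect_equal(s1$sd_km2[s1$fraction == 1], 0)
  expect_warning(subsample_sensitivity(pts[1:8, ], fractions = 0.5,
                                       n_rep = 2, seed = 1), "skipped")
})

test_that("area variability shrinks as the subsample grows", {
  set.seed(6)
  pts <- cbind(rnorm(120, 0, 600), rnorm(120, 0, 600))
  s <- subsample_sensitivity(pts, fractions = c(0.3, 0.9), n_rep = 50, seed = 2)
  expect_lt(s$sd_km2[s$fraction == 0.9], s$sd_km2[s$fraction == 0.3])
})

test_that("GeoJSON export writes a valid MultiPolygon of the region", {
  set.seed(7)
  pts <- cbind(rnorm(30, 0, 300), rnorm(30, 0, 300))
  cc <- volume_contour(kde_ud(pts, 200, 100), 0.5)
  path <- withr::local_tempfile(fileext = ".geojson")
  contour_to_geojson(cc, path, name = "core")
  gj <- jsonlite::read_json(path)
  expect_equal(gj$geometry$type, "MultiPolygon")
  expect_equal(gj$properties$area_km2, cc$area_km2)
  # total rectangle area equals the raster area
  area <- sum(vapply(gj$geometry$coordinates, function(poly) {
    ring <- poly[[1]]
    xs <- vapply(ring, function(p) p[[1]], 0)
    ys <- vapply(ring, function(p) p[[2]], 0)
    diff(range(xs)) * diff(range(ys))
  }, 0)) / 1e6
  expect_equal(area, cc$area_km2, tolerance = 1e-9)
})
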