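# Layer geometry: centroid, resampling, rays, midline, layer assignment.

test_that("blood-pool centre is the endo area centroid", {
  cs <- contour_set(circle_contour(c(50, 50), 15), circle_contour(c(50, 50), 25))
  expect_equal(blood_pool_center(cs), c(50, 50), tolerance = 1e-9)

  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(polygon_centroid(sq), c(5, 5))

  # crescent-like non-convex polygon vs a Monte-Carlo rejection oracle
  th_out <- seq(-2.3, 2.3, length.out = 60)
  th_in <- rev(seq(-2.0, 2.0, length.out = 50))
  cres <- rbind(cbind(20 * cos(th_out), 20 * sin(th_out)),
                cbind(12 * cos(th_in) + 4, 12 * sin(th_in)))
  got <- polygon_centroid(cres)
  set.seed(8)
  px <- runif(4e5, -25, 25); py <- runif(4e5, -25, 25)
  keep <- point_in_polygon(px, py, cres)
  expect_lt(max(abs(got - c(mean(px[keep]), mean(py[keep])))), 0.1)

  expect_error(polygon_centroid(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("resampling is exact for identity, constants and affine fields", {
  ph <- circle_phantom(spacing = 1, endo_value = 2, epi_value = 2,
                       profile = "uniform")
  same <- interpolate_map(ph$map, 1.0)
  expect_equal(same$values, ph$map$values)

  half <- interpolate_map(ph$map, 0.5)
  expect_equal(half$spacing, c(0.5, 0.5))
  expect_setequal(unique(half$values[!is.na(half$values)]), 2)

  # bilinear reproduces an affine field exactly in the interior
  x <- (seq_len(30) - 0.5) * 2; y <- (seq_len(24) - 0.5) * 2
  plane <- outer(y, x, function(yy, xx) 0.03 * xx + 0.05 * yy + 0.4)
  m <- perfusion_map(plane, 2, slice = "mid", state = "rest")
  fine <- interpolate_map(m, 1)
  xf <- (seq_len(ncol(fine$values)) - 0.5); yf <- (seq_len(nrow(fine$values)) - 0.5)
  expected <- outer(yf, xf, function(yy, xx) 0.03 * xx + 0.05 * yy + 0.4)
  interior <- 3:(length(yf) - 3)
  expect_equal(fine$values[interior, interior], expected[interior, interior],
               tolerance = 1e-12)

  expect_error(interpolate_map(m, 1000), "extent")
})

test_that("ray fans are uniform, ordered and symmetric", {
  r360 <- cast_rays(360)
  expect_equal(diff(attr(r360, "angles_deg")), rep(1, 359))
  r4 <- cast_rays(8)[c(1, 3, 5, 7), ]
  expect_equal(abs(r4 %*% t(r4)) < 1e-12 | abs(abs(r4 %*% t(r4)) - 1) < 1e-12,
               matrix(TRUE, 4, 4))
  for (n in c(8, 17, 90, 360)) {
    expect_lt(max(abs(colSums(cast_rays(n)))), 1e-10)
  }
  expect_error(cast_rays(4), ">= 8")
})

test_that("midline of concentric circles is the mid-radius circle", {
  cs <- contour_set(circle_contour(c(40, 40), 20), circle_contour(c(40, 40), 30))
  ml <- compute_midline(cs)
  expect_equal(nrow(ml), 360)
  expect_lt(max(abs(midline_radii(ml) - 25)), 0.01)
})

test_that("midline matches a 0.01 mm ray-march oracle on confocal ellipses", {
  ctr <- c(40, 40)
  cs <- contour_set(ellipse_contour(ctr, c(20, 15)), ellipse_contour(ctr, c(30, 25)))
  ml <- compute_midline(cs)
  th <- (0:359) * pi / 180
  ts <- seq(0.01, 40, by = 0.01)
  march <- function(ab) {
    vapply(th, function(a) {
      f <- ((ctr[1] + ts * cos(a) - 40) / ab[1])^2 +
        ((ctr[2] + ts * sin(a) - 40) / ab[2])^2
      i <- which(f > 1)[1]
      (ts[i - 1] + ts[i]) / 2
    }, numeric(1))
  }
  oracle <- (march(c(20, 15)) + march(c(30, 25))) / 2
  expect_lt(max(abs(midline_radii(ml) - oracle)), 0.05)
})

test_that("midline is translation-equivariant", {
  base <- contour_set(ellipse_contour(c(40, 40), c(18, 14)),
                      ellipse_contour(c(40, 40), c(28, 24)))
  shift <- c(3.7, -2.1)
  moved <- contour_set(sweep(base$endo, 2, -shift),
                       sweep(base$epi, 2, -shift))
  expect_equal(unclass(compute_midline(moved))[, 1],
               unclass(compute_midline(base))[, 1] + shift[1], tolerance = 1e-9)
  expect_equal(unclass(compute_midline(moved))[, 2],
               unclass(compute_midline(base))[, 2] + shift[2], tolerance = 1e-9)
})

test_that("severely non-star-shaped contours are rejected with the ray angle", {
  # horseshoe-shaped epi (thick C open at the top) with the endo contour in
  # its left arm: rays pointing across the central hole cross the epi
  # boundary three times
  ctr <- c(50, 50)
  th_out <- seq(100, 440, by = 2) * pi / 180          # outer arc, CCW
  th_in <- rev(th_out)                                 # inner arc, CW back
  epi <- rbind(cbind(ctr[1] + 30 * cos(th_out), ctr[2] + 30 * sin(th_out)),
               cbind(ctr[1] + 18 * cos(th_in), ctr[2] + 18 * sin(th_in)))
  arm <- ctr + 24 * c(cos(200 * pi / 180), sin(200 * pi / 180))
  endo <- circle_contour(arm, 4, n = 90)
  cs <- contour_set(endo, epi)
  expect_error(compute_midline(cs), "crosses the epicardial contour")
})

test_that("layer assignment partitions the myocardium and orders radially", {
  ph <- circle_phantom(spacing = 0.5)
  lm <- assign_layers(ph$map, ph$contours)
  expect_identical(lm$endo_layer & lm$epi_layer,
                   matrix(FALSE, nrow(lm$myocardium), ncol(lm$myocardium)))
  expect_identical(lm$endo_layer | lm$epi_layer, lm$myocardium)
  # specific pixels: radius 22 is endo, radius 28 is epi
  ctr <- ph$spec$center
  px <- function(r) {
    c(row = round((ctr[2] / 0.5) + 0.5), col = round(((ctr[1] + r) / 0.5) + 0.5))
  }
  p1 <- px(22); p2 <- px(28)
  expect_true(lm$endo_layer[p1["row"], p1["col"]])
  expect_true(lm$epi_layer[p2["row"], p2["col"]])
})

test_that("layer pixel counts match the analytic half-annulus areas", {
  ph <- make_phantom(phantom_spec(grid_shape = c(280, 280), pixel_spacing = 0.25,
                                  endo_radius = 20, epi_radius = 30,
                                  endo_value = 1, epi_value = 1,
                                  profile = "uniform"))
  lm <- assign_layers(ph$map, ph$contours)
  # half-annulus areas: inner 225*pi, outer 275*pi
  expect_equal(sum(lm$endo_layer) / sum(lm$epi_layer), 225 / 275,
               tolerance = 0.01)
})

test_that("rotating map and contours by 90 degrees leaves layer means unchanged", {
  ph <- make_phantom(phantom_spec(grid_shape = c(100, 100), pixel_spacing = 0.8,
                                  center = c(36, 44), endo_radius = c(16, 13),
                                  epi_radius = c(26, 22), endo_value = 1.3,
                                  epi_value = 0.9, profile = "linear"))
  lm <- assign_layers(ph$map, ph$contours)
  means <- c(region_mean_mbf(ph$map, lm$endo_layer),
             region_mean_mbf(ph$map, lm$epi_layer))
  # rotate 90 deg CCW about the grid centre: old (r, c) -> new (c, n+1-r)
  n <- 100
  v <- ph$map$values
  vr <- matrix(NA_real_, n, n)
  vr[cbind(as.vector(col(v)), n + 1 - as.vector(row(v)))] <- as.vector(v)
  ext <- n * 0.8
  rot <- function(p) cbind(ext / 2 - (p[, 2] - ext / 2), ext / 2 + (p[, 1] - ext / 2))
  csr <- contour_set(rot(ph$contours$endo), rot(ph$contours$epi))
  mr <- perfusion_map(vr, 0.8, slice = "mid", state = "rest")
  lmr <- assign_layers(mr, csr)
  expect_equal(region_mean_mbf(mr, lmr$endo_layer), means[1], tolerance = 1e-12)
  expect_equal(region_mean_mbf(mr, lmr$epi_layer), means[2], tolerance = 1e-12)
})

test_that("contour validation rejects malformed inputs", {
  expect_error(contour_set(circle_contour(c(50, 50), 25),
                           circle_contour(c(50, 50), 15)),
               "not strictly inside")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(contour_set(bowtie, circle_contour(c(5, 5), 40)),
               "self-intersecting")
})
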