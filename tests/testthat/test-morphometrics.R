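# 2D and inferred-3D morphometrics of tracings.

test_that("circularity matches closed forms for canonical outlines", {
  sq <- circularity_2d(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sq$area_2d, 1)
  expect_equal(sq$perimeter, 4)
  expect_equal(sq$circularity, pi / 4, tolerance = 1e-12)

  circ <- circularity_2d(regular_polygon(10000L, R = 300))
  expect_lt(abs(circ$circularity - 1), 1e-5)

  # stadium: straight length 500, cap radius 125
  stadium <- generate_stadium_trace(500, 125, n_outline = 4000L)
  cf <- stadium_forms(500, 125)
  m <- circularity_2d(stadium$outline)
  expect_lt(abs(m$area_2d - cf$area) / cf$area, 1e-3)
  expect_lt(abs(m$perimeter - cf$perimeter) / cf$perimeter, 1e-3)
  expect_lt(abs(m$circularity - cf$circularity), 1e-3)
})

test_that("invalid outlines are rejected", {
  expect_error(circularity_2d(cbind(c(0, 1), c(0, 1))),
               class = "mitoshape_invalid_trace")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(circularity_2d(bowtie), class = "mitoshape_invalid_trace")
  expect_error(mito_trace(bowtie), class = "mitoshape_invalid_trace")
  expect_error(mito_trace(cbind(c(0, 1, 2), c(0, 0, 0))),
               class = "mitoshape_invalid_trace")  # collinear
})

test_that("circularity is invariant under rigid motion and scaling", {
  tr <- generate_stadium_trace(600, 140, jitter = 0.05, seed = 4)
  base <- circularity_2d(tr$outline)$circularity
  th <- 0.83
  rot <- tr$outline %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(rot, 2, c(1234, -987), "+")
  expect_equal(circularity_2d(moved)$circularity, base, tolerance = 1e-10)
  expect_equal(circularity_2d(tr$outline * 7.3)$circularity, base,
               tolerance = 1e-10)
})

test_that("diameter estimation recovers the stadium width", {
  tr <- generate_stadium_trace(500, 125, n_outline = 400L)
  d <- estimate_diameter(tr$outline)
  expect_lt(abs(as.numeric(d) - 250) / 250, 0.01)
  expect_identical(attr(d, "method"), "chord")

  circle <- regular_polygon(720L, R = 300)
  dc <- estimate_diameter(circle)
  expect_lt(abs(as.numeric(dc) - 600) / 600, 0.01)
  expect_identical(attr(dc, "method"), "caliper")
  expect_true(attr(dc, "flagged"))
})

test_that("diameter estimate is robust to 2% outline jitter", {
  errs <- vapply(1:100, function(s) {
    tr <- generate_stadium_trace(500, 125, jitter = 0.02, seed = s)
    abs(as.numeric(estimate_diameter(tr$outline)) - 250) / 250
  }, 0)
  expect_true(all(errs < 0.05))
})

test_that("2D cristae fraction follows the doubling formula", {
  # outline: square of side 500 -> perimeter exactly 2000
  square <- cbind(c(0, 500, 500, 0), c(0, 0, 500, 500))
  three <- lapply(c(100, 250, 400), function(x)
    cbind(c(x, x), c(150, 350)))  # three cristae of length 200
  tr <- mito_trace(square, three)
  expect_equal(cristae_fraction_2d(tr), 100 * 1200 / 3200,
               tolerance = 1e-12)

  expect_equal(cristae_fraction_2d(mito_trace(square)), 0)

  one_half_P <- mito_trace(square,
                           list(cbind(c(250, 250), c(-250, 750))))
  expect_equal(cristae_fraction_2d(one_half_P), 50, tolerance = 1e-12)
})

test_that("3D transformation composes ring and disk constructions", {
  square <- cbind(c(0, 500, 500, 0), c(0, 0, 500, 500))  # P = 2000
  three <- lapply(c(100, 250, 400), function(x)
    cbind(c(x, x), c(150, 350)))  # lengths 200
  tr <- mito_trace(square, three)
  f3 <- cristae_fraction_3d(tr, diameter = 250)
  expect_equal(f3$S_boundary, pi * 125 * 2000, tolerance = 1e-12)
  expect_equal(f3$S_cristae, 3 * 2 * pi * 100^2, tolerance = 1e-12)
  expect_equal(f3$percent, 100 * f3$S_cristae / (f3$S_cristae + f3$S_boundary),
               tolerance = 1e-12)
  expect_lt(abs(f3$percent - 19.355), 0.01)
  expect_length(f3$flagged_cristae, 0)

  # a single disk: crista of length 250 with R = 125
  one <- mito_trace(square, list(cbind(c(250, 250), c(125, 375))))
  expect_equal(cristae_fraction_3d(one, diameter = 250)$S_cristae,
               2 * pi * 125^2, tolerance = 1e-12)

  # over-long crista is flagged, not dropped
  long <- mito_trace(square, list(cbind(c(250, 250), c(0, 500))))
  f3l <- cristae_fraction_3d(long, diameter = 250)
  expect_identical(f3l$flagged_cristae, 1L)
  expect_gt(f3l$S_cristae, 0)
})

test_that("both fractions increase monotonically with crista length", {
  square <- cbind(c(0, 500, 500, 0), c(0, 0, 500, 500))
  lens <- seq(50, 400, by = 50)
  f2 <- vapply(lens, function(l) {
    tr <- mito_trace(square, list(cbind(c(250, 250), c(250 - l / 2, 250 + l / 2))))
    cristae_fraction_2d(tr)
  }, 0)
  f3 <- vapply(lens, function(l) {
    tr <- mito_trace(square, list(cbind(c(250, 250), c(250 - l / 2, 250 + l / 2))))
    cristae_fraction_3d(tr, diameter = 250)$percent
  }, 0)
  expect_true(all(diff(f2) > 0))
  expect_true(all(diff(f3) > 0))
})

test_that("polygon measures converge as O(1/n^2) for regular n-gons", {
  err <- vapply(c(100L, 200L), function(n) {
    abs(circularity_2d(regular_polygon(n))$circularity - 1)
  }, 0)
  expect_gt(err[1L] / err[2L], 3.5)
})

test_that("measure_trace assembles the full row", {
  tr <- generate_stadium_trace(500, 125, n_cristae = 3, id = "m1",
                               timestamp = 12, group_label = "ctrl")
  row <- measure_trace(tr)
  expect_identical(row$id, "m1")
  expect_identical(row$n_cristae, 3L)
  expect_false(row$no_cristae)
  expect_identical(row$timestamp, 12)
  expect_identical(row$group_label, "ctrl")
  expect_gt(row$cristae_frac_3d, 0)
})
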