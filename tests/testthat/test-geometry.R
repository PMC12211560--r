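# Axisymmetric geometry: spheres, spheroids, membrane areas and the
# differential-geometric invariants they must satisfy.

test_that("discretized sphere reproduces its closed-form geometry", {
  A_target <- 4 * pi * 250^2  # diameter 500 nm
  sph <- make_sphere(A_target)
  g <- geometry_report(sph)
  expect_lt(abs(g$area - A_target) / A_target, 1e-6)
  expect_lt(abs(g$integrated_mean_curvature - 8 * pi * 250) / (8 * pi * 250),
            1e-6)
  expect_lt(abs(g$volume - 4 / 3 * pi * 250^3) / (4 / 3 * pi * 250^3), 1e-6)
  expect_lt(abs(g$sphericity_3d - 1), 1e-6)
  # J constant = 2/R at every node
  expect_lt(max(abs(g$mean_curvature_profile - 2 / 250)), 1e-9)

  unit <- geometry_report(make_sphere(4 * pi))
  expect_lt(abs(unit$area - 4 * pi) / (4 * pi), 1e-6)
  expect_lt(abs(max(make_sphere(4 * pi)$r) - 1), 1e-9)
})

test_that("sphere construction rejects non-positive area", {
  expect_error(make_sphere(0), class = "mitoshape_invalid_parameter")
  expect_error(make_sphere(-5), class = "mitoshape_invalid_parameter")
})

test_that("spheroid area and volume match closed forms", {
  sp <- make_spheroid(500, 250, n_nodes = 401L)
  g <- geometry_report(sp)
  cf <- spheroid_closed_forms(500, 250)
  expect_lt(abs(g$area - cf$area) / cf$area, 1e-4)
  expect_lt(abs(g$volume - cf$volume) / cf$volume, 1e-4)
})

test_that("profile constructor validates its inputs", {
  u <- seq(0, 1, length.out = 51)
  expect_error(axisym_shape(s = rev(u), psi = pi * u),
               class = "mitoshape_invalid_parameter")
  expect_error(axisym_shape(s = u[1:3], psi = pi * u[1:3]),
               class = "mitoshape_invalid_parameter")
  # open profile (psi never reaches pi) is detected and rejected downstream
  open_shape <- axisym_shape(s = u, psi = pi * u / 2)
  expect_false(open_shape$closed)
  expect_error(geometry_report(open_shape),
               class = "mitoshape_invalid_shape")
})

test_that("interior zero radius is flagged as degenerate", {
  sph <- make_sphere(4 * pi)
  r <- sph$r
  r[100] <- 0
  pinched <- axisym_shape(s = sph$s, psi = sph$psi, r = r, z = sph$z,
                          closed = TRUE)
  expect_error(geometry_report(pinched),
               class = "mitoshape_degenerate_shape")
})

test_that("mirror-symmetric tilt profiles give mirror-symmetric radii", {
  sh <- make_dumbbell(-0.6)
  expect_lt(max(abs(sh$r - rev(sh$r))), 1e-9 * max(sh$r))
})

test_that("membrane areas follow the curvature relation dA = d M", {
  sph <- make_sphere(4 * pi * 250^2)
  sys <- membrane_areas(sph, d = 10)
  # sphere: dA/A = 2 d / R
  expect_lt(abs(sys$dAoverA - 0.08), 1e-6)
  expect_lt(abs(sys$area_diff - 10 * 8 * pi * 250) / (10 * 8 * pi * 250),
            1e-6)
  # d = 0 collapses the membranes onto the mid-surface
  sys0 <- membrane_areas(sph, d = 0)
  expect_equal(sys0$area_diff, 0)
  expect_equal(sys0$area_out, sys0$area_in)
  # linearity in d
  sys2 <- membrane_areas(sph, d = 20)
  expect_equal(sys2$area_diff, 2 * sys$area_diff, tolerance = 1e-12)
  # Eqns consistency: (A_out + A_in)/2 = A exactly
  expect_equal((sys$area_out + sys$area_in) / 2, sys$mid_area,
               tolerance = 1e-12)
})

test_that("small-curvature regime violations are rejected with the node", {
  sph <- make_sphere(4 * pi * 250^2)  # |J| d = 2 d / R
  err <- tryCatch(membrane_areas(sph, d = 130), condition = identity)
  expect_s3_class(err, "mitoshape_model_validity")
  expect_true(length(err$nodes) > 0)
  expect_match(conditionMessage(err), "node")
})

test_that("Willmore bound holds for every closed shape, tight only for spheres", {
  sph_E <- geometry_report(make_sphere(4 * pi * 123^2))$j_squared_integral
  expect_lt(abs(sph_E - 16 * pi) / (16 * pi), 1e-3)
  for (seed in 1:12) {
    sh <- random_mild_shape(seed)
    E <- geometry_report(sh)$j_squared_integral
    expect_gte(E, 16 * pi * (1 - 1e-9))
  }
  # a visibly non-spherical member is clear of the bound
  E_db <- geometry_report(make_dumbbell())$j_squared_integral
  expect_gt(E_db, 16 * pi * 1.01)
})

test_that("the bending integral is scale invariant", {
  sh <- make_dumbbell()
  scaled <- axisym_shape(s = 137 * sh$s, psi = sh$psi, r = 137 * sh$r,
                         z = 137 * sh$z, dpsi_ds = sh$dpsi_ds / 137)
  E1 <- geometry_report(sh)$j_squared_integral
  E2 <- geometry_report(scaled)$j_squared_integral
  expect_lt(abs(E1 - E2) / E1, 1e-6)
})

test_that("quadrature errors shrink at least quadratically with resolution", {
  A_true <- 4 * pi * 200^2
  err <- vapply(c(25L, 51L), function(n) {
    abs(geometry_report(make_sphere(A_true, n_nodes = n))$area - A_true)
  }, 0)
  expect_gt(err[1L] / max(err[2L], .Machine$double.eps * A_true), 4)
})
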