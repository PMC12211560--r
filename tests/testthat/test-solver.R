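# Constrained bending-energy minimization: energies, the continuation
# family, shape classification and the prolate-spheroid oracle.

A500 <- 4 * pi * 250^2  # mid-surface area of the 500 nm sphere

test_that("bending energy of any sphere is 16 pi kappa and scale invariant", {
  for (R in c(1, 250, 1e4)) {
    E <- bending_energy(make_sphere(4 * pi * R^2))
    expect_lt(abs(E - 16 * pi) / (16 * pi), 1e-6)
  }
  expect_equal(bending_energy(make_sphere(4 * pi), energy_model(kappa = 25)),
               25 * bending_energy(make_sphere(4 * pi)), tolerance = 1e-12)
})

test_that("bending energy of a spheroid matches independent quadrature", {
  E_pkg <- bending_energy(make_spheroid(500, 250, n_nodes = 401L))
  E_oracle <- spheroid_energy_quadrature(500, 250)
  expect_lt(abs(E_pkg - E_oracle) / E_oracle, 1e-3)
})

test_that("model and option constructors validate parameters", {
  expect_error(energy_model(kappa = -1), class = "mitoshape_invalid_parameter")
  expect_error(energy_model(d = 0), class = "mitoshape_invalid_parameter")
  expect_identical(energy_model()$spontaneous_curvature, 0)
  expect_identical(solver_options(n_nodes = 200L)$n_nodes, 201L)
})

test_that("at the sphere's own area difference the sphere is recovered", {
  sol <- minimize_shape(A500, 0.08, energy_model(d = 10))
  expect_true(sol$solver_diagnostics$converged)
  expect_lt(abs(sol$sphericity - 1), 1e-3)
  expect_lt(abs(sol$energy - 16 * pi) / (16 * pi), 1e-3)
  expect_identical(sol$shape_class, "sphere")
})

test_that("an elevated area difference elongates the shape within the oracle bound", {
  sol <- minimize_shape(A500, 0.12, energy_model(d = 10))
  expect_true(sol$solver_diagnostics$converged)
  expect_lt(sol$sphericity, 1)
  expect_lte(sol$constraint_residuals[["dAoverA"]], 1e-4)
  bound <- trial_prolate_oracle(A500, 0.12, 10)
  expect_lte(sol$energy, bound * (1 + 1e-3))
  expect_gte(sol$energy, 16 * pi)
})

test_that("targets below the sphere value are rejected as oblate-branch", {
  expect_error(minimize_shape(A500, 0.05, energy_model(d = 10)),
               class = "mitoshape_branch_out_of_scope")
  expect_error(shape_family(A500, 10, c(0.10, 0.09)),
               class = "mitoshape_invalid_parameter")
})

test_that("shape classification separates sphere, prolate and dumbbell", {
  expect_identical(classify_shape(make_sphere(4 * pi)), "sphere")
  expect_identical(classify_shape(make_spheroid(500, 250)), "elongated")
  expect_identical(classify_shape(make_dumbbell()), "peanut")
})

test_that("prolate oracle equals the sphere energy at the sphere value", {
  expect_lt(abs(trial_prolate_oracle(A500, 0.08, 10) - 16 * pi) / (16 * pi),
            1e-6)
  expect_gt(trial_prolate_oracle(A500, 0.12, 10), 16 * pi)
  expect_error(trial_prolate_oracle(A500, 0.2, 10, max_aspect = 2),
               class = "mitoshape_unreachable")
  expect_error(trial_prolate_oracle(A500, 0.05, 10),
               class = "mitoshape_branch_out_of_scope")
})

test_that("the solution is insensitive to perturbation seed and mesh", {
  s_ref <- minimize_shape(A500, 0.12, energy_model(d = 10),
                          solver_options(seed = 0))
  s_seed <- minimize_shape(A500, 0.12, energy_model(d = 10),
                           solver_options(seed = 99))
  expect_lt(abs(s_ref$sphericity - s_seed$sphericity), 1e-3)
  s_fine <- minimize_shape(A500, 0.12, energy_model(d = 10),
                           solver_options(n_nodes = 401L))
  expect_lt(abs(s_ref$sphericity - s_fine$sphericity), 1e-3)
})
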