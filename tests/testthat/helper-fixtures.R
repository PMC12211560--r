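# Shared fixtures and independent oracles.

# Independent dense quadrature of the bending integrand of a spheroid with
# polar semi-axis a and equatorial semi-axis b, using the closed-form
# parametric principal curvatures of an ellipse of revolution. This path
# shares no code with the package's profile machinery.
spheroid_energy_quadrature <- function(a, b, n = 20001L) {
  theta <- seq(0, pi, length.out = n)
  h <- theta[2L] - theta[1L]
  g <- sqrt(b^2 * cos(theta)^2 + a^2 * sin(theta)^2)
  k_meridian <- a * b / g^3
  k_parallel <- a / (b * g)
  J <- k_meridian + k_parallel
  integrand <- J^2 * 2 * pi * b * sin(theta) * g
  # composite Simpson (n odd)
  s <- integrand[1L] + integrand[n] +
    4 * sum(integrand[seq(2L, n - 1L, by = 2L)]) +
    2 * sum(integrand[seq(3L, n - 2L, by = 2L)])
  h * s / 3
}

# closed-form area / volume of a prolate spheroid (a > b)
spheroid_closed_forms <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  list(area = 2 * pi * b^2 * (1 + (a / b) / e * asin(e)),
       volume = 4 / 3 * pi * b^2 * a)
}

# mirror-symmetric dumbbell profile: two lobes bridged by a neck of about
# 0.8 x the lobe radius (tilt-angle perturbation pi u - 0.8 sin(4 pi u))
make_dumbbell <- function(a2 = -0.8, n = 201L) {
  u <- seq(0, 1, length.out = n)
  axisym_shape(s = u, psi = pi * u + a2 * sin(4 * pi * u),
               dpsi_ds = pi + a2 * 4 * pi * cos(4 * pi * u))
}

# regular polygon approximating a circle of radius R
regular_polygon <- function(n, R = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(R * cos(th), R * sin(th))
}

# stadium closed forms (straight length L, cap radius R)
stadium_forms <- function(L, R) {
  area <- 2 * R * L + pi * R^2
  per <- 2 * L + 2 * pi * R
  list(area = area, perimeter = per, circularity = 4 * pi * area / per^2)
}

# random mild closed profile in the tilt-angle sine basis (for invariant
# sweeps); valid by construction for small amplitudes
random_mild_shape <- function(seed, n = 201L, amp = 0.25) {
  withr::with_seed(seed, {
    u <- seq(0, 1, length.out = n)
    k <- 1:6
    a <- amp * rnorm(6) / k^2
    psi <- pi * u + drop(sin(outer(u, 2 * pi * k)) %*% a)
    dpsi <- pi + drop((2 * pi * k * t(cos(outer(u, 2 * pi * k)))) |>
                        t() %*% a)
    axisym_shape(s = u, psi = psi, dpsi_ds = dpsi)
  })
}

# generate + measure a cohort quietly
measured_cohort <- function(spec) {
  gc <- suppressWarnings(generate_cohort(spec))
  suppressMessages(measure_cohort(gc$traces))
}
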