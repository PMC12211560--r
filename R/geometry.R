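# Axisymmetric mid-surface geometry.
#
# The coupled OMM/IBM system is represented by its mid-surface, a surface of
# revolution described by a 1D profile: arclength s, tangent tilt angle psi
# (angle between the profile tangent and the plane normal to the symmetry
# axis), radius r and axial coordinate z, with
#   dr/ds = cos(psi),  dz/ds = sin(psi).
# The total (twice-mean) curvature is J = dpsi/ds + sin(psi)/r, with the
# L'Hopital limit J -> 2 dpsi/ds at the poles (r -> 0). Gaussian-curvature
# contributions are neglected throughout (small-curvature regime |J| d << 1).

# ---- quadrature helpers ----

# composite Simpson on a uniform grid; falls back to trapezoid + 3/8 blend
# when the number of intervals is odd
.simpson <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(0)
  if (n == 2L) return(h * (y[1L] + y[2L]) / 2)
  if (n %% 2L == 1L) {
    idx <- seq(2L, n - 1L, by = 2L)
    s <- y[1L] + y[n] + 4 * sum(y[idx]) +
      2 * sum(y[seq(3L, n - 2L, by = 2L)])
    return(h * s / 3)
  }
  # even number of nodes: Simpson on the first n-3 intervals, 3/8 on the rest
  if (n == 4L) return(h * 3 / 8 * (y[1L] + 3 * y[2L] + 3 * y[3L] + y[4L]))
  .simpson(y[1:(n - 3L)], h) +
    h * 3 / 8 * (y[n - 3L] + 3 * y[n - 2L] + 3 * y[n - 1L] + y[n])
}

# integral on a possibly non-uniform grid (trapezoid); used when profiles
# come from external sources
.trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

.is_uniform <- function(x, tol = 1e-8) {
  d <- diff(x)
  diff(range(d)) <= tol * max(abs(d))
}

# cumulative integral of f on a uniform grid with Hermite end correction
# (4th order when the derivative fp is supplied, else plain trapezoid)
.cumtrapz <- function(f, h, fp = NULL) {
  n <- length(f)
  inc <- h * (f[-n] + f[-1L]) / 2
  if (!is.null(fp)) inc <- inc - h^2 / 12 * (fp[-1L] - fp[-n])
  c(0, cumsum(inc))
}

# centered finite-difference derivative on an arbitrary grid
.fdiff <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (x[3:n] - x[1:(n - 2L)])
  d
}

# ---- AxisymmetricShape ----

#' Construct an axisymmetric shape from its profile
#'
#' Builds the discretized profile of a surface of revolution from arclength
#' and tilt-angle samples. Radius and axial position are obtained by
#' integrating `dr/ds = cos(psi)`, `dz/ds = sin(psi)`; they can also be
#' supplied directly (e.g. when importing a profile CSV).
#'
#' @param s strictly increasing arclength samples (nm), starting at 0.
#' @param psi tilt angle of the profile tangent (radians). A closed shape has
#'   `psi = 0` at the starting pole and `psi = pi` at the ending pole.
#' @param r,z optional radius / axial samples (nm); integrated from `psi`
#'   when omitted.
#' @param dpsi_ds optional analytic derivative of `psi` with respect to
#'   arclength (1/nm). Stored when available so curvature evaluations do not
#'   rely on finite differences.
#' @param closed logical; if `NULL` (default), closure is detected from the
#'   pole conditions.
#'
#' @return An object of class `axisym_shape`: a list with fields `s`, `psi`,
#'   `r`, `z`, `dpsi_ds`, `closed` and `n_nodes`.
#' @seealso [make_sphere()], [make_spheroid()], [geometry_report()]
#' @export
axisym_shape <- function(s, psi, r = NULL, z = NULL, dpsi_ds = NULL,
                         closed = NULL) {
  n <- length(s)
  if (n < 5L) .err("mitoshape_invalid_parameter", "profile needs >= 5 nodes")
  if (length(psi) != n)
    .err("mitoshape_invalid_parameter", "s and psi lengths differ")
  if (any(diff(s) <= 0))
    .err("mitoshape_invalid_parameter", "arclength must be strictly increasing")
  if (abs(s[1L]) > 1e-9 * s[n])
    .err("mitoshape_invalid_parameter", "arclength must start at 0")
  if (is.null(dpsi_ds)) dpsi_num <- .fdiff(s, psi) else dpsi_num <- dpsi_ds
  if (is.null(r)) {
    if (.is_uniform(s)) {
      h <- s[2L] - s[1L]
      r <- .cumtrapz(cos(psi), h, fp = -sin(psi) * dpsi_num)
      z <- .cumtrapz(sin(psi), h, fp = cos(psi) * dpsi_num)
    } else {
      r <- c(0, cumsum(diff(s) * (cos(psi)[-n] + cos(psi)[-1L]) / 2))
      z <- c(0, cumsum(diff(s) * (sin(psi)[-n] + sin(psi)[-1L]) / 2))
    }
  } else if (is.null(z)) {
    z <- c(0, cumsum(diff(s) * (sin(psi)[-n] + sin(psi)[-1L]) / 2))
  }
  rmax <- max(r)
  if (is.null(closed)) {
    closed <- abs(psi[1L]) < 1e-6 && abs(psi[n] - pi) < 1e-6 &&
      abs(r[1L]) < 1e-6 * rmax && abs(r[n]) < 1e-5 * rmax
  }
  if (closed) {
    r[1L] <- 0
    r[n] <- 0
  }
  if (any(r[2:(n - 1L)] < 0))
    .err("mitoshape_degenerate_shape", "negative radius in profile interior")
  structure(
    list(s = s, psi = psi, r = r, z = z, dpsi_ds = dpsi_ds,
         closed = closed, n_nodes = n),
    class = "axisym_shape"
  )
}

#' @export
print.axisym_shape <- function(x, ...) {
  g <- try(geometry_report(x), silent = TRUE)
  cat(sprintf("<axisym_shape> %d nodes, %s, length %.1f nm\n",
              x$n_nodes, if (x$closed) "closed" else "open",
              max(x$s)))
  if (!inherits(g, "try-error"))
    cat(sprintf("  area %.4g nm^2, volume %.4g nm^3, sphericity %.4f\n",
                g$area, g$volume, g$sphericity_3d))
  invisible(x)
}

# total curvature J(s) = dpsi/ds + sin(psi)/r, pole limit 2 dpsi/ds
.curvature_profile <- function(shape) {
  n <- shape$n_nodes
  dpsi <- if (is.null(shape$dpsi_ds)) .fdiff(shape$s, shape$psi) else shape$dpsi_ds
  J <- numeric(n)
  interior <- shape$r > 0
  J[interior] <- dpsi[interior] + sin(shape$psi[interior]) / shape$r[interior]
  J[!interior] <- 2 * dpsi[!interior]
  J
}

.surface_integral <- function(shape, integrand) {
  if (.is_uniform(shape$s)) {
    .simpson(integrand, shape$s[2L] - shape$s[1L])
  } else {
    .trapz(shape$s, integrand)
  }
}

#' Differential-geometric summary of a closed axisymmetric shape
#'
#' Computes surface area, enclosed volume, the total-curvature profile
#' `J(s)`, its surface integral `M = integral of J dA`, and the sphericity
#' `36 pi V^2 / A^3` (one for a perfect sphere, decreasing with elongation).
#'
#' @param shape an [axisym_shape()].
#' @return A list with `area` (nm^2), `volume` (nm^3),
#'   `integrated_mean_curvature` M (nm), `mean_curvature_profile` J(s)
#'   (1/nm), `j_squared_integral` (dimensionless) and `sphericity_3d`.
#' @examples
#' g <- geometry_report(make_sphere(4 * pi * 250^2))
#' g$sphericity_3d  # 1 up to quadrature error
#' @export
geometry_report <- function(shape) {
  stopifnot(inherits(shape, "axisym_shape"))
  if (!shape$closed)
    .err("mitoshape_invalid_shape", "geometry_report requires a closed shape")
  n <- shape$n_nodes
  if (any(shape$r[2:(n - 1L)] <= 0))
    .err("mitoshape_degenerate_shape",
         "radius vanishes at an interior node; shape is degenerate")
  J <- .curvature_profile(shape)
  ring <- 2 * pi * shape$r
  area <- .surface_integral(shape, ring)
  volume <- .surface_integral(shape, pi * shape$r^2 * sin(shape$psi))
  M <- .surface_integral(shape, ring * J)
  E2 <- .surface_integral(shape, ring * J^2)
  list(
    area = area,
    volume = volume,
    integrated_mean_curvature = M,
    mean_curvature_profile = J,
    j_squared_integral = E2,
    sphericity_3d = 36 * pi * volume^2 / area^3
  )
}

#' Discretized sphere of a given mid-surface area
#'
#' @param mid_area target surface area (nm^2).
#' @param n_nodes number of profile nodes (default 201).
#' @return A closed [axisym_shape()] sphere of radius
#'   `sqrt(mid_area / (4 pi))`.
#' @examples
#' sph <- make_sphere(4 * pi * 250^2)  # diameter 500 nm
#' @export
make_sphere <- function(mid_area, n_nodes = 201L) {
  if (!is.numeric(mid_area) || length(mid_area) != 1L || mid_area <= 0)
    .err("mitoshape_invalid_parameter", "mid_area must be a positive number")
  R <- sqrt(mid_area / (4 * pi))
  u <- seq(0, 1, length.out = as.integer(n_nodes))
  axisym_shape(
    s = pi * R * u,
    psi = pi * u,
    r = R * sin(pi * u),
    z = R * (1 - cos(pi * u)),
    dpsi_ds = rep(1 / R, length(u)),
    closed = TRUE
  )
}

#' Discretized spheroid (surface of revolution of an ellipse)
#'
#' Builds a prolate (`a > b`) or oblate (`a < b`) spheroid profile with polar
#' semi-axis `a` along the symmetry axis and equatorial semi-axis `b`,
#' resampled to a uniform arclength grid with analytic tilt and curvature.
#'
#' @param a polar semi-axis (nm).
#' @param b equatorial semi-axis (nm).
#' @param n_nodes number of profile nodes.
#' @return A closed [axisym_shape()].
#' @export
make_spheroid <- function(a, b, n_nodes = 201L) {
  if (a <= 0 || b <= 0)
    .err("mitoshape_invalid_parameter", "semi-axes must be positive")
  n_nodes <- as.integer(n_nodes)
  # dense parametric sweep, then invert s(theta) onto a uniform grid
  theta_f <- seq(0, pi, length.out = 20L * n_nodes)
  g <- sqrt(b^2 * cos(theta_f)^2 + a^2 * sin(theta_f)^2)  # ds/dtheta
  s_f <- .cumtrapz(g, theta_f[2L] - theta_f[1L])
  s_u <- seq(0, s_f[length(s_f)], length.out = n_nodes)
  theta <- stats::spline(s_f, theta_f, xout = s_u, method = "hyman")$y
  theta[1L] <- 0
  theta[n_nodes] <- pi
  gg <- sqrt(b^2 * cos(theta)^2 + a^2 * sin(theta)^2)
  axisym_shape(
    s = s_u,
    psi = atan2(a * sin(theta), b * cos(theta)),
    r = b * sin(theta),
    z = a * (1 - cos(theta)),
    dpsi_ds = a * b / gg^3,
    closed = TRUE
  )
}

# ---- MembraneSystem ----

#' Outer/inner membrane areas induced by the mid-surface geometry
#'
#' For two membranes held parallel at distance `d` on either side of the
#' mid-surface, the outer and inner areas follow from the integrated total
#' curvature `M`:
#' `A_out = A + (d/2) M`, `A_in = A - (d/2) M`, so the area difference is
#' `dA = d M = d <J> A`. Valid only in the small-curvature regime
#' `|J| d < 1`.
#'
#' @param shape a closed [axisym_shape()] mid-surface.
#' @param d intermembrane distance (nm), `d >= 0`.
#' @return A list of class `membrane_system` with `mid_area`, `d`,
#'   `area_out`, `area_in`, `area_diff` and `dAoverA` (all areas nm^2).
#' @examples
#' sys <- membrane_areas(make_sphere(4 * pi * 250^2), d = 10)
#' sys$dAoverA  # 2 d / R = 0.08
#' @export
membrane_areas <- function(shape, d) {
  stopifnot(inherits(shape, "axisym_shape"))
  if (!is.numeric(d) || length(d) != 1L || d < 0)
    .err("mitoshape_invalid_parameter", "d must be a single non-negative number")
  g <- geometry_report(shape)
  J <- g$mean_curvature_profile
  bad <- which(abs(J) * d >= 1)
  if (length(bad) > 0L)
    .err("mitoshape_model_validity",
         sprintf("small-curvature regime violated: |J| d = %.3f >= 1 at node %d",
                 max(abs(J[bad])) * d, bad[which.max(abs(J[bad]))]),
         nodes = bad)
  A <- g$area
  M <- g$integrated_mean_curvature
  structure(
    list(
      mid_area = A,
      d = d,
      area_out = A + d / 2 * M,
      area_in = A - d / 2 * M,
      area_diff = d * M,
      dAoverA = d * M / A
    ),
    class = "membrane_system"
  )
}

#' @export
print.membrane_system <- function(x, ...) {
  cat(sprintf(
    "<membrane_system> A = %.4g nm^2, d = %.3g nm\n  A_out = %.6g, A_in = %.6g, dA = %.4g nm^2 (dA/A = %.4f)\n",
    x$mid_area, x$d, x$area_out, x$area_in, x$area_diff, x$dAoverA))
  invisible(x)
}
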