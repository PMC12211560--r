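# Constrained Helfrich bending-energy minimization.
#
# The mid-surface profile is parametrized on u in [0, 1] (normalized
# arclength) by the tilt angle
#   psi(u) = pi u + sum_k a_k sin(2 pi k u).
# This basis builds in the pole conditions psi(0) = 0, psi(1) = pi, up-down
# mirror symmetry psi(1 - u) = pi - psi(u), and (through the symmetry) exact
# closure of the radius integral. The bending energy
#   F = kappa * integral of J^2 dA
# (two membranes, each kappa/2 J^2 per unit area, evaluated with the
# mid-surface curvature) and the normalized area difference
#   dA/A = d M / A, M = integral of J dA
# are both invariant under uniform rescaling, so the only effective
# constraint is scale-invariant; the mid-surface area is then matched
# exactly by a final rescale. The constrained minimum is found by an
# augmented-Lagrangian scheme over the mode amplitudes a_k.

# ---- model / options ----

#' Bending-energy model parameters
#'
#' @param kappa bending modulus (arbitrary energy units; minimizing shapes
#'   do not depend on its value, energies scale linearly with it).
#' @param d intermembrane distance (nm).
#' @return A list of class `energy_model`. The spontaneous curvature is
#'   identically zero (symmetric leaflets).
#' @export
energy_model <- function(kappa = 1, d = 10) {
  if (kappa <= 0) .err("mitoshape_invalid_parameter", "kappa must be positive")
  if (d <= 0) .err("mitoshape_invalid_parameter", "d must be positive")
  structure(list(kappa = kappa, d = d, spontaneous_curvature = 0),
            class = "energy_model")
}

#' Solver options
#'
#' @param n_nodes quadrature nodes along the half-meridian (odd; default 201).
#' @param n_modes number of sine modes parametrizing the tilt angle.
#' @param step continuation step in dA/A (default 0.01), halved automatically
#'   on failure.
#' @param tol relative tolerance on the area-difference constraint residual.
#' @param max_outer maximum augmented-Lagrangian multiplier updates.
#' @param max_inner maximum BFGS iterations per inner solve.
#' @param perturb_amplitude initial symmetry-breaking perturbation of the
#'   profile, as a fraction of the sphere radius.
#' @param seed seed for the initial perturbation.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(n_nodes = 201L, n_modes = 16L, step = 0.01,
                           tol = 1e-4, max_outer = 40L, max_inner = 400L,
                           perturb_amplitude = 1e-3, seed = 0L) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  structure(list(n_nodes = n_nodes, n_modes = as.integer(n_modes),
                 step = step, tol = tol, max_outer = as.integer(max_outer),
                 max_inner = as.integer(max_inner),
                 perturb_amplitude = perturb_amplitude, seed = seed),
            class = "solver_options")
}

# precomputed basis matrices on the uniform u grid
.spectral_grid <- function(n_nodes, n_modes) {
  u <- seq(0, 1, length.out = n_nodes)
  k <- seq_len(n_modes)
  S <- sin(outer(u, 2 * pi * k))            # psi modes
  C <- t(2 * pi * k * t(cos(outer(u, 2 * pi * k))))  # d psi / du modes
  list(u = u, h = u[2L] - u[1L], S = S, C = C,
       n_nodes = n_nodes, n_modes = n_modes)
}

# raw (unit total arclength) geometry of the spectral shape; d_int is the
# intermembrane distance in units of the sphere radius R0
.shape_eval <- function(a, grid, d_int) {
  psi <- pi * grid$u + drop(grid$S %*% a)
  dpsi <- pi + drop(grid$C %*% a)
  cpsi <- cos(psi)
  spsi <- sin(psi)
  r <- .cumtrapz(cpsi, grid$h, fp = -spsi * dpsi)
  n <- grid$n_nodes
  r[1L] <- 0
  r[n] <- 0
  rin <- r[2:(n - 1L)]
  if (any(rin <= 0)) {
    return(list(valid = FALSE, violation = -min(rin) / max(abs(r)) + 1e-3))
  }
  J <- numeric(n)
  J[2:(n - 1L)] <- dpsi[2:(n - 1L)] + spsi[2:(n - 1L)] / rin
  J[c(1L, n)] <- 2 * dpsi[c(1L, n)]
  ring <- 2 * pi * r
  A <- .simpson(ring, grid$h)
  M <- .simpson(ring * J, grid$h)
  E2 <- .simpson(ring * J^2, grid$h)
  V <- .simpson(pi * r^2 * spsi, grid$h)
  list(valid = TRUE, psi = psi, dpsi = dpsi, r = r, J = J,
       A = A, M = M, E = E2, V = V,
       # scale-invariant dA/A achieved after rescaling the area
       c = d_int * M / sqrt(4 * pi * A),
       sphericity = 36 * pi * V^2 / A^3)
}

# augmented-Lagrangian solve of min E(a) s.t. c(a) = target
.al_solve <- function(a0, target, grid, d_int, lambda = 0, mu = 1e6,
                      tol = 1e-4, max_outer = 40L, max_inner = 400L) {
  K <- length(a0)
  phi <- function(a, lam, mu) {
    ev <- .shape_eval(a, grid, d_int)
    if (!ev$valid) return(1e8 * (1 + ev$violation))
    g <- (ev$c - target) / target
    ev$E + lam * g + mu / 2 * g^2
  }
  grad <- function(a, lam, mu) {
    g <- numeric(K)
    for (j in seq_len(K)) {
      hj <- 1e-6 * max(1, abs(a[j]))
      ap <- a; ap[j] <- a[j] + hj
      am <- a; am[j] <- a[j] - hj
      g[j] <- (phi(ap, lam, mu) - phi(am, lam, mu)) / (2 * hj)
    }
    g
  }
  a <- a0
  g_prev <- Inf
  total_iter <- 0L
  best <- NULL  # lowest-energy iterate satisfying the constraint tolerance
  for (outer in seq_len(max_outer)) {
    fit <- stats::optim(a, fn = phi, gr = grad, lam = lambda, mu = mu,
                        method = "BFGS",
                        control = list(maxit = max_inner, reltol = 1e-13))
    a <- fit$par
    total_iter <- total_iter + fit$counts[["function"]]
    ev <- .shape_eval(a, grid, d_int)
    if (!ev$valid) break
    g <- (ev$c - target) / target
    if (abs(g) < tol && (is.null(best) || ev$E < best$eval$E))
      best <- list(a = a, lambda = lambda, eval = ev, g = g)
    if (abs(g) < tol && outer > 1L) break
    lambda <- lambda + mu * g
    if (abs(g) > 0.25 * abs(g_prev)) mu <- min(mu * 5, 1e9)
    g_prev <- g
  }
  if (is.null(best)) {
    ev <- .shape_eval(a, grid, d_int)
    return(list(a = a, lambda = lambda, mu = mu,
                residual = if (ev$valid) abs(ev$c - target) / target else NA_real_,
                eval = ev, converged = FALSE, iterations = total_iter))
  }
  list(a = best$a, lambda = best$lambda, mu = mu,
       residual = abs(best$g), eval = best$eval, converged = TRUE,
       iterations = total_iter)
}

# seeded symmetry-breaking perturbation of the mode amplitudes
.initial_perturbation <- function(n_modes, amplitude, seed) {
  withr::with_seed(seed, {
    amplitude * stats::rnorm(n_modes) / seq_len(n_modes)^2
  })
}

# least-squares projection of a tilt profile psi(u) onto the sine basis
.coeffs_from_psi <- function(psi, grid) {
  f <- psi - pi * grid$u
  qr.solve(grid$S, f)
}

# mode amplitudes of the prolate spheroid whose scale-invariant area
# difference matches the target; used to seed the minimizer on the
# physically relevant branch
.spheroid_init <- function(target, d_int, grid) {
  t_sphere <- 2 * d_int
  theta <- seq(0, pi, length.out = 2001L)
  h <- theta[2L] - theta[1L]
  st <- sin(theta)
  ct <- cos(theta)
  eval_q <- function(q) {
    g <- sqrt(ct^2 + q^2 * st^2)
    J <- q / g^3 + q / g
    ring <- 2 * pi * st * g
    A <- .simpson(ring, h)
    list(c = d_int * .simpson(ring * J, h) / sqrt(4 * pi * A),
         E = .simpson(ring * J^2, h))
  }
  q <- if (target <= t_sphere * (1 + 1e-9)) 1 else {
    f <- function(q) eval_q(q)$c - target
    if (f(80) < 0) 80 else stats::uniroot(f, c(1, 80), tol = 1e-9)$root
  }
  # shadow price of the constraint, estimated along the spheroid branch:
  # lambda ~ -t dE/dc keeps the augmented Lagrangian stationary there
  e1 <- eval_q(q * 1.002 + 1e-3)
  e0 <- eval_q(max(1, q * 0.998 - 1e-3))
  lambda <- if (e1$c > e0$c) -target * (e1$E - e0$E) / (e1$c - e0$c) else 0
  # spheroid tilt angle on a uniform arclength grid
  g <- sqrt(ct^2 + q^2 * st^2)
  s_f <- .cumtrapz(g, h)
  th_u <- stats::spline(s_f / s_f[length(s_f)], theta,
                        xout = grid$u, method = "hyman")$y
  psi <- atan2(q * sin(th_u), cos(th_u))
  list(a = .coeffs_from_psi(psi, grid), lambda = lambda)
}

# package a converged iterate as a shape_solution in physical units
.make_solution <- function(state, mid_area, target, model, options, grid) {
  ev <- state$eval
  R0 <- sqrt(mid_area / (4 * pi))
  L <- R0 * sqrt(4 * pi / ev$A)  # physical total arclength
  shape <- axisym_shape(
    s = L * grid$u,
    psi = ev$psi,
    r = L * ev$r,
    z = L * (ev$r * 0 + cumsum(c(0, (sin(ev$psi)[-grid$n_nodes] +
                                       sin(ev$psi)[-1L]) / 2 * grid$h))),
    dpsi_ds = ev$dpsi / L,
    closed = TRUE
  )
  sol <- structure(
    list(
      shape = shape,
      target_dAoverA = target,
      achieved_dAoverA = ev$c,
      energy = model$kappa * ev$E,
      sphericity = ev$sphericity,
      constraint_residuals = c(area = 0, dAoverA = state$residual),
      solver_diagnostics = list(
        iterations = state$iterations,
        converged = state$converged,
        lambda = state$lambda,
        coefficients = state$a,
        n_nodes = options$n_nodes,
        n_modes = options$n_modes,
        seed = options$seed
      )
    ),
    class = "shape_solution"
  )
  sol$shape_class <- classify_shape(sol)
  sol
}

#' @export
print.shape_solution <- function(x, ...) {
  cat(sprintf(
    "<shape_solution> dA/A target %.4f achieved %.4f | F = %.4f kappa | sphericity %.4f | %s\n",
    x$target_dAoverA, x$achieved_dAoverA, x$energy, x$sphericity,
    x$shape_class))
  invisible(x)
}

# ---- public operations ----

#' Bending energy of a closed shape
#'
#' Total Helfrich bending energy of the two coupled membranes evaluated with
#' the mid-surface curvature: `F = kappa * integral of J^2 dA` (each membrane
#' contributes `kappa/2 J^2` per unit area; deviations of the individual
#' membrane curvatures from J are second order and neglected). For any
#' sphere this equals `16 pi kappa`, the Willmore lower bound over all
#' closed shapes.
#'
#' @param shape a closed [axisym_shape()].
#' @param model an [energy_model()].
#' @return Energy in units of kappa (times `model$kappa`).
#' @export
bending_energy <- function(shape, model = energy_model()) {
  g <- geometry_report(shape)
  model$kappa * g$j_squared_integral
}

#' Minimize the coupled-membrane bending energy at fixed area difference
#'
#' Finds the axisymmetric shape minimizing the bending energy subject to a
#' fixed mid-surface area and a fixed normalized area difference
#' `dA/A = d M / A`. Targets below the sphere's own value `2 d / R0` belong
#' to the oblate branch and are rejected. The enclosed volume is left
#' unconstrained. Starting from a slightly perturbed sphere, the target is
#' approached by continuation in small `dA/A` steps.
#'
#' @param mid_area mid-surface area (nm^2).
#' @param target_dAoverA target normalized area difference.
#' @param model an [energy_model()] (supplies `d` and `kappa`).
#' @param options a [solver_options()].
#' @return A `shape_solution`: the minimizing shape plus achieved
#'   constraints, energy (units of kappa), sphericity, morphological class
#'   and solver diagnostics.
#' @examples
#' \donttest{
#' sol <- minimize_shape(4 * pi * 250^2, 0.12, energy_model(d = 10))
#' sol$sphericity  # < 1: elongated
#' }
#' @export
minimize_shape <- function(mid_area, target_dAoverA,
                           model = energy_model(),
                           options = solver_options()) {
  cont <- .continuation(mid_area, c(target_dAoverA), model, options)
  cont$solutions[[length(cont$solutions)]]
}

# shared continuation engine; returns solutions at each requested target
.continuation <- function(mid_area, targets, model, options) {
  if (mid_area <= 0)
    .err("mitoshape_invalid_parameter", "mid_area must be positive")
  R0 <- sqrt(mid_area / (4 * pi))
  d_int <- model$d / R0
  t_sphere <- 2 * d_int
  if (any(diff(targets) <= 0))
    .err("mitoshape_invalid_parameter", "targets must be strictly increasing")
  if (targets[1L] < t_sphere * (1 - 1e-9))
    .err("mitoshape_branch_out_of_scope",
         sprintf("target dA/A = %.4f is below the sphere value 2d/R0 = %.4f (oblate branch, out of scope)",
                 targets[1L], t_sphere))
  grid <- .spectral_grid(options$n_nodes, options$n_modes)
  perturb <- .initial_perturbation(options$n_modes,
                                   options$perturb_amplitude, options$seed)
  # solve one target from warm start and from the matched-spheroid trial,
  # keeping the lower-energy converged candidate (branch tracking guard)
  solve_at <- function(t, warm) {
    cand <- list()
    st_w <- .al_solve(warm$a, t, grid, d_int, lambda = warm$lambda,
                      tol = options$tol, max_outer = options$max_outer,
                      max_inner = options$max_inner)
    if (st_w$converged) cand <- c(cand, list(st_w))
    sph_init <- .spheroid_init(t, d_int, grid)
    st_s <- .al_solve(sph_init$a + perturb, t, grid, d_int,
                      lambda = sph_init$lambda,
                      tol = options$tol, max_outer = options$max_outer,
                      max_inner = options$max_inner)
    if (st_s$converged) cand <- c(cand, list(st_s))
    if (length(cand) == 0L) return(st_w)
    cand[[which.min(vapply(cand, function(s) s$eval$E, 0))]]
  }
  warm <- list(a = perturb, lambda = 0)
  t_now <- t_sphere
  solutions <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    t_goal <- targets[i]
    step <- options$step
    while (t_now < t_goal * (1 - 1e-12)) {
      t_next <- min(t_now + step, t_goal)
      st <- solve_at(t_next, warm)
      if (st$converged) {
        warm <- list(a = st$a, lambda = st$lambda)
        t_now <- t_next
      } else {
        step <- step / 2
        if (step < 1e-4)
          .err("mitoshape_nonconvergence",
               sprintf("continuation stalled at dA/A = %.4f (goal %.4f)",
                       t_now, t_goal),
               last_iterate = st,
               partial = solutions[seq_len(i - 1L)])
      }
    }
    # targets at (or numerically equal to) the sphere value: solve in place
    st <- solve_at(t_goal, warm)
    if (!st$converged)
      .err("mitoshape_nonconvergence",
           sprintf("failed to converge at dA/A = %.4f", t_goal),
           last_iterate = st, partial = solutions[seq_len(i - 1L)])
    warm <- list(a = st$a, lambda = st$lambda)
    solutions[[i]] <- .make_solution(st, mid_area, t_goal, model, options,
                                     grid)
  }
  list(solutions = solutions, coefficients = warm$a)
}

#' Continuation family of minimizing shapes over increasing area difference
#'
#' Solves [minimize_shape()] along an increasing sequence of `dA/A` targets,
#' each minimization warm-started from the previous solution (the first from
#' a slightly perturbed sphere). As the area difference grows the sphericity
#' decreases: the sphere elongates into prolate-like shapes and then into
#' peanut shapes with a constricted middle.
#'
#' @param mid_area mid-surface area (nm^2).
#' @param d intermembrane distance (nm).
#' @param targets strictly increasing `dA/A` values, the first at or above
#'   the sphere value `2 d / R0`.
#' @param model an [energy_model()]; its `d` is overridden by `d`.
#' @param options a [solver_options()].
#' @return A list of `shape_solution` objects (class `shape_family`).
#' @export
shape_family <- function(mid_area, d, targets,
                         model = energy_model(d = d),
                         options = solver_options()) {
  model$d <- d
  cont <- .continuation(mid_area, targets, model, options)
  structure(cont$solutions, class = "shape_family")
}

#' Summary table of a shape family
#'
#' @param family a `shape_family` (list of `shape_solution`).
#' @return data.frame with one row per target: target and achieved `dA/A`,
#'   energy (kappa units), sphericity, class, convergence diagnostics.
#' @export
family_summary <- function(family) {
  do.call(rbind, lapply(family, function(s) {
    data.frame(
      target_dAoverA = s$target_dAoverA,
      achieved_dAoverA = s$achieved_dAoverA,
      energy = s$energy,
      sphericity = s$sphericity,
      shape_class = s$shape_class,
      residual = s$constraint_residuals[["dAoverA"]],
      converged = s$solver_diagnostics$converged
    )
  }))
}

#' Morphological class of a minimized shape
#'
#' Classifies a solution as `sphere` (sphericity >= 0.999), `peanut` (the
#' radius profile has an interior local minimum — a neck — whose depth is at
#' least 2% of the maximal radius), or `elongated` otherwise.
#'
#' @param solution a `shape_solution` or a closed [axisym_shape()].
#' @return One of `"sphere"`, `"elongated"`, `"peanut"`.
#' @export
classify_shape <- function(solution) {
  if (inherits(solution, "shape_solution")) {
    shape <- solution$shape
    sph <- solution$sphericity
  } else if (inherits(solution, "axisym_shape")) {
    shape <- solution
    sph <- geometry_report(shape)$sphericity_3d
  } else {
    .err("mitoshape_invalid_parameter",
         "expected a shape_solution or axisym_shape")
  }
  if (sph >= 0.999) return("sphere")
  if (.has_neck(shape$r)) "peanut" else "elongated"
}

# interior local minimum of the radius profile with depth >= 2% of max(r)
.has_neck <- function(r, depth_frac = 0.02) {
  n <- length(r)
  if (n < 5L) return(FALSE)
  rmax <- max(r)
  interior <- 2:(n - 1L)
  is_min <- r[interior] <= r[interior - 1L] & r[interior] <= r[interior + 1L] &
    (r[interior] < r[interior - 1L] | r[interior] < r[interior + 1L])
  idx <- interior[is_min]
  idx <- idx[r[idx] > 0]  # poles excluded
  for (i in idx) {
    left_max <- max(r[1:i])
    right_max <- max(r[i:n])
    if (min(left_max, right_max) - r[i] >= depth_frac * rmax) return(TRUE)
  }
  FALSE
}

#' Prolate-spheroid trial energy: a rigorous upper bound
#'
#' Scans the one-parameter prolate-spheroid family (rescaled to the given
#' mid-surface area) for the member whose normalized area difference matches
#' the target, and returns its bending energy. Because spheroids are
#' admissible trial shapes for the constrained minimization, this value is a
#' rigorous upper bound for the constrained minimum; it serves as an
#' independent check on the minimizer.
#'
#' All spheroid quantities are evaluated by dense quadrature of the
#' closed-form parametric curvatures of an ellipse of revolution,
#' independently of the solver's profile machinery.
#'
#' @param mid_area mid-surface area (nm^2).
#' @param target_dAoverA target normalized area difference.
#' @param d intermembrane distance (nm).
#' @param max_aspect largest aspect ratio scanned (default 50).
#' @param n_theta quadrature points for the parametric integrals.
#' @return Bending energy of the matched spheroid, in units of kappa.
#' @export
trial_prolate_oracle <- function(mid_area, target_dAoverA, d,
                                 max_aspect = 50, n_theta = 4001L) {
  R0 <- sqrt(mid_area / (4 * pi))
  t_sphere <- 2 * d / R0
  if (target_dAoverA < t_sphere * (1 - 1e-9))
    .err("mitoshape_branch_out_of_scope",
         "target below the sphere value: oblate branch, out of scope")
  theta <- seq(0, pi, length.out = as.integer(n_theta))
  h <- theta[2L] - theta[1L]
  st <- sin(theta)
  ct <- cos(theta)
  # scale-invariant quantities of the spheroid with b = 1, a = q
  spheroid <- function(q) {
    g <- sqrt(ct^2 + q^2 * st^2)   # |d gamma / d theta|, b = 1
    k_mer <- q / g^3               # meridian principal curvature
    k_par <- q / g                 # parallel principal curvature (r = sin)
    J <- k_mer + k_par
    ring <- 2 * pi * st * g        # r * ds
    A <- .simpson(ring, h)
    M <- .simpson(ring * J, h)
    E <- .simpson(ring * J^2, h)
    list(A = A, M = M, E = E, c = (d / R0) * M / sqrt(4 * pi * A))
  }
  f <- function(q) spheroid(q)$c - target_dAoverA
  if (abs(f(1)) < 1e-12 || target_dAoverA <= t_sphere * (1 + 1e-9))
    return(spheroid(1)$E)
  if (f(max_aspect) < 0)
    .err("mitoshape_unreachable",
         sprintf("target dA/A = %.4f unreachable within aspect ratio %.0f",
                 target_dAoverA, max_aspect))
  q <- stats::uniroot(f, c(1, max_aspect), tol = 1e-10)$root
  sp <- spheroid(q)
  if (abs(sp$c - target_dAoverA) / target_dAoverA > 1e-4)
    .err("mitoshape_unreachable", "spheroid constraint match failed")
  sp$E
}
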