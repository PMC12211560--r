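# Synthetic tracings emulating manual tracings of PKMO-stained live-cell
# STED images: stadium-shaped outlines (2D silhouette of a spherocylinder)
# with transverse crista segments, cohorts with a tunable coupling between
# cristae fraction and circularity, and time series of cristae retraction
# with conserved total 2D IMM length.

# closed-form stadium descriptors (straight length L, cap radius R)
.stadium_closed_form <- function(L, R) {
  area <- 2 * R * L + pi * R^2
  per <- 2 * L + 2 * pi * R
  list(area = area, perimeter = per, circularity = 4 * pi * area / per^2)
}

# smooth random radial perturbation profile over the closed boundary
# parameter t in [0, 1); low-order Fourier modes so the outline stays simple
.jitter_profile <- function(t, n_modes = 6L) {
  k <- 2:(n_modes + 1L)
  bc <- stats::rnorm(2L * length(k)) / rep(k, 2L)
  f <- drop(cos(outer(2 * pi * t, k)) %*% bc[seq_along(k)] +
              sin(outer(2 * pi * t, k)) %*% bc[-seq_along(k)])
  f / max(stats::sd(f), 1e-12)
}

#' Generate a stadium-shaped synthetic tracing
#'
#' The outline is a discretized stadium (rectangle of length `axis_length`
#' capped by two semicircles of radius `radius`), optionally perturbed along
#' the outward normal by smooth random jitter. Cristae are transverse
#' segments evenly spaced along the straight section. `axis_length = 0`
#' gives a circle. Deterministic for a given `seed`.
#'
#' @param axis_length length of the straight section (nm), `>= 0`.
#' @param radius cap radius (nm), half the width.
#' @param n_cristae number of transverse cristae (requires spacing
#'   `axis_length / (n_cristae + 1) >= 40` nm, a typical crista spacing
#'   floor).
#' @param crista_span crista length as a fraction of the local width, used
#'   when `crista_lengths` is not given.
#' @param jitter outline jitter amplitude as a fraction of `radius`.
#' @param seed integer seed (jitter only); `NULL` uses the current RNG state.
#' @param crista_lengths optional explicit crista lengths (nm), overriding
#'   `crista_span`.
#' @param n_outline approximate number of outline vertices.
#' @param enforce_spacing enforce the 40 nm crista spacing floor (disabled
#'   by the retraction time-series generator, where shrinking geometry keeps
#'   its crista count).
#' @param ... passed to [mito_trace()] (`id`, `timestamp`, `group_label`, ...).
#' @return A [mito_trace()].
#' @examples
#' tr <- generate_stadium_trace(500, 125, n_cristae = 3)
#' circularity_2d(tr$outline)$circularity  # ~ 0.686
#' @export
generate_stadium_trace <- function(axis_length, radius, n_cristae = 0L,
                                   crista_span = 0.8, jitter = 0,
                                   seed = NULL, crista_lengths = NULL,
                                   n_outline = 96L, enforce_spacing = TRUE,
                                   ...) {
  if (axis_length < 0)
    .err("mitoshape_invalid_parameter", "axis_length must be >= 0")
  if (radius <= 0)
    .err("mitoshape_invalid_parameter", "radius must be positive")
  n_cristae <- as.integer(n_cristae)
  if (n_cristae > 0L && enforce_spacing) {
    spacing <- axis_length / (n_cristae + 1L)
    if (spacing < 40)
      .err("mitoshape_capacity",
           sprintf("%d cristae on a %.0f nm axis: spacing %.1f nm < 40 nm floor",
                   n_cristae, axis_length, spacing))
  }
  L <- axis_length
  R <- radius
  per <- 2 * L + 2 * pi * R
  n_outline <- max(24L, as.integer(n_outline))
  # boundary samples at (approximately) even arclength, t in [0, 1)
  t <- (seq_len(n_outline) - 1L) / n_outline
  s <- t * per
  pt <- matrix(0, n_outline, 2L)
  nrm <- matrix(0, n_outline, 2L)
  for (i in seq_len(n_outline)) {
    si <- s[i]
    if (si < pi * R) {                       # right cap, from bottom to top
      phi <- si / R - pi / 2
      pt[i, ] <- c(L / 2 + R * cos(phi), R * sin(phi))
      nrm[i, ] <- c(cos(phi), sin(phi))
    } else if (si < pi * R + L) {            # top edge, right to left
      pt[i, ] <- c(L / 2 - (si - pi * R), R)
      nrm[i, ] <- c(0, 1)
    } else if (si < 2 * pi * R + L) {        # left cap
      phi <- pi / 2 + (si - pi * R - L) / R
      pt[i, ] <- c(-L / 2 + R * cos(phi), R * sin(phi))
      nrm[i, ] <- c(cos(phi), sin(phi))
    } else {                                 # bottom edge, left to right
      pt[i, ] <- c(-L / 2 + (si - 2 * pi * R - L), -R)
      nrm[i, ] <- c(0, -1)
    }
  }
  if (jitter > 0) {
    gen <- function() pt + nrm * (jitter * R * .jitter_profile(t))
    pt <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  }
  if (is.null(crista_lengths) && n_cristae > 0L)
    crista_lengths <- rep(crista_span * 2 * R, n_cristae)
  cristae <- list()
  if (n_cristae > 0L) {
    xs <- -L / 2 + seq_len(n_cristae) * L / (n_cristae + 1L)
    cristae <- lapply(seq_len(n_cristae), function(j) {
      l <- crista_lengths[j]
      cbind(c(xs[j], xs[j]), c(-l / 2, l / 2))
    })
  }
  mito_trace(pt, cristae, check_simple = nrow(pt) <= 2000L, ...)
}

#' Specification of a synthetic cohort
#'
#' @param n number of mitochondria (>= 3).
#' @param axis_length_range log-uniform sampling range for the straight
#'   section length (nm).
#' @param radius_range uniform sampling range for the cap radius (nm).
#' @param coupling_r target Pearson correlation between the 2D cristae
#'   fraction and circularity (negative for paper-like cohorts).
#' @param noise_sd multiplicative noise on realized crista lengths
#'   (fraction of value).
#' @param outline_jitter outline jitter as a fraction of the radius.
#' @param fraction_mean,fraction_sd population mean / sd of the targeted
#'   cristae fraction (percent).
#' @param crista_span maximal crista length as a fraction of local width.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100L, axis_length_range = c(120, 2500),
                        radius_range = c(125, 250), coupling_r = -0.6,
                        noise_sd = 0.05, outline_jitter = 0.02,
                        fraction_mean = 30, fraction_sd = 8,
                        crista_span = 0.8, seed = 1L) {
  n <- as.integer(n)
  if (n < 3L) .err("mitoshape_invalid_parameter", "cohort needs n >= 3")
  if (abs(coupling_r) > 1)
    .err("mitoshape_invalid_parameter", "|coupling_r| must be <= 1")
  if (any(axis_length_range <= 0) || diff(axis_length_range) < 0)
    .err("mitoshape_invalid_parameter", "bad axis_length_range")
  if (any(radius_range <= 0) || diff(radius_range) < 0)
    .err("mitoshape_invalid_parameter", "bad radius_range")
  structure(list(n = n, axis_length_range = axis_length_range,
                 radius_range = radius_range, coupling_r = coupling_r,
                 noise_sd = noise_sd, outline_jitter = outline_jitter,
                 fraction_mean = fraction_mean, fraction_sd = fraction_sd,
                 crista_span = crista_span, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of tracings
#'
#' Elongations are sampled log-uniformly, radii uniformly. The targeted
#' cristae fraction of each mitochondrion is constructed as a linear
#' function of the standardized (closed-form) circularity plus independent
#' Gaussian scatter, with weights chosen so that the population correlation
#' between cristae fraction and circularity equals `coupling_r` before
#' measurement noise. Cristae are then realized as transverse segments whose
#' total length produces the targeted fraction, subject to the geometric
#' capacity of the outline (per-crista length cap and the 40 nm spacing
#' floor); when capacity truncates the target, the achieved fraction is
#' recorded in the truth table.
#'
#' @param spec a [cohort_spec()].
#' @return list with `traces` (list of [mito_trace()]) and `truth`
#'   (data.frame of per-trace generative parameters, including the achieved
#'   pre-noise correlation as attribute `achieved_r`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(spec) {
  n <- spec$n
  L <- exp(stats::runif(n, log(spec$axis_length_range[1L]),
                        log(spec$axis_length_range[2L])))
  R <- stats::runif(n, spec$radius_range[1L], spec$radius_range[2L])
  # realize the (possibly jittered) outlines first and couple the cristae
  # target to the realized circularity and perimeter, so that outline noise
  # cannot leak into the fraction-circularity correlation
  outlines <- lapply(seq_len(n), function(i)
    generate_stadium_trace(L[i], R[i], n_cristae = 0L,
                           jitter = spec$outline_jitter,
                           id = sprintf("synth_%03d", i)))
  geom <- lapply(outlines, function(tr) circularity_2d(tr$outline))
  circ <- vapply(geom, `[[`, 0, "circularity")
  P <- vapply(geom, `[[`, 0, "perimeter")
  zc <- (circ - mean(circ)) / max(stats::sd(circ), 1e-12)
  rho <- spec$coupling_r
  Ftarget <- spec$fraction_mean + spec$fraction_sd *
    (rho * zc + sqrt(1 - rho^2) * stats::rnorm(n))
  Ftarget <- pmin(pmax(Ftarget, 0.5), 70)
  total <- P * Ftarget / (2 * (100 - Ftarget))
  lmax <- spec$crista_span * 2 * R
  m_needed <- pmax(1L, ceiling(total / lmax))
  m_cap <- pmax(0L, floor(L / 40) - 1L)
  m <- pmin(m_needed, m_cap)
  capped <- m < m_needed | m_cap < 1L
  total_real <- ifelse(m >= 1L, pmin(total, m * lmax), 0)
  m <- pmax(m, 0L)
  Freal <- 100 * 2 * total_real / (P + 2 * total_real)
  achieved_r <- suppressWarnings(stats::cor(Freal, circ))
  if (any(capped))
    .warn("mitoshape_coupling_truncated",
          sprintf("capacity truncated the cristae target in %d of %d traces; achieved pre-noise r = %.3f",
                  sum(capped), n, achieved_r))
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    lens <- if (m[i] >= 1L) rep(total_real[i] / m[i], m[i]) else numeric(0)
    if (spec$noise_sd > 0 && length(lens) > 0L) {
      lens <- lens * pmax(0.1, 1 + spec$noise_sd * stats::rnorm(length(lens)))
      lens <- pmin(lens, lmax[i])
    }
    cristae <- list()
    if (length(lens) > 0L) {
      xs <- -L[i] / 2 + seq_along(lens) * L[i] / (length(lens) + 1L)
      cristae <- lapply(seq_along(lens), function(j)
        cbind(c(xs[j], xs[j]), c(-lens[j] / 2, lens[j] / 2)))
    }
    traces[[i]] <- mito_trace(outlines[[i]]$outline, cristae,
                              id = outlines[[i]]$id,
                              check_simple = FALSE)
  }
  truth <- data.frame(
    id = vapply(traces, function(tr) tr$id, ""),
    axis_length = L, radius = R, circularity_realized = circ,
    perimeter_realized = P,
    target_fraction = Ftarget, realized_fraction = Freal,
    n_cristae = m, total_crista_length = total_real,
    capped = capped, stringsAsFactors = FALSE
  )
  attr(truth, "achieved_r") <- achieved_r
  list(traces = traces, truth = truth)
}

#' Generate a cristae-retraction time series
#'
#' Frames morph from a stadium towards a circle as cristae retract into the
#' boundary membrane. With `conserve_imm_length = TRUE` the total 2D IMM
#' length `P + 2 sum(l)` is held constant across frames (no lipid gain or
#' loss): retracting cristae lengthen the boundary, so the outline's straight
#' section shrinks with the retraction schedule while the cap radius grows
#' to absorb the returned membrane. Full retraction yields a circle.
#'
#' @param retraction_schedule non-increasing fractions in `[0, 1]` of the
#'   initial crista extent, one per frame (1 = initial, 0 = fully
#'   retracted).
#' @param axis_length,radius initial stadium geometry (nm).
#' @param n_cristae,crista_span initial cristae layout.
#' @param conserve_imm_length conserve `P + 2 sum(l)` across frames.
#' @param dt frame interval (seconds).
#' @param jitter,seed outline jitter (applied per frame, seeded).
#' @return list of [mito_trace()] with timestamps attached.
#' @export
generate_timeseries <- function(retraction_schedule,
                                axis_length = 500, radius = 125,
                                n_cristae = 5L, crista_span = 0.8,
                                conserve_imm_length = TRUE,
                                dt = 15, jitter = 0, seed = NULL) {
  sched <- retraction_schedule
  if (any(sched < 0 | sched > 1))
    .err("mitoshape_invalid_parameter", "schedule fractions must be in [0, 1]")
  if (any(diff(sched) > 1e-12))
    .err("mitoshape_invalid_parameter",
         "retraction schedule must be non-increasing")
  L0 <- axis_length
  R0 <- radius
  l0 <- rep(crista_span * 2 * R0, n_cristae)
  P0 <- 2 * L0 + 2 * pi * R0
  T0 <- P0 + 2 * sum(l0)
  frames <- vector("list", length(sched))
  for (k in seq_along(sched)) {
    fk <- sched[k]
    lens <- l0 * fk
    lens <- lens[lens > 0]
    if (conserve_imm_length) {
      Pk <- T0 - 2 * sum(lens)
      Lk <- L0 * fk
      Rk <- (Pk - 2 * Lk) / (2 * pi)
    } else {
      Lk <- L0
      Rk <- R0
    }
    frames[[k]] <- generate_stadium_trace(
      Lk, Rk, n_cristae = length(lens), crista_lengths = lens,
      jitter = jitter, seed = if (is.null(seed)) NULL else seed + k,
      enforce_spacing = FALSE,
      id = sprintf("frame_%02d", k), timestamp = (k - 1L) * dt
    )
  }
  frames
}

#' Generate a two-group cohort (control vs perturbed)
#'
#' Emulates a knockdown of cristae-shaping proteins: the perturbed group's
#' elongation distribution is shifted towards shorter axis lengths (hence
#' higher circularity). By default the perturbed spec is derived from the
#' control by scaling the axis-length range.
#'
#' @param control a [cohort_spec()] for the control group.
#' @param perturbed a [cohort_spec()] for the perturbed group; if `NULL`,
#'   derived from `control` with axis lengths scaled by `axis_scale`.
#' @param axis_scale factor applied to the control axis-length range when
#'   deriving the perturbed spec (default 0.5).
#' @param labels group labels.
#' @return list with `traces` (labelled), `truth` (with `group` column).
#' @export
generate_two_group_cohort <- function(control, perturbed = NULL,
                                      axis_scale = 0.5,
                                      labels = c("control", "perturbed")) {
  stopifnot(inherits(control, "cohort_spec"))
  if (is.null(perturbed)) {
    perturbed <- control
    perturbed$axis_length_range <- pmax(control$axis_length_range * axis_scale,
                                        81)
    perturbed$seed <- control$seed + 1L
  }
  stopifnot(inherits(perturbed, "cohort_spec"))
  if (control$n < 1L || perturbed$n < 1L)
    .err("mitoshape_invalid_parameter", "both groups need n >= 1")
  gc1 <- generate_cohort(control)
  gc2 <- generate_cohort(perturbed)
  tag <- function(gc, lab) {
    gc$traces <- lapply(gc$traces, function(tr) {
      tr$group_label <- lab
      tr$id <- paste0(lab, "_", tr$id)
      tr
    })
    gc$truth$group <- lab
    gc$truth$id <- paste0(lab, "_", gc$truth$id)
    gc
  }
  gc1 <- tag(gc1, labels[1L])
  gc2 <- tag(gc2, labels[2L])
  list(traces = c(gc1$traces, gc2$traces),
       truth = rbind(gc1$truth, gc2$truth))
}

# ---- rasterization (optional robustness fixture) ----

.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-rad:rad, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {
    # convolve each column with k, replicating edges
    top <- m[rep(1L, rad), , drop = FALSE]
    bot <- m[rep(nrow(m), rad), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Rasterize a tracing into a synthetic STED-like image
#'
#' Renders the outline and crista polylines as intensity ridges on a pixel
#' grid, applies Gaussian blur of width `psf_sigma`, and (optionally) Poisson
#' photon noise. The ground-truth trace is retained alongside the image.
#'
#' @param trace a [mito_trace()].
#' @param pixel_size pixel size in nm (STED-typical: 25).
#' @param psf_sigma Gaussian PSF sigma in nm (0 = none).
#' @param noise_level peak photon count for Poisson noise (0 = noiseless).
#' @param seed seed for the noise.
#' @param margin extra margin around the bounding box (nm).
#' @return list of class `mito_raster`: `image` (matrix, rows = y),
#'   `pixel_size`, `origin` (nm coordinates of pixel [1,1] center), `trace`.
#' @export
rasterize_trace <- function(trace, pixel_size = 25, psf_sigma = 0,
                            noise_level = 0, seed = NULL, margin = NULL) {
  stopifnot(inherits(trace, "mito_trace"))
  if (pixel_size <= 0)
    .err("mitoshape_invalid_parameter", "pixel_size must be positive")
  if (is.null(margin)) margin <- 3 * psf_sigma + 2 * pixel_size
  all_pts <- rbind(trace$outline, do.call(rbind, c(trace$cristae,
                                                   list(NULL))))
  xr <- range(all_pts[, 1L]) + c(-margin, margin)
  yr <- range(all_pts[, 2L]) + c(-margin, margin)
  nx <- ceiling(diff(xr) / pixel_size)
  ny <- ceiling(diff(yr) / pixel_size)
  # dense samples along all membrane polylines, splatted with bilinear
  # (anti-aliased) weights so ridge centroids sit on the true curves
  sample_poly <- function(poly, closed) {
    if (closed) poly <- rbind(poly, poly[1L, ])
    out <- vector("list", nrow(poly) - 1L)
    for (i in seq_len(nrow(poly) - 1L)) {
      p0 <- poly[i, ]; p1 <- poly[i + 1L, ]
      len <- sqrt(sum((p1 - p0)^2))
      ns <- max(2L, ceiling(len / (pixel_size / 4)))
      tt <- (seq_len(ns) - 0.5) / ns
      out[[i]] <- cbind(p0[1L] + tt * (p1[1L] - p0[1L]),
                        p0[2L] + tt * (p1[2L] - p0[2L]),
                        len / ns)
    }
    do.call(rbind, out)
  }
  pts <- rbind(sample_poly(trace$outline, TRUE),
               do.call(rbind, c(lapply(trace$cristae, sample_poly,
                                       closed = FALSE), list(NULL))))
  cx <- (pts[, 1L] - xr[1L]) / pixel_size + 0.5  # pixel-center coordinates
  cy <- (pts[, 2L] - yr[1L]) / pixel_size + 0.5
  j0 <- pmin(pmax(floor(cx), 1L), nx - 1L)
  i0 <- pmin(pmax(floor(cy), 1L), ny - 1L)
  fx <- pmin(pmax(cx - j0, 0), 1)
  fy <- pmin(pmax(cy - i0, 0), 1)
  v <- numeric(ny * nx)
  splat <- function(ii, jj, w) {
    acc <- rowsum(w, (jj - 1L) * ny + ii)
    idx <- as.integer(rownames(acc))
    v[idx] <<- v[idx] + acc[, 1L]
  }
  w0 <- pts[, 3L]
  splat(i0, j0, w0 * (1 - fx) * (1 - fy))
  splat(i0, j0 + 1L, w0 * fx * (1 - fy))
  splat(i0 + 1L, j0, w0 * (1 - fx) * fy)
  splat(i0 + 1L, j0 + 1L, w0 * fx * fy)
  img <- matrix(v, ny, nx)
  img <- .gauss_blur(img, psf_sigma / pixel_size)
  if (noise_level > 0) {
    scale <- noise_level / max(img)
    sample_noise <- function() {
      matrix(stats::rpois(length(img), img * scale), nrow(img)) / scale
    }
    img <- if (is.null(seed)) sample_noise() else
      withr::with_seed(seed, sample_noise())
  }
  structure(list(image = img, pixel_size = pixel_size,
                 origin = c(xr[1L] + pixel_size / 2, yr[1L] + pixel_size / 2),
                 trace = trace),
            class = "mito_raster")
}

# border-connected background fill (flood from the image border)
.fill_interior <- function(mask) {
  bg <- !mask
  outside <- matrix(FALSE, nrow(mask), ncol(mask))
  outside[1L, ] <- bg[1L, ]
  outside[nrow(mask), ] <- bg[nrow(mask), ]
  outside[, 1L] <- bg[, 1L]
  outside[, ncol(mask)] <- bg[, ncol(mask)]
  repeat {
    grown <- outside
    grown[-1L, ] <- grown[-1L, ] | outside[-nrow(mask), ]
    grown[-nrow(mask), ] <- grown[-nrow(mask), ] | outside[-1L, ]
    grown[, -1L] <- grown[, -1L] | outside[, -ncol(mask)]
    grown[, -ncol(mask)] <- grown[, -ncol(mask)] | outside[, -1L]
    grown <- grown & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  mask | !outside
}

#' Re-trace the outline from a rasterized image
#'
#' Recovers the outline polygon from a raster by thresholding, filling the
#' border-connected background, smoothing the filled mask and extracting the
#' half-maximum contour. Intended as a round-trip check that rasterization
#' preserves shape descriptors.
#'
#' @param raster a `mito_raster` from [rasterize_trace()].
#' @param level threshold as a fraction of the image maximum.
#' @param smooth_sigma_px Gaussian smoothing of the filled mask (pixels).
#' @return Outline polygon (n x 2 matrix, nm).
#' @export
retrace_raster <- function(raster, level = 0.5, smooth_sigma_px = 1.5) {
  stopifnot(inherits(raster, "mito_raster"))
  img <- raster$image
  # threshold relative to the typical ridge intensity (robust to bright
  # crossings and corners)
  ridge <- stats::median(img[img > 0.1 * max(img)])
  mask <- img > level * ridge
  filled <- .fill_interior(mask)
  sm <- .gauss_blur(filled * 1, smooth_sigma_px)
  px <- raster$pixel_size
  xs <- raster$origin[1L] + (seq_len(ncol(img)) - 1L) * px
  ys <- raster$origin[2L] + (seq_len(nrow(img)) - 1L) * px
  # contourLines expects z[x, y]: transpose so rows index x
  cl <- grDevices::contourLines(xs, ys, t(sm), levels = 0.5)
  if (length(cl) == 0L)
    .err("mitoshape_invalid_trace", "no contour found in raster")
  best <- which.max(vapply(cl, function(cc) length(cc$x), 0))
  poly <- cbind(cl[[best]]$x, cl[[best]]$y)
  if (nrow(poly) > 3L &&
      sqrt(sum((poly[1L, ] - poly[nrow(poly), ])^2)) < px / 10)
    poly <- poly[-nrow(poly), , drop = FALSE]
  # smooth marching-squares jaggies, then snap each vertex to the intensity
  # centroid of the membrane ridge along the local normal (ridge following)
  poly <- .smooth_polygon(poly, window = 3L)
  poly <- .refine_to_ridge(poly, raster, reach_px = 2.5)
  poly <- .refine_to_ridge(poly, raster, reach_px = 1.2)
  .smooth_polygon(poly, window = 3L)
}

# move polygon vertices to the intensity centroid along their normals
.refine_to_ridge <- function(poly, raster, reach_px = 1.6, n_samp = 13L) {
  img <- .gauss_blur(raster$image, 1)
  px <- raster$pixel_size
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  tan_v <- poly[nxt, , drop = FALSE] - poly[prv, , drop = FALSE]
  len <- sqrt(rowSums(tan_v^2))
  len[len == 0] <- 1
  nrm <- cbind(tan_v[, 2L], -tan_v[, 1L]) / len
  tt <- seq(-reach_px * px, reach_px * px, length.out = n_samp)
  sample_img <- function(x, y) {
    # bilinear lookup in image coordinates (rows = y)
    cx <- (x - raster$origin[1L]) / px + 1
    cy <- (y - raster$origin[2L]) / px + 1
    i0 <- pmin(pmax(floor(cy), 1L), nrow(img) - 1L)
    j0 <- pmin(pmax(floor(cx), 1L), ncol(img) - 1L)
    fy <- pmin(pmax(cy - i0, 0), 1)
    fx <- pmin(pmax(cx - j0, 0), 1)
    img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      img[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
      img[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
      img[cbind(i0 + 1L, j0 + 1L)] * fx * fy
  }
  shift <- numeric(n)
  wsum <- numeric(n)
  for (t_off in tt) {
    w <- sample_img(poly[, 1L] + t_off * nrm[, 1L],
                    poly[, 2L] + t_off * nrm[, 2L])^2
    shift <- shift + w * t_off
    wsum <- wsum + w
  }
  ok <- wsum > 0
  shift[ok] <- shift[ok] / wsum[ok]
  poly + shift * nrm
}

# circular moving-average smoothing of a closed polygon
.smooth_polygon <- function(poly, window = 5L) {
  n <- nrow(poly)
  if (n <= window) return(poly)
  half <- window %/% 2L
  out <- poly
  for (d in seq_len(half)) {
    fwd <- poly[c((d + 1L):n, 1:d), , drop = FALSE]
    bwd <- poly[c((n - d + 1L):n, 1:(n - d)), , drop = FALSE]
    out <- out + fwd + bwd
  }
  out / (2L * half + 1L)
}

# offset a closed polygon along its vertex normals; negative = inward
.offset_polygon <- function(poly, h) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  tan_v <- poly[nxt, , drop = FALSE] - poly[prv, , drop = FALSE]
  len <- sqrt(rowSums(tan_v^2))
  len[len == 0] <- 1
  tan_v <- tan_v / len
  nrm <- cbind(tan_v[, 2L], -tan_v[, 1L])  # right-hand normal
  cand1 <- poly + h * nrm
  cand2 <- poly - h * nrm
  # inward (negative h) must shrink the area
  if ((.poly_area(cand1) < .poly_area(poly)) == (h < 0)) cand1 else cand2
}
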