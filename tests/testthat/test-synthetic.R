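# Synthetic tracing generator: stadium traces, cohorts with controlled
# coupling, retraction time series, two-group cohorts and rasterization.

test_that("stadium traces reproduce their closed-form descriptors", {
  circle <- generate_stadium_trace(0, 250)
  expect_lt(abs(circularity_2d(circle$outline)$circularity - 1), 1e-3)

  tr <- generate_stadium_trace(500, 125)
  cf <- stadium_forms(500, 125)
  expect_lt(abs(circularity_2d(tr$outline)$circularity - cf$circularity),
            2e-3)

  # plug-in of the generator parameters into the fraction formula
  tr3 <- generate_stadium_trace(500, 125, n_cristae = 3, crista_span = 0.8)
  P <- circularity_2d(tr3$outline)$perimeter
  expected <- 100 * (2 * 3 * 0.8 * 250) / (P + 2 * 3 * 0.8 * 250)
  expect_equal(cristae_fraction_2d(tr3), expected, tolerance = 1e-9)
})

test_that("crista capacity and parameter validation are enforced", {
  expect_error(generate_stadium_trace(100, 125, n_cristae = 5),
               class = "mitoshape_capacity")
  expect_error(generate_stadium_trace(-1, 125),
               class = "mitoshape_invalid_parameter")
  expect_error(generate_stadium_trace(100, 0),
               class = "mitoshape_invalid_parameter")
  expect_error(cohort_spec(n = 2), class = "mitoshape_invalid_parameter")
  expect_error(cohort_spec(coupling_r = -1.2),
               class = "mitoshape_invalid_parameter")
})

test_that("generation is fully deterministic under a fixed seed", {
  g1 <- suppressWarnings(generate_cohort(cohort_spec(n = 20, seed = 5)))
  g2 <- suppressWarnings(generate_cohort(cohort_spec(n = 20, seed = 5)))
  expect_identical(g1$truth, g2$truth)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_traces(g1$traces, f1)
  write_traces(g2$traces, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth tables allow exact parameter recovery when jitter is off", {
  gc <- suppressWarnings(generate_cohort(
    cohort_spec(n = 20, noise_sd = 0, outline_jitter = 0, seed = 9)))
  tab <- suppressMessages(measure_cohort(gc$traces,
                                         exclude_no_cristae = FALSE))
  expect_equal(tab$total_crista_length, gc$truth$total_crista_length,
               tolerance = 1e-9)
  expect_equal(tab$cristae_frac_2d, gc$truth$realized_fraction,
               tolerance = 1e-9)
})

test_that("a deterministic linear link yields a Pearson r of exactly -1", {
  gc <- generate_cohort(cohort_spec(n = 50, coupling_r = -1, noise_sd = 0,
                                    outline_jitter = 0.02, seed = 7))
  tab <- suppressMessages(measure_cohort(gc$traces))
  r <- cor(tab$cristae_frac_2d, tab$circularity)
  expect_lt(abs(r - (-1)), 1e-6)
})

test_that("a moderate coupling target is recovered from measurements", {
  tab <- measured_cohort(cohort_spec(n = 100, coupling_r = -0.6, seed = 42))
  r <- cor(tab$cristae_frac_2d, tab$circularity)
  expect_lt(abs(r - (-0.6)), 0.15)
})

test_that("retraction series conserves total IMM length and circularizes", {
  frames <- generate_timeseries(seq(1, 0, length.out = 8))
  tab <- suppressMessages(measure_cohort(frames, exclude_no_cristae = FALSE))
  total <- tab$perimeter + 2 * tab$total_crista_length
  expect_lt(diff(range(total)) / total[1L], 1e-3)
  expect_equal(tab$cristae_frac_2d[8L], 0)
  expect_gte(tab$circularity[8L], 0.95)
  expect_true(all(diff(tab$cristae_frac_2d) < 0))

  expect_error(generate_timeseries(c(0.2, 0.8)),
               class = "mitoshape_invalid_parameter")
})

test_that("without conservation the outline stays fixed during retraction", {
  frames <- generate_timeseries(c(1, 0.5, 0), conserve_imm_length = FALSE)
  per <- vapply(frames, function(f) circularity_2d(f$outline)$perimeter, 0)
  expect_lt(diff(range(per)) / per[1L], 1e-9)
})

test_that("two-group generation labels groups and shifts elongation", {
  two <- suppressWarnings(generate_two_group_cohort(
    cohort_spec(n = 30, seed = 3)))
  labs <- vapply(two$traces, function(tr) tr$group_label, "")
  expect_setequal(unique(labs), c("control", "perturbed"))
  expect_identical(sum(labs == "control"), 30L)
  med_axis <- tapply(two$truth$axis_length, two$truth$group, median)
  expect_lt(med_axis[["perturbed"]], med_axis[["control"]])
  expect_error(cohort_spec(n = 0), class = "mitoshape_invalid_parameter")
})

test_that("rasterization places ridges on the polylines at the right scale", {
  tr <- generate_stadium_trace(500, 125, n_cristae = 3)
  ra <- rasterize_trace(tr, pixel_size = 25)
  all_pts <- rbind(tr$outline, do.call(rbind, tr$cristae))
  bbox <- apply(all_pts, 2, function(v) diff(range(v)))
  margin <- 2 * 25  # default margin at psf 0
  expect_identical(ncol(ra$image), as.integer(ceiling((bbox[1] + 2 * margin) / 25)))
  expect_identical(nrow(ra$image), as.integer(ceiling((bbox[2] + 2 * margin) / 25)))
  # every bright pixel lies within one pixel of some membrane polyline
  hot <- which(ra$image > 0.25 * max(ra$image), arr.ind = TRUE)
  cx <- ra$origin[1L] + (hot[, 2L] - 1L) * 25
  cy <- ra$origin[2L] + (hot[, 1L] - 1L) * 25
  densify <- function(poly, closed = FALSE) {
    if (closed) poly <- rbind(poly, poly[1L, ])
    do.call(rbind, lapply(seq_len(nrow(poly) - 1L), function(i) {
      tt <- seq(0, 1, length.out = 40L)
      cbind(poly[i, 1L] + tt * (poly[i + 1L, 1L] - poly[i, 1L]),
            poly[i, 2L] + tt * (poly[i + 1L, 2L] - poly[i, 2L]))
    }))
  }
  seg_pts <- rbind(densify(tr$outline, closed = TRUE),
                   do.call(rbind, lapply(tr$cristae, densify)))
  mind <- vapply(seq_len(nrow(hot)), function(i)
    min(sqrt((seg_pts[, 1L] - cx[i])^2 + (seg_pts[, 2L] - cy[i])^2)), 0)
  expect_lt(max(mind), 25 * 1.5)
})

test_that("re-tracing a noiseless raster recovers circularity within 2%", {
  tr <- generate_stadium_trace(800, 150, n_cristae = 5)
  ra <- rasterize_trace(tr, pixel_size = 25)
  rec <- retrace_raster(ra)
  c_true <- circularity_2d(tr$outline)$circularity
  c_rec <- circularity_2d(rec)$circularity
  expect_lt(abs(c_rec - c_true) / c_true, 0.02)
})

test_that("Poisson noise is seeded and leaves the ground truth attached", {
  tr <- generate_stadium_trace(300, 125, n_cristae = 2)
  r1 <- rasterize_trace(tr, 25, psf_sigma = 40, noise_level = 50, seed = 8)
  r2 <- rasterize_trace(tr, 25, psf_sigma = 40, noise_level = 50, seed = 8)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$trace$id, tr$id)
})
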