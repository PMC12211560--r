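# File formats and the pipeline driver.
#
# Traces travel as one JSON document per cohort (schema-versioned,
# human-inspectable); tables as CSV; shape profiles as CSV with unit
# comments; meshes as ASCII OBJ/PLY.

.TRACE_FORMAT <- "mitoshape-traces"
.TRACE_VERSION <- 1L

.trace_to_record <- function(tr) {
  rec <- list(
    id = tr$id,
    outline = list(x = tr$outline[, 1L], y = tr$outline[, 2L]),
    cristae = lapply(tr$cristae, function(cxy)
      list(x = cxy[, 1L], y = cxy[, 2L]))
  )
  if (!is.null(tr$timestamp)) rec$timestamp <- tr$timestamp
  if (!is.null(tr$pixel_size)) rec$pixel_size <- tr$pixel_size
  if (!is.null(tr$group_label)) rec$group_label <- tr$group_label
  if (!is.null(tr$extra)) rec <- c(rec, tr$extra)
  rec
}

.record_to_trace <- function(rec, idx) {
  where <- sprintf("record %d%s", idx,
                   if (!is.null(rec$id)) sprintf(" ('%s')", rec$id) else "")
  need <- function(cond, field, msg) {
    if (!cond)
      .err("mitoshape_schema_error",
           sprintf("%s, field '%s': %s", where, field, msg))
  }
  need(!is.null(rec$outline), "outline", "missing")
  need(is.list(rec$outline) && !is.null(rec$outline$x) &&
         !is.null(rec$outline$y), "outline", "needs x and y arrays")
  need(length(rec$outline$x) == length(rec$outline$y), "outline",
       "x and y lengths differ")
  need(length(rec$outline$x) >= 3L, "outline", "needs >= 3 vertices")
  cristae <- rec$cristae
  if (is.null(cristae)) cristae <- list()
  cr <- lapply(seq_along(cristae), function(i) {
    ci <- cristae[[i]]
    f <- sprintf("cristae[%d]", i)
    need(!is.null(ci$x) && !is.null(ci$y), f, "needs x and y arrays")
    need(length(ci$x) == length(ci$y), f, "x and y lengths differ")
    need(length(ci$x) >= 2L, f, "needs >= 2 vertices")
    cbind(as.numeric(ci$x), as.numeric(ci$y))
  })
  known <- c("id", "outline", "cristae", "timestamp", "pixel_size",
             "group_label")
  extra <- rec[setdiff(names(rec), known)]
  if (length(extra) == 0L) extra <- NULL
  mito_trace(
    outline = cbind(as.numeric(rec$outline$x), as.numeric(rec$outline$y)),
    cristae = cr,
    id = if (is.null(rec$id)) sprintf("trace_%03d", idx) else rec$id,
    timestamp = rec$timestamp,
    pixel_size = rec$pixel_size,
    group_label = rec$group_label,
    extra = extra
  )
}

#' Write tracings to a JSON trace file
#'
#' One schema-versioned JSON document per cohort; coordinates are stored in
#' nm at full double precision, so write - read - write round trips are
#' byte-identical.
#'
#' @param traces list of [mito_trace()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "mito_trace")) traces <- list(traces)
  doc <- list(
    format = .TRACE_FORMAT,
    version = .TRACE_VERSION,
    units = "nm",
    traces = lapply(traces, .trace_to_record)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read tracings from a JSON trace file
#'
#' @param path trace file written by [write_traces()].
#' @return list of [mito_trace()]. Unknown per-record fields are preserved
#'   in `$extra` and survive a rewrite.
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    .err("mitoshape_io_error", sprintf("no such file: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, .TRACE_FORMAT))
    .err("mitoshape_schema_error",
         sprintf("not a %s file (format '%s')", .TRACE_FORMAT,
                 if (is.null(doc$format)) "?" else doc$format))
  if (!is.numeric(doc$version) || doc$version > .TRACE_VERSION)
    .err("mitoshape_schema_error",
         sprintf("unsupported schema version %s", doc$version))
  lapply(seq_along(doc$traces), function(i)
    .record_to_trace(doc$traces[[i]], i))
}

#' Write / read an axisymmetric profile as CSV
#'
#' Columns `s, psi, r, z` (nm / radians), with unit comments in the header.
#'
#' @param shape an [axisym_shape()].
#' @param path file path.
#' @return `path` invisibly / an [axisym_shape()].
#' @export
write_profile_csv <- function(shape, path) {
  stopifnot(inherits(shape, "axisym_shape"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# axisymmetric mid-surface profile",
               "# s: arclength (nm); psi: tilt (rad); r, z: nm"), con)
  utils::write.csv(data.frame(s = shape$s, psi = shape$psi,
                              r = shape$r, z = shape$z),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  axisym_shape(s = df$s, psi = df$psi, r = df$r, z = df$z)
}

# ---- mesh export ----

#' Export a minimized shape as a surface-of-revolution mesh
#'
#' Triangulates the solution profile around the symmetry axis and writes an
#' ASCII OBJ or PLY file. The mesh is watertight (pole fans + quad strips);
#' at the default angular resolution its total triangle area matches the
#' profile quadrature area within 0.5%.
#'
#' @param solution a `shape_solution` (or closed [axisym_shape()]).
#' @param path destination file; extension chooses the format unless
#'   `format` is given.
#' @param format `"obj"` or `"ply"`.
#' @param n_phi angular resolution (default 64).
#' @return Invisibly, a list with `n_vertices`, `n_faces`, `mesh_area`.
#' @export
export_shape_mesh <- function(solution, path, format = NULL, n_phi = 64L) {
  shape <- if (inherits(solution, "shape_solution")) solution$shape
           else solution
  stopifnot(inherits(shape, "axisym_shape"))
  if (!shape$closed)
    .err("mitoshape_invalid_shape", "mesh export requires a closed shape")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply"))
  n_phi <- as.integer(n_phi)
  n <- shape$n_nodes
  interior <- which(shape$r > 0)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  nv_ring <- length(interior)
  # vertices: pole0, rings, pole1
  verts <- matrix(0, 2L + nv_ring * n_phi, 3L)
  verts[1L, ] <- c(0, 0, shape$z[1L])
  for (i in seq_along(interior)) {
    ii <- interior[i]
    idx <- 1L + (i - 1L) * n_phi + seq_len(n_phi)
    verts[idx, ] <- cbind(shape$r[ii] * cos(phi), shape$r[ii] * sin(phi),
                          shape$z[ii])
  }
  last <- nrow(verts)
  verts[last, ] <- c(0, 0, shape$z[n])
  ring <- function(i) 1L + (i - 1L) * n_phi + seq_len(n_phi)
  faces <- vector("list", nv_ring + 1L)
  r1 <- ring(1L)
  faces[[1L]] <- cbind(1L, r1, c(r1[-1L], r1[1L]))
  for (i in seq_len(nv_ring - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    faces[[i + 1L]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  rl <- ring(nv_ring)
  faces[[nv_ring + 1L]] <- cbind(last, c(rl[-1L], rl[1L]), rl)
  F_mat <- do.call(rbind, faces)
  tri_area <- function(v, f) {
    e1 <- v[f[, 2L], ] - v[f[, 1L], ]
    e2 <- v[f[, 3L], ] - v[f[, 1L], ]
    cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
    cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
    cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
    sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
  }
  area <- tri_area(verts, F_mat)
  if (format == "obj") {
    lines <- c("# mitoshape surface-of-revolution mesh",
               sprintf("v %.6f %.6f %.6f", verts[, 1L], verts[, 2L],
                       verts[, 3L]),
               sprintf("f %d %d %d", F_mat[, 1L], F_mat[, 2L], F_mat[, 3L]))
  } else {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F_mat)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.6f %.6f %.6f", verts[, 1L], verts[, 2L],
                       verts[, 3L]),
               sprintf("3 %d %d %d", F_mat[, 1L] - 1L, F_mat[, 2L] - 1L,
                       F_mat[, 3L] - 1L))
  }
  writeLines(lines, path)
  invisible(list(n_vertices = nrow(verts), n_faces = nrow(F_mat),
                 mesh_area = area))
}

# ---- pipeline driver ----

.PIPELINE_STAGES <- c("simulate-shapes", "synth", "measure", "correlate",
                      "split", "compare", "timeseries")

.cohort_spec_from_config <- function(cfg, seed) {
  args <- cfg[intersect(names(cfg),
                        names(formals(cohort_spec)))]
  if (is.null(args$seed)) args$seed <- seed
  do.call(cohort_spec, args)
}

#' Run the analysis pipeline from a configuration file
#'
#' Executes the configured stages in order and writes all tables, plots and
#' logs into an output directory. Stages: `simulate-shapes` (bending-energy
#' shape family), `synth` (synthetic cohort), `measure`, `correlate`,
#' `split`, `compare` (two-group), `timeseries`. Every stage draws its seed
#' from the config so a run is reproducible from its logged configuration
#' alone.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Fields: `stages` (character vector), `seed`, `out_dir`
#'   (optional; default a timestamped directory), plus per-stage blocks
#'   (`shapes`, `cohort`, `perturbed`, `timeseries`).
#' @param out_dir overrides the configured output directory.
#' @return The output directory path, invisibly; `summary.json` and
#'   `summary.txt` within it hold the headline numbers.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config))
      .err("mitoshape_io_error", sprintf("no such config: %s", config))
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L)
    .err("mitoshape_config_error", "config selects no stages")
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown) > 0L)
    .err("mitoshape_config_error",
         sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(out_dir))
    out_dir <- if (!is.null(config$out_dir)) config$out_dir else
      sprintf("mitoshape-run-%s", format(Sys.time(), "%Y%m%d-%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  logf("mitoshape %s", as.character(utils::packageVersion("mitoshape")))
  logf("config md5: %s", cfg_hash)
  logf("seed: %d", seed)
  logf("stages: %s", paste(stages, collapse = ", "))

  state <- list()
  summary <- list(seed = seed)

  for (stage in stages) {
    logf("stage %s", stage)
    if (stage == "simulate-shapes") {
      sh <- config$shapes
      area <- if (!is.null(sh$mid_area)) sh$mid_area else
        4 * pi * (if (!is.null(sh$diameter)) sh$diameter / 2 else 250)^2
      d <- if (!is.null(sh$d)) sh$d else 10
      targets <- if (!is.null(sh$targets)) as.numeric(sh$targets) else
        c(0.08, 0.10, 0.12, 0.16, 0.20)
      fam <- shape_family(area, d, targets,
                          options = solver_options(seed = seed))
      fs <- family_summary(fam)
      utils::write.csv(fs, file.path(out_dir, "shape_family.csv"),
                       row.names = FALSE)
      for (i in seq_along(fam))
        write_profile_csv(fam[[i]]$shape,
                          file.path(out_dir, sprintf("profile_%03d.csv", i)))
      state$family <- fam
      summary$shape_family <- list(
        n_targets = nrow(fs),
        final_sphericity = fs$sphericity[nrow(fs)],
        final_class = fs$shape_class[nrow(fs)]
      )
    } else if (stage == "synth") {
      spec <- .cohort_spec_from_config(config$cohort, seed)
      gc <- generate_cohort(spec)
      write_traces(gc$traces, file.path(out_dir, "traces.json"))
      utils::write.csv(gc$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      logf("synth: n = %d, seed = %d", spec$n, spec$seed)
      state$traces <- gc$traces
    } else if (stage == "measure") {
      if (is.null(state$traces)) {
        tf <- config$traces
        if (is.null(tf))
          .err("mitoshape_config_error",
               "measure stage needs a synth stage or a traces file")
        state$traces <- read_traces(tf)
      }
      excl <- utils::capture.output(
        tab <- measure_cohort(state$traces), type = "message")
      if (length(excl) > 0L) logf("%s", paste(excl, collapse = "; "))
      utils::write.csv(tab, file.path(out_dir, "measurements.csv"),
                       row.names = FALSE)
      state$table <- tab
      summary$measure <- list(n = nrow(tab),
                              excluded = attr(tab, "excluded"))
    } else if (stage == "correlate") {
      if (is.null(state$table))
        .err("mitoshape_config_error", "correlate stage needs measurements")
      for (mode in c("2d", "3d")) {
        cr <- correlate_fraction_circularity(state$table, mode = mode)
        summary[[paste0("correlation_", mode)]] <-
          list(n = cr$n, r = cr$pearson_r, p = cr$p_value,
               slope = cr$slope, intercept = cr$intercept)
      }
      .plot_correlation(state$table,
                        correlate_fraction_circularity(state$table, "2d"),
                        file.path(out_dir, "correlation_2d.png"))
    } else if (stage == "split") {
      if (is.null(state$table))
        .err("mitoshape_config_error", "split stage needs measurements")
      sp <- size_split_analysis(state$table)
      summary$size_split <- list(
        threshold = sp$threshold,
        small = if (is.null(sp$small)) NULL else
          list(n = sp$small$n, r = sp$small$pearson_r, p = sp$small$p_value),
        large = if (is.null(sp$large)) NULL else
          list(n = sp$large$n, r = sp$large$pearson_r, p = sp$large$p_value)
      )
      utils::write.csv(sp$table, file.path(out_dir,
                                           "measurements_split.csv"),
                       row.names = FALSE)
    } else if (stage == "compare") {
      ctrl <- .cohort_spec_from_config(config$cohort, seed)
      pert <- if (!is.null(config$perturbed))
        .cohort_spec_from_config(config$perturbed, seed + 1L) else NULL
      two <- generate_two_group_cohort(ctrl, pert)
      tabs <- split(seq_along(two$traces),
                    vapply(two$traces, function(tr) tr$group_label, ""))
      mt <- suppressMessages(lapply(tabs, function(ii)
        measure_cohort(two$traces[ii])))
      cmp <- compare_groups(mt[[1L]], mt[[2L]],
                            labels = names(mt))
      summary$comparison <- list(metric = cmp$metric,
                                 t = cmp$t_statistic, p = cmp$p_value)
      .plot_comparison(mt[[1L]], mt[[2L]], names(mt),
                       file.path(out_dir, "comparison.png"))
    } else if (stage == "timeseries") {
      tscfg <- config$timeseries
      nf <- if (!is.null(tscfg$n_frames)) tscfg$n_frames else 8L
      sched <- if (!is.null(tscfg$schedule)) as.numeric(tscfg$schedule) else
        seq(1, 0, length.out = nf)
      frames <- generate_timeseries(sched, seed = seed)
      write_traces(frames, file.path(out_dir, "timeseries.json"))
      prof <- timeseries_profile(frames)
      utils::write.csv(prof$profile, file.path(out_dir, "timeseries.csv"),
                       row.names = FALSE)
      summary$timeseries <- list(
        kendall_tau = prof$kendall_tau,
        final_circularity = prof$profile$circularity[nrow(prof$profile)],
        final_fraction = prof$profile$cristae_frac_2d[nrow(prof$profile)]
      )
      .plot_timeseries(prof$profile, file.path(out_dir, "timeseries.png"))
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  txt <- utils::capture.output(utils::str(summary, give.attr = FALSE))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  logf("done")
  invisible(out_dir)
}

# ---- base-graphics plot helpers (pipeline artifacts) ----

.plot_correlation <- function(table, cr, path) {
  grDevices::png(path, width = 900, height = 700, res = 130)
  on.exit(grDevices::dev.off())
  ycol <- if (cr$mode == "2d") "cristae_frac_2d" else "cristae_frac_3d"
  plot(table$circularity, table[[ycol]],
       pch = 19, col = "#00000088",
       xlab = "circularity", ylab = "[cristae/IMM]%",
       main = sprintf("n = %d, r = %.2f, p = %.2g", cr$n, cr$pearson_r,
                      cr$p_value))
  graphics::polygon(c(cr$conf_band$x, rev(cr$conf_band$x)),
                    c(cr$conf_band$lwr, rev(cr$conf_band$upr)),
                    col = "#1f77b433", border = NA)
  graphics::abline(cr$intercept, cr$slope, col = "#1f77b4", lwd = 2)
}

.plot_comparison <- function(t1, t2, labels, path) {
  grDevices::png(path, width = 700, height = 700, res = 130)
  on.exit(grDevices::dev.off())
  graphics::boxplot(list(t1$circularity, t2$circularity), names = labels,
                    ylab = "circularity", range = 1.5)
}

.plot_timeseries <- function(profile, path) {
  grDevices::png(path, width = 900, height = 700, res = 130)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(5, 4, 2, 4))
  plot(profile$time, profile$cristae_frac_2d, type = "b", pch = 19,
       xlab = "time (s)", ylab = "[cristae/IMM]%", col = "#d62728")
  graphics::par(new = TRUE)
  plot(profile$time, profile$circularity, type = "b", pch = 17,
       axes = FALSE, xlab = "", ylab = "", col = "#1f77b4",
       ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("circularity", side = 4, line = 2.5)
}
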