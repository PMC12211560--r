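# Cohort statistics relating cristae extent to mitochondrial shape:
# Pearson correlation of [cristae/IMM]% against circularity, median size
# splits, unpaired two-group comparisons, and time-resolved profiles.

#' Measure a cohort of tracings
#'
#' Applies [measure_trace()] to every trace. Mitochondria without any
#' traced cristae are excluded by default (mirroring the acquisition rule
#' that unlabelled-cristae mitochondria cannot be scored); exclusions are
#' reported via a message and the `excluded` attribute.
#'
#' @param traces list of [mito_trace()].
#' @param exclude_no_cristae drop traces without cristae (default TRUE).
#' @return data.frame of measurements (one row per retained trace), with
#'   attribute `excluded` (number of dropped rows).
#' @export
measure_cohort <- function(traces, exclude_no_cristae = TRUE) {
  if (length(traces) == 0L)
    .err("mitoshape_invalid_parameter", "no traces supplied")
  tab <- do.call(rbind, lapply(traces, measure_trace))
  n_no <- sum(tab$no_cristae)
  if (exclude_no_cristae && n_no > 0L) {
    message(sprintf("excluded %d of %d traces without cristae",
                    n_no, nrow(tab)))
    tab <- tab[!tab$no_cristae, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "excluded") <- if (exclude_no_cristae) n_no else 0L
  tab
}

#' Correlate cristae fraction with circularity
#'
#' Pearson product-moment correlation of the cristae fraction (2D length
#' fraction or inferred-3D surface fraction) against circularity, with the
#' two-tailed p-value from the exact t transform on n - 2 degrees of
#' freedom, the least-squares line, and a pointwise 95% confidence band for
#' the mean response.
#'
#' @param table measurement table from [measure_cohort()].
#' @param mode `"2d"` (cristae_frac_2d) or `"3d"` (cristae_frac_3d).
#' @param conf_level confidence level for the band (default 0.95).
#' @return list of class `mito_correlation`: `n`, `pearson_r`, `p_value`,
#'   `slope`, `intercept`, `conf_band` (data.frame x, fit, lwr, upr),
#'   `mode`.
#' @export
correlate_fraction_circularity <- function(table, mode = c("2d", "3d"),
                                           conf_level = 0.95) {
  mode <- match.arg(mode)
  ycol <- if (mode == "2d") "cristae_frac_2d" else "cristae_frac_3d"
  x <- table$circularity
  y <- table[[ycol]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    .err("mitoshape_insufficient_data",
         "need >= 3 finite rows for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .err("mitoshape_degenerate_data",
         "zero variance in circularity or cristae fraction")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson",
                                         alternative = "two.sided"))
  fit <- stats::lm(y ~ x)
  xg <- seq(min(x), max(x), length.out = 50L)
  band <- stats::predict(fit, newdata = data.frame(x = xg),
                         interval = "confidence", level = conf_level)
  structure(
    list(n = length(x),
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         conf_band = data.frame(x = xg, fit = band[, "fit"],
                                lwr = band[, "lwr"], upr = band[, "upr"]),
         conf_level = conf_level,
         mode = mode),
    class = "mito_correlation"
  )
}

#' @export
print.mito_correlation <- function(x, ...) {
  cat(sprintf(
    "<mito_correlation> [cristae/IMM]%% (%s) vs circularity: n = %d, r = %.3f, p = %.3g\n",
    x$mode, x$n, x$pearson_r, x$p_value))
  invisible(x)
}

#' Median size split with per-group correlations
#'
#' Splits the cohort at the median 2D area into `small` (at or below the
#' median; ties are assigned to small deterministically) and `large` (above
#' it) groups, and computes [correlate_fraction_circularity()] within each.
#' A group with fewer than 3 usable rows, or with degenerate variance, gets
#' an undefined (NULL) correlation rather than aborting.
#'
#' @param table measurement table from [measure_cohort()].
#' @param mode passed to [correlate_fraction_circularity()].
#' @return list with `threshold` (median area, nm^2), `small`, `large`
#'   (each a `mito_correlation` or NULL), `size_class` (factor aligned with
#'   `table` rows), `table` (input with a `size_class` column).
#' @export
size_split_analysis <- function(table, mode = "2d") {
  if (nrow(table) < 6L)
    .err("mitoshape_insufficient_data", "need >= 6 rows for a size split")
  med <- stats::median(table$area_2d)
  cls <- ifelse(table$area_2d <= med, "small", "large")
  table$size_class <- cls
  run <- function(sub) {
    tryCatch(correlate_fraction_circularity(sub, mode = mode),
             mitoshape_error = function(e) NULL)
  }
  list(
    threshold = med,
    small = run(table[cls == "small", , drop = FALSE]),
    large = run(table[cls == "large", , drop = FALSE]),
    size_class = cls,
    table = table
  )
}

#' Two-group comparison of a shape metric
#'
#' Unpaired two-tailed Student's t-test on the chosen metric, with
#' per-group descriptive statistics matching the box-plot conventions
#' (median, IQR, Tukey whisker bounds at 1.5 x IQR).
#'
#' @param table_control,table_perturbed measurement tables.
#' @param metric column to compare (default `"circularity"`).
#' @param labels group labels.
#' @return list of class `mito_comparison`: `t_statistic`, `p_value`,
#'   `groups` (data.frame of n/mean/median/q1/q3/iqr/whisker bounds).
#' @export
compare_groups <- function(table_control, table_perturbed,
                           metric = "circularity",
                           labels = c("control", "perturbed")) {
  xc <- table_control[[metric]]
  xp <- table_perturbed[[metric]]
  xc <- xc[is.finite(xc)]
  xp <- xp[is.finite(xp)]
  if (length(xc) < 2L || length(xp) < 2L)
    .err("mitoshape_insufficient_data",
         "each group needs >= 2 finite values for a t-test")
  tt <- stats::t.test(xc, xp, var.equal = TRUE,
                      alternative = "two.sided")
  desc <- function(v, lab) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(group = lab, n = length(v), mean = mean(v), median = q[2L],
               q1 = q[1L], q3 = q[3L], iqr = iqr,
               whisker_low = q[1L] - 1.5 * iqr,
               whisker_high = q[3L] + 1.5 * iqr,
               stringsAsFactors = FALSE)
  }
  structure(
    list(metric = metric,
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         groups = rbind(desc(xc, labels[1L]), desc(xp, labels[2L]))),
    class = "mito_comparison"
  )
}

#' @export
print.mito_comparison <- function(x, ...) {
  cat(sprintf("<mito_comparison> %s: t = %.3f (df %.0f), p = %.3g\n",
              x$metric, x$t_statistic, x$df, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Time-resolved cristae-fraction and circularity profile
#'
#' Per-frame morphometrics for a time series of tracings of one
#' mitochondrion, with start-to-end deltas and a monotonic-trend statistic
#' (Kendall tau of cristae fraction against time).
#'
#' @param traces list of [mito_trace()] with strictly increasing timestamps.
#' @return list with `profile` (data.frame time, cristae_frac_2d,
#'   cristae_frac_3d, circularity, area_2d, perimeter), `delta`
#'   (end - start for fraction and circularity), `kendall_tau` (NA when the
#'   fraction is constant).
#' @export
timeseries_profile <- function(traces) {
  if (length(traces) < 2L)
    .err("mitoshape_insufficient_data", "need >= 2 frames")
  times <- vapply(traces, function(tr) {
    if (is.null(tr$timestamp)) NA_real_ else tr$timestamp
  }, 0)
  if (anyNA(times) || any(diff(times) <= 0))
    .err("mitoshape_invalid_parameter",
         "timestamps must be present and strictly increasing")
  tab <- do.call(rbind, lapply(traces, measure_trace))
  profile <- data.frame(
    time = times,
    cristae_frac_2d = tab$cristae_frac_2d,
    cristae_frac_3d = tab$cristae_frac_3d,
    circularity = tab$circularity,
    area_2d = tab$area_2d,
    perimeter = tab$perimeter
  )
  nfr <- nrow(profile)
  tau <- if (stats::sd(profile$cristae_frac_2d) == 0) NA_real_ else
    suppressWarnings(stats::cor(profile$time, profile$cristae_frac_2d,
                                method = "kendall"))
  list(
    profile = profile,
    delta = c(cristae_frac_2d = profile$cristae_frac_2d[nfr] -
                profile$cristae_frac_2d[1L],
              circularity = profile$circularity[nfr] -
                profile$circularity[1L]),
    kendall_tau = tau
  )
}
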