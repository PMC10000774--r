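#' Fit a calibration line
#'
#' Ordinary least-squares line of detector response on concentration, the
#' basis of ICH Q2 linearity assessment and of the LOD/LOQ calculation.
#'
#' @param concentrations Concentrations (ug/mL), at least 3 distinct.
#' @param responses Detector areas, same length.
#' @param analyte Optional analyte label carried through to reports.
#' @return A `"calibration_curve"`: slope, intercept, `r_squared`,
#'   `sigma` (residual SD of the response), plus `lod`/`loq` derived from
#'   them via [lod_loq()].
#' @export
fit_calibration <- function(concentrations, responses, analyte = "") {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  sigma <- sqrt(rss / stats::df.residual(fit))
  limits <- lod_loq(sigma, slope)
  structure(list(analyte = analyte, concentrations = x, responses = y,
                 slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - rss / sum((y - mean(y))^2), sigma = sigma,
                 lod = limits[["lod"]], loq = limits[["loq"]]),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration%s: slope %.6g, intercept %.6g, R2 %.5f, LOD %.4g, LOQ %.4g\n",
    if (nzchar(x$analyte)) paste0(" (", x$analyte, ")") else "",
    x$slope, x$intercept, x$r_squared, x$lod, x$loq))
  invisible(x)
}

#' Detection and quantitation limits from calibration noise
#'
#' The ICH Q2 signal-to-noise construction: `LOD = 3.3 sigma / s` and
#' `LOQ = 10 sigma / s`, where `sigma` is the standard deviation of the
#' response and `s` the calibration slope.  Both derive from the same
#' sigma and slope, so `LOQ / LOD = 10 / 3.3` identically.
#'
#' @param sigma Response standard deviation (>= 0).
#' @param slope Calibration slope (non-zero), response units per (ug/mL).
#' @return Named numeric vector `c(lod = , loq = )` in ug/mL.
#' @examples
#' lod_loq(sigma = 1, slope = 1)   # c(lod = 3.3, loq = 10)
#' @export
lod_loq <- function(sigma, slope) {
  if (slope == 0) stop("slope must be non-zero", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  c(lod = 3.3 * sigma / abs(slope), loq = 10 * sigma / abs(slope))
}

#' Recovery and precision of replicate determinations
#'
#' `%recovery = 100 * mean(found) / nominal`;
#' `%RSD = 100 * sd(found) / mean(found)`.  The usual ICH acceptance
#' bands for an assay of this kind are recovery in 98--102% and RSD
#' below 2%.
#'
#' @param found Replicate measured amounts (>= 2 values).
#' @param nominal True (spiked) amount, > 0.
#' @return Named numeric vector `c(recovery = , rsd = )` in percent.
#' @export
recovery_and_precision <- function(found, nominal) {
  found <- as.numeric(found)
  if (length(found) < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (nominal <= 0) stop("nominal must be positive", call. = FALSE)
  m <- mean(found)
  if (m == 0) stop("mean of found values is zero", call. = FALSE)
  c(recovery = 100 * m / nominal, rsd = 100 * stats::sd(found) / m)
}

#' Critical values for the two-sample comparison tests
#'
#' Two-sided Student t quantile at level `alpha` with `df` degrees of
#' freedom, and the upper-`alpha` F quantile at (`df1`, `df2`).
#'
#' @param alpha Significance level.
#' @param df,df1,df2 Degrees of freedom.
#' @return Scalar critical value.
#' @examples
#' round(critical_t(0.05, 4), 2)      # 2.78
#' round(critical_f(0.05, 4, 4), 2)   # 6.39
#' @export
critical_t <- function(alpha, df) stats::qt(1 - alpha / 2, df)

#' @rdname critical_t
#' @export
critical_f <- function(alpha, df1, df2) stats::qf(1 - alpha, df1, df2)

#' Compare two analytical methods from summary statistics
#'
#' Pooled-variance two-sample t test (Welch optional) on the means and a
#' variance-ratio F test (larger variance in the numerator, so `F >= 1`).
#' The F-test degrees of freedom default to `(nA-1, nB-1)` but can be
#' overridden: published comparison tables sometimes quote critical values
#' computed at other df conventions, and reproducing such a table requires
#' matching its df.
#'
#' @param mean_a,sd_a,n_a Summary of method A (per analyte).
#' @param mean_b,sd_b,n_b Summary of method B.
#' @param alpha Significance level (default 0.05).
#' @param analyte Optional label.
#' @param welch Use the Welch (unequal-variance) t instead of pooled.
#' @param df_f Length-2 override for the F-test critical-value df.
#' @return A `"method_comparison"`: t and F statistics, critical values,
#'   degrees of freedom and equivalent/different verdicts.
#' @examples
#' cmp <- compare_methods(27.15, 0.35, 3, 27.62, 0.26, 3)
#' round(cmp$t, 2)  # 1.87
#' @export
compare_methods <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                            alpha = 0.05, analyte = "", welch = FALSE,
                            df_f = NULL) {
  stopifnot(n_a >= 2, n_b >= 2)
  if (sd_a <= 0 || sd_b <= 0)
    stop("both SDs must be strictly positive", call. = FALSE)
  if (welch) {
    se <- sqrt(sd_a^2 / n_a + sd_b^2 / n_b)
    df_t <- se^4 / ((sd_a^2 / n_a)^2 / (n_a - 1) +
                      (sd_b^2 / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df_t <- n_a + n_b - 2
  }
  tstat <- abs(mean_a - mean_b) / se
  fstat <- max(sd_a, sd_b)^2 / min(sd_a, sd_b)^2
  if (is.null(df_f)) {
    df_f <- if (sd_a >= sd_b) c(n_a - 1, n_b - 1) else c(n_b - 1, n_a - 1)
  }
  t_crit <- critical_t(alpha, df_t)
  f_crit <- critical_f(alpha, df_f[1L], df_f[2L])
  structure(list(analyte = analyte,
                 mean_a = mean_a, sd_a = sd_a, n_a = n_a,
                 mean_b = mean_b, sd_b = sd_b, n_b = n_b,
                 t = tstat, df_t = df_t, t_critical = t_crit,
                 F = fstat, df_f = df_f, f_critical = f_crit,
                 alpha = alpha, welch = welch,
                 means_equivalent = tstat <= t_crit,
                 variances_equivalent = fstat <= f_crit),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "%s%.2f +/- %.2f (n=%d) vs %.2f +/- %.2f (n=%d): t = %.2f (crit %.2f), F = %.2f (crit %.2f)\n",
    if (nzchar(x$analyte)) paste0(x$analyte, ": ") else "",
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$t, x$t_critical, x$F, x$f_critical))
  cat(sprintf("means %s, variances %s at alpha = %g\n",
              if (x$means_equivalent) "equivalent" else "different",
              if (x$variances_equivalent) "equivalent" else "different",
              x$alpha))
  invisible(x)
}

#' Tabulated chromatographic peak list
#'
#' @param condition Stress-condition label (`"none"`, `"acid"`, `"base"`,
#'   `"thermal"`, `"sunlight"`, `"oxidative"`, `"uv"`, ...).
#' @param rt Retention times in minutes, strictly increasing.
#' @param area Peak areas, non-negative.
#' @param parent Logical flags marking the parent (analyte) peaks.
#' @return A `"peak_table"` data frame.
#' @export
peak_table <- function(condition, rt, area, parent) {
  rt <- as.numeric(rt); area <- as.numeric(area); parent <- as.logical(parent)
  stopifnot(length(rt) == length(area), length(rt) == length(parent))
  if (any(rt <= 0)) stop("retention times must be positive", call. = FALSE)
  if (is.unsorted(rt, strictly = TRUE))
    stop("retention times must be strictly increasing", call. = FALSE)
  if (any(area < 0)) stop("areas must be non-negative", call. = FALSE)
  structure(data.frame(condition = condition, rt = rt, area = area,
                       parent = parent),
            class = c("peak_table", "data.frame"))
}

#' Percent degradation from pre/post-stress peak tables
#'
#' Matches each parent peak of the reference table to the stressed table
#' by retention time (within `rt_tol` minutes) and reports
#' `100 * (sum of reference parent areas - sum of matched stressed areas)
#' / sum of reference parent areas`.  Stressed peaks matching no reference
#' parent are returned as the degradant list; in a stability-indicating
#' assay these typically elute before the parents (lower retention).
#'
#' @param reference Unstressed [peak_table()] containing the parent peaks.
#' @param stressed Post-stress [peak_table()].
#' @param rt_tol Retention-time matching tolerance in minutes
#'   (default 0.2).
#' @return List with `percent_degradation` and `degradants` (a subset of
#'   the stressed table).
#' @export
percent_degradation <- function(reference, stressed, rt_tol = 0.2) {
  stopifnot(inherits(reference, "peak_table"), inherits(stressed, "peak_table"))
  par_ref <- reference[reference$parent, , drop = FALSE]
  if (nrow(par_ref) == 0L)
    stop("reference table contains no parent peaks", call. = FALSE)
  ref_sum <- sum(par_ref$area)
  if (ref_sum == 0) stop("reference parent area sum is zero", call. = FALSE)

  matched_area <- 0
  matched_idx <- integer()
  for (i in seq_len(nrow(par_ref))) {
    dists <- abs(stressed$rt - par_ref$rt[i])
    j <- which.min(dists)
    if (length(j) && dists[j] <= rt_tol && !(j %in% matched_idx)) {
      matched_area <- matched_area + stressed$area[j]
      matched_idx <- c(matched_idx, j)
    }
  }
  degradants <- stressed[setdiff(seq_len(nrow(stressed)), matched_idx), ,
                         drop = FALSE]
  list(percent_degradation = 100 * (ref_sum - matched_area) / ref_sum,
       degradants = degradants)
}
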