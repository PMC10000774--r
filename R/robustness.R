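#' Plackett--Burman factor effects
#'
#' Classical two-level screening effects: for each factor and each CMA,
#' `effect = mean(response at high level) - mean(response at low level)`
#' over the non-centre rows.  Centre rows never enter the contrasts.  An
#' unbalanced factor column (unequal high/low counts, as happens when a
#' printed plan is ingested as-is) is computed from the level means with a
#' warning.
#'
#' @param data A [response_table()] over a two-level (plus centre) design.
#' @param factors Factors to estimate; default all design factors.
#' @return Data frame of class `"pb_effects"` with columns `factor`,
#'   `cma`, `effect`, `mean_high`, `mean_low`, `n_high`, `n_low`.
#' @export
pb_effects <- function(data, factors = data$design$factors) {
  stopifnot(inherits(data, "response_table"))
  factors <- as_factor_list(factors)
  keep <- !data$design$runs$is_center
  out <- list()
  for (f in factors) {
    x <- data$design$runs[[f$name]][keep]
    hi <- x >= (f$low + f$high) / 2 + (f$high - f$low) / 4
    lo <- x <= (f$low + f$high) / 2 - (f$high - f$low) / 4
    if (any(!hi & !lo))
      stop("factor '", f$name, "' has non-centre rows at intermediate ",
           "levels; two-level settings required", call. = FALSE)
    if (sum(hi) != sum(lo))
      warning("factor '", f$name, "' is unbalanced (", sum(hi), " high vs ",
              sum(lo), " low); effect computed from level means")
    for (cma in names(data$responses)) {
      y <- data$responses[[cma]][keep]
      out[[length(out) + 1L]] <- data.frame(
        factor = f$name, cma = cma,
        effect = mean(y[hi]) - mean(y[lo]),
        mean_high = mean(y[hi]), mean_low = mean(y[lo]),
        n_high = sum(hi), n_low = sum(lo))
    }
  }
  structure(do.call(rbind, out), class = c("pb_effects", "data.frame"))
}

#' Significance tests for Plackett--Burman effects
#'
#' Attaches a standard error, t statistic and two-sided p-value to each
#' effect, using one of three error estimates:
#' \describe{
#'   \item{`regression_residual`}{residual mean square of the
#'     main-effects-only regression on the two-level rows (default; works
#'     for any printed plan, standard geometry or not).}
#'   \item{`dummy_columns`}{root-mean-square of the effects of the
#'     unassigned PB columns (requires a design generated by
#'     [plackett_burman()] with spare columns).}
#'   \item{`center_points`}{pure error from the centre-point replicates.}
#' }
#'
#' @param data The [response_table()] the effects came from.
#' @param effects A `"pb_effects"` data frame.
#' @param method Error-estimation method (see above).
#' @param alpha Significance level (default 0.05).
#' @return The effects data frame with columns `se`, `t`, `df`, `p_value`,
#'   `significant` added.
#' @export
pb_significance <- function(data, effects,
                            method = c("regression_residual", "dummy_columns",
                                       "center_points"),
                            alpha = 0.05) {
  stopifnot(inherits(data, "response_table"),
            inherits(effects, "pb_effects"))
  method <- match.arg(method)
  keep <- !data$design$runs$is_center
  n <- sum(keep)
  fac_names <- unique(effects$factor)
  k <- length(fac_names)

  # coded +/-1 matrix for the tested factors over the two-level rows
  Xf <- vapply(fac_names, function(nm) {
    f <- data$design$factors[[nm]]
    sign(code_levels(f, data$design$runs[[nm]][keep]))
  }, numeric(n))

  res <- effects
  res$se <- res$t <- res$df <- res$p_value <- NA_real_

  for (cma in unique(effects$cma)) {
    y <- data$responses[[cma]][keep]
    sel <- res$cma == cma
    if (method == "regression_residual") {
      X <- cbind(1, Xf)
      df_err <- n - ncol(X)
      if (df_err < 1L)
        stop("regression_residual: no residual degrees of freedom",
             call. = FALSE)
      fit <- lm.fit(X, y)
      mse <- sum(fit$residuals^2) / df_err
      # a response exactly reproduced by the main effects leaves only
      # floating-point noise as "error"; treat it as zero variance
      if (mse < (1e-8 * (mean(abs(y)) + 1))^2) mse <- 0
      XtXinv <- solve(crossprod(X))
      # effect = 2 * slope, so SE(effect) = 2 * SE(slope)
      se_eff <- 2 * sqrt(mse * diag(XtXinv)[-1L])
      res$se[sel] <- se_eff[match(res$factor[sel], fac_names)]
      res$df[sel] <- df_err
    } else if (method == "dummy_columns") {
      dummy <- attr(data$design, "dummy_coded")
      if (is.null(dummy) || ncol(dummy) < 1L)
        stop("dummy_columns: the design carries no unassigned PB columns",
             call. = FALSE)
      d_eff <- apply(dummy, 2L, function(col)
        mean(y[col > 0]) - mean(y[col < 0]))
      res$se[sel] <- sqrt(mean(d_eff^2))
      res$df[sel] <- ncol(dummy)
    } else {
      yc <- data$responses[[cma]][data$design$runs$is_center]
      if (length(yc) < 2L)
        stop("center_points: need at least two centre replicates",
             call. = FALSE)
      s2 <- stats::var(yc)
      nh <- res$n_high[sel]; nl <- res$n_low[sel]
      res$se[sel] <- sqrt(s2 * (1 / nh + 1 / nl))
      res$df[sel] <- length(yc) - 1L
    }
  }
  res$t <- ifelse(res$se == 0,
                  ifelse(res$effect == 0, 0, sign(res$effect) * Inf),
                  res$effect / res$se)
  res$p_value <- 2 * stats::pt(abs(res$t), res$df, lower.tail = FALSE)
  res$significant <- res$p_value < alpha
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  res
}
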