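#' Distribution of a CMP for Monte Carlo propagation
#'
#' Describes how a method parameter varies in routine use.  `uniform` over
#' an operable interval is the least-assumption default; `normal`
#' (mean, sd) and `triangular` (min, mode, max) are available.  Draws are
#' truncated to the factor's range by rejection.
#'
#' @param kind `"uniform"`, `"normal"` or `"triangular"`.
#' @param ... Parameters: `min`/`max` (uniform, triangular), `mean`/`sd`
#'   (normal), `mode` (triangular).
#' @return An `"mc_distribution"`.
#' @export
mc_distribution <- function(kind = c("uniform", "normal", "triangular"), ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  need <- switch(kind, uniform = c("min", "max"), normal = c("mean", "sd"),
                 triangular = c("min", "mode", "max"))
  miss <- setdiff(need, names(pars))
  if (length(miss))
    stop(kind, " distribution needs parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (kind == "triangular" &&
      !(pars$min <= pars$mode && pars$mode <= pars$max))
    stop("triangular: need min <= mode <= max", call. = FALSE)
  structure(c(list(kind = kind), pars[need]), class = "mc_distribution")
}

draw_mc <- function(dist, n) {
  switch(dist$kind,
         uniform = stats::runif(n, dist$min, dist$max),
         normal = stats::rnorm(n, dist$mean, dist$sd),
         triangular = {
           u <- stats::runif(n)
           fc <- (dist$mode - dist$min) / (dist$max - dist$min)
           ifelse(u < fc,
                  dist$min + sqrt(u * (dist$max - dist$min) *
                                    (dist$mode - dist$min)),
                  dist$max - sqrt((1 - u) * (dist$max - dist$min) *
                                    (dist$max - dist$mode)))
         })
}

#' Monte Carlo settings for capability simulation
#'
#' @param distributions Named list of [mc_distribution()] objects, one per
#'   factor of the models being propagated.
#' @param n_draws Number of draws (at least 100; default 100000).
#' @param seed Integer seed; identical seeds give identical results.
#' @param include_residual_noise Add N(0, sqrt(MSE)) model error to each
#'   prediction (transmission of model uncertainty); default TRUE.
#' @param truncate Clip draws to each factor's range by rejection
#'   (default TRUE); disable for untruncated analytic comparisons.
#' @param n_bins Histogram bins per CMA (default 30).
#' @return An `"mc_config"`.
#' @export
mc_config <- function(distributions, n_draws = 1e5L, seed = 1L,
                      include_residual_noise = TRUE, truncate = TRUE,
                      n_bins = 30L) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 100L) stop("n_draws must be at least 100", call. = FALSE)
  if (!all(vapply(distributions, inherits, logical(1), "mc_distribution")))
    stop("'distributions' must be mc_distribution objects", call. = FALSE)
  structure(list(distributions = distributions, n_draws = n_draws,
                 seed = as.integer(seed),
                 include_residual_noise = isTRUE(include_residual_noise),
                 truncate = isTRUE(truncate), n_bins = as.integer(n_bins)),
            class = "mc_config")
}

#' Process capability index against a specification window
#'
#' Two-sided: `min((USL - mean)/(3 sd), (mean - LSL)/(3 sd))`; one-sided
#' windows use the single finite term.  `Cpk = 1` means the nearer limit
#' sits three standard deviations from the mean; 1.33 is the usual
#' "capable" floor.
#'
#' @param mean,sd Summary of the response distribution (`sd > 0`).
#' @param window A [spec_window()].
#' @return The capability index (can be negative when the mean is outside
#'   the window).
#' @export
cpk <- function(mean, sd, window) {
  stopifnot(inherits(window, "spec_window"))
  if (sd <= 0) stop("sd must be strictly positive", call. = FALSE)
  terms <- c(if (!is.na(window$usl)) (window$usl - mean) / (3 * sd),
             if (!is.na(window$lsl)) (mean - window$lsl) / (3 * sd))
  min(terms)
}

#' Propagate CMP variation through the fitted models
#'
#' Draws factor vectors i.i.d. from the configured distributions, predicts
#' every CMA, optionally adds residual model noise, and summarizes each CMA
#' against its specification window: mean, SD, Cpk, fraction out of spec
#' and a fixed-width histogram.  A degenerate zero-SD sample reports
#' `Cpk = Inf` (all mass at one point; out-of-spec fraction still tells
#' you whether that point conforms).
#'
#' @param models Named list of `"aqbd_fit"` objects.
#' @param windows List of [spec_window()] objects (one per CMA to assess).
#' @param config An [mc_config()].
#' @return An `"mc_result"`: `summary` data frame (cma, mean, sd, cpk,
#'   frac_out), `histograms` data frame (cma, bin_left, bin_right, count),
#'   `draws_summary` of the factor draws, `n_draws`, `seed`.
#' @export
simulate_capability <- function(models, windows, config) {
  stopifnot(inherits(config, "mc_config"))
  cmas <- vapply(windows, `[[`, character(1), "cma")
  missing_models <- setdiff(cmas, names(models))
  if (length(missing_models))
    stop("no model supplied for CMA(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  fac_names <- names(config$distributions)
  mod1 <- models[[cmas[1L]]]
  bad <- setdiff(names(mod1$factors), fac_names)
  if (length(bad))
    stop("no distribution configured for factor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  with_seed(config$seed, {
    n <- config$n_draws
    draws <- as.data.frame(lapply(fac_names, function(nm) {
      d <- draw_mc(config$distributions[[nm]], n)
      if (config$truncate) {
        f <- mod1$factors[[nm]]
        if (!is.null(f)) {
          bad_i <- which(d < f$low | d > f$high)
          tries <- 0L
          while (length(bad_i) && tries < 1000L) {
            d[bad_i] <- draw_mc(config$distributions[[nm]], length(bad_i))
            bad_i <- bad_i[d[bad_i] < f$low | d[bad_i] > f$high]
            tries <- tries + 1L
          }
          if (length(bad_i))
            stop("distribution for '", nm,
                 "' has negligible mass inside the factor range", call. = FALSE)
        }
      }
      d
    }))
    names(draws) <- fac_names

    summ <- vector("list", length(windows))
    hists <- vector("list", length(windows))
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      m <- models[[w$cma]]
      y <- predict(m, draws)
      if (config$include_residual_noise && m$stats$mse > 0)
        y <- y + stats::rnorm(n, 0, sqrt(m$stats$mse))
      mu <- mean(y); s <- stats::sd(y)
      ck <- if (s > 0) cpk(mu, s, w) else Inf
      summ[[i]] <- data.frame(cma = w$cma, mean = mu, sd = s, cpk = ck,
                              frac_out = mean(!in_window(y, w)))
      rng <- range(y)
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      brk <- seq(rng[1], rng[2], length.out = config$n_bins + 1L)
      cnt <- tabulate(pmin(pmax(findInterval(y, brk, rightmost.closed = TRUE),
                                1L), config$n_bins), nbins = config$n_bins)
      hists[[i]] <- data.frame(cma = w$cma, bin_left = brk[-length(brk)],
                               bin_right = brk[-1L], count = cnt)
    }
    structure(list(summary = do.call(rbind, summ),
                   histograms = do.call(rbind, hists),
                   draws_summary = data.frame(
                     factor = fac_names,
                     mean = vapply(draws, mean, numeric(1)),
                     sd = vapply(draws, stats::sd, numeric(1))),
                   n_draws = n, seed = config$seed),
              class = "mc_result")
  })
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo capability, %d draws (seed %d)\n", x$n_draws,
              x$seed))
  print(transform(x$summary, mean = signif(mean, 6), sd = signif(sd, 4),
                  cpk = round(cpk, 3)))
  invisible(x)
}
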