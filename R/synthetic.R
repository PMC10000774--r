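#' Ground truth for the synthetic chromatographic generator
#'
#' Defines a three-analyte reversed-phase separation in the
#' linear-solvent-strength style: each analyte's log retention factor
#' `ln k` is linear in the organic-modifier fraction, mobile-phase pH and
#' column temperature, retention time is `t0 * (1 + k)`, and plate counts
#' follow a linear efficiency model.  Defaults emulate the curcuminoid
#' assay this package grew out of: bisdemethoxycurcumin elutes first,
#' then demethoxycurcumin, then curcumin; pH raises retention while
#' acetonitrile fraction and temperature lower it; at the optimum
#' (54% ACN, pH 2.7, 33 degC) all three peaks sit between 2 and 7 minutes
#' with plate counts above 2000.  The elution order and every coefficient
#' are overridable.
#'
#' @param seed Integer seed recorded in the truth and used as the default
#'   downstream; the default truth itself is deterministic.
#' @param overrides Named list replacing any top-level element (e.g.
#'   `list(noise = list(rt = 0, rs = 0, tp = 0))` for noise-free runs, or
#'   a modified `analytes` table to change the elution order).
#' @return A `"synthetic_truth"` object.
#' @export
make_truth <- function(seed = 1L, overrides = list()) {
  truth <- list(
    t0 = 1.0,                       # column dead time, minutes
    reference = c(ACN = 54, pH = 2.7, Temperature = 33),
    # per-analyte ln k at the reference point and sensitivities:
    # per unit ACN fraction (negative: stronger eluent, less retention),
    # per pH unit (positive), per degC (negative)
    analytes = data.frame(
      name = c("BDMCMN", "DMCMN", "CMN"),
      lnk_ref = log(c(3.88, 4.37, 4.92)),
      beta_phi = c(-5, -5, -5),
      beta_ph = c(0.15, 0.15, 0.15),
      beta_temp = c(-0.01, -0.01, -0.01),
      n_ref = c(4800, 3950, 4900),
      stringsAsFactors = FALSE),
    # plate model: N = n_ref + n_temp*(T - Tref) + n_phi*(%ACN - ACNref)
    n_temp = 15, n_phi = -10,
    # calibration truth, detector area per (ug/mL), near realistic scales
    calibration = data.frame(
      name = c("BDMCMN", "DMCMN", "CMN"),
      slope = c(1077486.9, 3457396, 2222250),
      intercept = c(-133404.51, -414324.79, 499471.1),
      stringsAsFactors = FALSE),
    # typical assay content, mg/g, used for degradation peak areas
    content = c(BDMCMN = 3.78, DMCMN = 15.6, CMN = 27.15),
    # relative (multiplicative) noise SD per CMA family
    noise = list(rt = 0.01, rs = 0.02, tp = 0.03),
    seed = as.integer(seed))
  for (nm in names(overrides)) {
    if (is.list(truth[[nm]]) && is.list(overrides[[nm]]) &&
        !is.data.frame(truth[[nm]]))
      truth[[nm]] <- utils::modifyList(truth[[nm]], overrides[[nm]])
    else truth[[nm]] <- overrides[[nm]]
  }
  if (truth$t0 <= 0) stop("dead time t0 must be positive", call. = FALSE)
  if (any(unlist(truth$noise) < 0))
    stop("noise SDs must be non-negative", call. = FALSE)
  structure(truth, class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic separation truth:", nrow(x$analytes), "analytes, t0 =",
      x$t0, "min\n")
  print(x$analytes)
  invisible(x)
}

# ln k, retention time (min) and plate count for every analyte at the
# given natural-unit settings (vectors recycled row-wise).
truth_predict <- function(truth, acn, ph, temp) {
  ref <- truth$reference
  out <- lapply(seq_len(nrow(truth$analytes)), function(i) {
    a <- truth$analytes[i, ]
    lnk <- a$lnk_ref +
      a$beta_phi * (acn - ref[["ACN"]]) / 100 +
      a$beta_ph * (ph - ref[["pH"]]) +
      a$beta_temp * (temp - ref[["Temperature"]])
    k <- exp(lnk)
    n <- a$n_ref + truth$n_temp * (temp - ref[["Temperature"]]) +
      truth$n_phi * (acn - ref[["ACN"]])
    list(name = a$name, k = k, rt = truth$t0 * (1 + k), n = n)
  })
  names(out) <- truth$analytes$name
  out
}

# Fundamental resolution relation between an adjacent peak pair.
resolution_pair <- function(k1, k2, n1, n2) {
  ka <- pmin(k1, k2); kb <- pmax(k1, k2)
  alpha <- kb / ka
  nbar <- (n1 + n2) / 2
  (sqrt(nbar) / 4) * ((alpha - 1) / alpha) * (kb / (1 + kb))
}

#' Simulate chromatographic responses over a design
#'
#' Evaluates the truth's retention and plate models at every design row
#' and derives the eight standard CMAs: `RS1` (curcumin /
#' demethoxycurcumin resolution), `RS2` (demethoxy / bisdemethoxy),
#' retention times `RT_CMN`, `RT_DMCMN`, `RT_BDMCMN` and plate counts
#' `TP_CMN`, `TP_DMCMN`, `TP_BDMCMN`.  Resolutions come from the
#' fundamental relation `Rs = (sqrt(N)/4) ((alpha-1)/alpha) (k2/(1+k2))`.
#' Each value then receives multiplicative Gaussian noise at the truth's
#' relative SD for its CMA family.
#'
#' @param truth A [make_truth()] object.
#' @param design An `"aqbd_design"` whose factors include `ACN`, `pH` and
#'   `Temperature` (extra factors, e.g. buffer concentration, are inert).
#' @param seed Integer seed; defaults to the truth's seed.
#' @return A [response_table()].
#' @export
simulate_responses <- function(truth, design, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "aqbd_design"))
  need <- c("ACN", "pH", "Temperature")
  bad <- setdiff(need, names(design$factors))
  if (length(bad))
    stop("design lacks required factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(truth$analytes) < 2L)
    stop("at least two analytes are needed for resolutions", call. = FALSE)
  runs <- design$runs
  pr <- truth_predict(truth, runs$ACN, runs$pH, runs$Temperature)
  n <- nrow(runs)

  resp <- data.frame(
    RS1 = resolution_pair(pr$CMN$k, pr$DMCMN$k, pr$CMN$n, pr$DMCMN$n),
    RS2 = resolution_pair(pr$DMCMN$k, pr$BDMCMN$k, pr$DMCMN$n, pr$BDMCMN$n),
    RT_CMN = pr$CMN$rt, RT_DMCMN = pr$DMCMN$rt, RT_BDMCMN = pr$BDMCMN$rt,
    TP_CMN = pr$CMN$n, TP_DMCMN = pr$DMCMN$n, TP_BDMCMN = pr$BDMCMN$n)

  with_seed(seed, {
    rel <- c(RS1 = truth$noise$rs, RS2 = truth$noise$rs,
             RT_CMN = truth$noise$rt, RT_DMCMN = truth$noise$rt,
             RT_BDMCMN = truth$noise$rt, TP_CMN = truth$noise$tp,
             TP_DMCMN = truth$noise$tp, TP_BDMCMN = truth$noise$tp)
    for (nm in names(resp))
      if (rel[[nm]] > 0)
        resp[[nm]] <- resp[[nm]] * (1 + stats::rnorm(n, 0, rel[[nm]]))
    response_table(design, resp)
  })
}

#' Simulate a calibration series for one analyte
#'
#' `response = slope * concentration + intercept + noise`, with noise SD
#' equal to `relative_noise` times the noise-free signal at each level.
#'
#' @param truth A [make_truth()] object.
#' @param analyte One of the truth's analyte names.
#' @param levels Concentrations in ug/mL (positive).
#' @param relative_noise Relative response noise SD (default 0.005).
#' @param seed Integer seed; defaults to the truth's seed.
#' @return Data frame with columns `analyte`, `concentration`, `response`.
#' @export
simulate_calibration <- function(truth, analyte, levels,
                                 relative_noise = 0.005, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cal <- truth$calibration[truth$calibration$name == analyte, ]
  if (nrow(cal) != 1L)
    stop("unknown analyte '", analyte, "'", call. = FALSE)
  levels <- as.numeric(levels)
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  mu <- cal$slope * levels + cal$intercept
  with_seed(seed, {
    y <- mu + stats::rnorm(length(levels), 0,
                           relative_noise * abs(cal$slope * levels))
    data.frame(analyte = analyte, concentration = levels, response = y)
  })
}

#' Simulate a forced-degradation experiment as pre/post peak tables
#'
#' Builds a reference chromatogram (the three parent peaks at the
#' optimum-condition retention times, areas proportional to typical
#' content), then a stressed table whose parent areas are reduced so that
#' exactly `extent` of the total parent area is lost, with seeded per-peak
#' jitter in how the loss is shared.  The lost area reappears as
#' `n_degradants` new peaks, all eluting before the earliest parent --
#' the behaviour expected of the more polar degradation products.
#'
#' @param truth A [make_truth()] object.
#' @param condition Stress label (`"acid"`, `"base"`, `"thermal"`,
#'   `"sunlight"`, `"oxidative"`, `"uv"`, ...).
#' @param extent Total fraction of parent area lost, in `[0, 1]`.
#' @param n_degradants Number of degradant peaks (ignored at extent 0).
#' @param seed Integer seed; defaults to the truth's seed.
#' @return List with `reference` and `stressed` [peak_table()] objects.
#' @export
simulate_degradation <- function(truth, condition, extent, n_degradants = 2L,
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (extent < 0 || extent > 1)
    stop("extent must lie in [0, 1]", call. = FALSE)
  ref <- truth$reference
  pr <- truth_predict(truth, ref[["ACN"]], ref[["pH"]], ref[["Temperature"]])
  rts <- vapply(pr, `[[`, numeric(1), "rt")
  areas <- 1e5 * as.numeric(truth$content[names(rts)])
  ord <- order(rts)
  reference <- peak_table("none", rts[ord], areas[ord],
                          rep(TRUE, length(rts)))
  if (extent == 0)
    return(list(reference = reference,
                stressed = peak_table(condition, rts[ord], areas[ord],
                                      rep(TRUE, length(rts)))))

  with_seed(seed, {
    a <- reference$area
    total_lost <- extent * sum(a)
    w <- stats::runif(length(a), 0.8, 1.2)
    lost <- total_lost * (w * a) / sum(w * a)
    # redistribute any overdraw so no peak loses more than it has
    repeat {
      over <- lost > a
      if (!any(over)) break
      excess <- sum(lost[over] - a[over])
      lost[over] <- a[over]
      room <- a[!over] - lost[!over]
      lost[!over] <- lost[!over] + excess * room / sum(room)
    }
    stressed_parent_area <- a - lost

    n_deg <- max(1L, as.integer(n_degradants))
    min_rt <- min(reference$rt)
    deg_rt <- sort(stats::runif(n_deg, 1.2, max(min_rt - 0.3, 1.3)))
    while (any(diff(deg_rt) <= 0))       # enforce strict ordering
      deg_rt <- sort(deg_rt + cumsum(rep(1e-6, n_deg)))
    dw <- stats::runif(n_deg, 0.5, 1.5)
    deg_area <- total_lost * dw / sum(dw)

    stressed <- peak_table(condition,
                           c(deg_rt, reference$rt),
                           c(deg_area, stressed_parent_area),
                           c(rep(FALSE, n_deg), rep(TRUE, nrow(reference))))
    list(reference = reference, stressed = stressed)
  })
}
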