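noise_free <- function() make_truth(overrides = list(
  noise = list(rt = 0, rs = 0, tp = 0)))

test_that("the default truth reproduces the intended optimum-condition chromatogram", {
  truth <- make_truth()
  pr <- chromaqbd:::truth_predict(truth, 54, 2.7, 33)
  rts <- vapply(pr, `[[`, numeric(1), "rt")
  expect_true(all(rts > 2 & rts < 7))
  expect_true(all(vapply(pr, `[[`, numeric(1), "n") > 2000))
  # elution order: bisdemethoxycurcumin first, curcumin last
  expect_lt(rts[["BDMCMN"]], rts[["DMCMN"]])
  expect_lt(rts[["DMCMN"]], rts[["CMN"]])
  expect_identical(make_truth(seed = 5), make_truth(seed = 5))
})

test_that("qualitative factor effects match the intended chromatography", {
  truth <- noise_free()
  d <- full_factorial(std_factors(), seed = 1)
  rt <- simulate_responses(truth, d)
  fit <- fit_response_model(rt, "RT_CMN")
  expect_gt(coef(fit)[["pH"]], 0)           # pH raises retention
  expect_lt(coef(fit)[["ACN"]], 0)          # organic modifier lowers it
  expect_lt(coef(fit)[["Temperature"]], 0)  # temperature lowers it
  # elution order holds at every design point, not just the optimum
  expect_true(all(rt$responses$RT_BDMCMN < rt$responses$RT_DMCMN))
  expect_true(all(rt$responses$RT_DMCMN < rt$responses$RT_CMN))
})

test_that("simulation is deterministic per seed and repeats identical rows without noise", {
  truth <- make_truth()
  d <- full_factorial(std_factors(), n_center = 3, n_replicates = 2, seed = 2)
  expect_identical(simulate_responses(truth, d, seed = 4),
                   simulate_responses(truth, d, seed = 4))
  nf <- simulate_responses(noise_free(), d, seed = 4)
  key <- apply(d$coded, 1, paste, collapse = "/")
  for (cm in names(nf$responses))
    expect_true(all(tapply(nf$responses[[cm]], key, function(v)
      diff(range(v))) == 0))
})

test_that("retention responds only to factors with nonzero coefficients", {
  truth <- noise_free()
  truth$analytes$beta_phi[truth$analytes$name == "CMN"] <- 0
  d <- full_factorial(list(cmp_factor("ACN", 50, 70, "percent"),
                           cmp_factor("pH", 2.7, 2.8),
                           cmp_factor("Temperature", 33, 34)), seed = 1)
  rt <- simulate_responses(truth, d)
  # with beta_phi = 0 the curcumin RT ignores ACN: equal within pH/T groups
  key <- paste(d$runs$pH, d$runs$Temperature)
  spread <- tapply(rt$responses$RT_CMN, key, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("doubling plate counts scales resolution by sqrt(2)", {
  base <- noise_free()
  doubled <- noise_free()
  doubled$analytes$n_ref <- 2 * doubled$analytes$n_ref
  doubled$n_temp <- 2 * doubled$n_temp
  doubled$n_phi <- 2 * doubled$n_phi
  d <- full_factorial(std_factors(), n_center = 1, seed = 3)
  r1 <- simulate_responses(base, d)
  r2 <- simulate_responses(doubled, d)
  expect_equal(r2$responses$RS1, sqrt(2) * r1$responses$RS1,
               tolerance = 1e-12)
  expect_equal(r2$responses$RS2, sqrt(2) * r1$responses$RS2,
               tolerance = 1e-12)
})

test_that("noise-free simulations are reproduced end-to-end by a saturated model", {
  truth <- noise_free()
  d <- full_factorial(std_factors(), n_center = 3, seed = 5)
  rt <- simulate_responses(truth, d)
  terms <- default_terms(d, interactions = 3, curvature = TRUE)
  for (cm in c("RS1", "RT_CMN", "TP_BDMCMN")) {
    fit <- fit_response_model(rt, cm, terms = terms)
    expect_equal(fit$fitted, rt$responses[[cm]], tolerance = 1e-8)
  }
})

test_that("calibration refits recover the true slope at its standard error", {
  truth <- make_truth()
  levels <- c(0.76, 2, 5, 10, 15, 20, 24.5)
  slope_true <- truth$calibration$slope[truth$calibration$name == "CMN"]
  hits <- vapply(1:200, function(s) {
    sim <- simulate_calibration(truth, "CMN", levels, seed = s)
    # weighted fit matching the proportional-noise model, so the reported
    # standard error is the right yardstick
    fit <- stats::lm(response ~ concentration, data = sim,
                     weights = 1 / sim$concentration^2)
    se <- summary(fit)$coefficients["concentration", "Std. Error"]
    abs(coef(fit)[["concentration"]] - slope_true) <= 3 * se
  }, logical(1))
  # with 5 residual df the pivot is t5: P(|t| <= 3) ~ 0.97
  expect_gte(mean(hits), 0.9)
  ests <- vapply(1:50, function(s) {
    sim <- simulate_calibration(truth, "CMN", levels, seed = s)
    coef(stats::lm(response ~ concentration, data = sim))[["concentration"]]
  }, numeric(1))
  expect_lt(abs(mean(ests) - slope_true) / slope_true, 0.005)  # unbiased
  expect_error(simulate_calibration(truth, "XX", levels), "unknown analyte")
})

test_that("degradation tables round-trip the requested extent exactly", {
  truth <- make_truth()
  z <- simulate_degradation(truth, "none", extent = 0)
  expect_equal(z$reference, z$stressed)

  for (extent in c(0.0492, 0.2145, 0.492)) {
    sim <- simulate_degradation(truth, "acid", extent, n_degradants = 2,
                                seed = 11)
    res <- percent_degradation(sim$reference, sim$stressed)
    expect_equal(res$percent_degradation, 100 * extent, tolerance = 1e-9)
    # degradants all elute before the earliest parent peak
    expect_true(all(res$degradants$rt < min(sim$reference$rt)))
    expect_equal(nrow(res$degradants), 2L)
    # lost mass reappears in the degradant peaks
    expect_equal(sum(res$degradants$area),
                 extent * sum(sim$reference$area), tolerance = 1e-9)
  }
  expect_error(simulate_degradation(truth, "acid", 1.2), "extent")
})

test_that("make_truth validates physical parameters", {
  expect_error(make_truth(overrides = list(t0 = -1)), "positive")
  expect_error(make_truth(overrides = list(noise = list(rt = -0.1))),
               "non-negative")
})
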