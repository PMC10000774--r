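test_that("noise-free coded surfaces are recovered exactly", {
  d <- full_factorial(std_factors(), n_center = 3, seed = 1)
  beta <- c(pH = 0.4, ACN = -1.2, Temperature = 0.3, `pH:ACN` = 0.15,
            `pH:Temperature` = -0.05, `ACN:Temperature` = 0.08)
  data <- linear_response(d, b0 = 5, beta = beta)
  fit <- fit_response_model(data, "y")
  expect_equal(unname(coef(fit)), unname(c(5, beta)), tolerance = 1e-10)
  expect_lt(sum(fit$residuals^2), 1e-18)
  expect_equal(fit$stats$r_squared, 1)
  expect_equal(fit$stats$cv_percent, 0)
  # predictions at design points reproduce observations
  expect_equal(predict(fit, d$runs[names(d$factors)]),
               data$responses$y, tolerance = 1e-10)
})

test_that("coefficients equal the normal-equations solution on a toy design", {
  # 5-run, 2-factor irregular design (coded levels off the lattice are
  # allowed in the fit even though generators never emit them)
  fs <- list(cmp_factor("A", -1, 1), cmp_factor("B", -1, 1))
  coded <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1), c(0.5, -0.5))
  d <- chromaqbd:::new_design(chromaqbd:::as_factor_list(fs), coded,
                              rep(FALSE, 5), rep(1L, 5), 1:5)
  set.seed(3)
  y <- rnorm(5)
  data <- response_table(d, data.frame(y = y))
  fit <- fit_response_model(data, "y", terms = c("A", "B", "A:B"))
  X <- cbind(1, coded[, 1], coded[, 2], coded[, 1] * coded[, 2])
  expect_equal(unname(coef(fit)),
               as.numeric(solve(t(X) %*% X, t(X) %*% y)), tolerance = 1e-10)
})

test_that("intercept equals the response mean on orthogonal designs", {
  d <- full_factorial(std_factors(), n_center = 0, seed = 2)
  set.seed(8)
  data <- response_table(d, data.frame(y = rnorm(8, 10)))
  fit <- fit_response_model(data, "y")
  expect_equal(unname(coef(fit)[1]), mean(data$responses$y))
  # predict at the centre returns the intercept
  ctr <- data.frame(pH = 3, ACN = 60, Temperature = 30)
  expect_equal(predict(fit, ctr), unname(coef(fit)[1]))
})

test_that("unestimable terms raise an error naming them", {
  d <- full_factorial(std_factors(), n_center = 0, seed = 1)
  set.seed(1)
  data <- response_table(d, data.frame(y = rnorm(8)))
  # a duplicated column is rank deficient
  expect_error(fit_response_model(data, "y", terms = c("pH", "pH")), "pH")
  expect_error(default_terms(d, curvature = TRUE), "centre points")
})

test_that("ANOVA sums of squares decompose additively", {
  set.seed(21)
  for (rep in 1:10) {
    d <- full_factorial(std_factors(), n_center = sample(0:3, 1),
                        n_replicates = sample(1:2, 1), seed = rep)
    data <- response_table(d, data.frame(y = rnorm(nrow(d$runs), 20, 4)))
    fit <- fit_response_model(data, "y")
    an <- fit$anova
    g <- function(s) an$SS[an$source == s]
    expect_lt(abs(g("model") + g("residual") - g("total")) / g("total"), 1e-8)
    # term SS add up to the model SS on these orthogonal designs
    terms_ss <- sum(an$SS[!an$source %in%
                            c("model", "residual", "lack-of-fit",
                              "pure error", "total")])
    expect_equal(terms_ss, g("model"), tolerance = 1e-8)
    if (!fit$lof_omitted)
      expect_equal(g("lack-of-fit") + g("pure error"), g("residual"),
                   tolerance = 1e-8)
  }
})

test_that("pure error vanishes for identical replicates; lack of fit flagged without them", {
  d <- full_factorial(std_factors(), n_center = 0, n_replicates = 2, seed = 4)
  # identical responses within each replicate pair
  key <- apply(d$coded, 1, paste, collapse = "/")
  y <- as.numeric(factor(key)) * 1.5
  fit <- fit_response_model(response_table(d, data.frame(y = y)), "y")
  expect_equal(fit$anova$SS[fit$anova$source == "pure error"], 0)
  # no replicates at all: lack-of-fit row omitted, flag set
  d1 <- full_factorial(std_factors(), n_center = 0, seed = 4)
  fit1 <- fit_response_model(response_table(d1, data.frame(y = y[1:8])), "y")
  expect_true(fit1$lof_omitted)
  expect_false("lack-of-fit" %in% fit1$anova$source)
})

test_that("F-test p-values match a numerical-quadrature oracle", {
  d <- full_factorial(std_factors(), n_center = 2, n_replicates = 2, seed = 6)
  set.seed(6)
  data <- response_table(d, data.frame(
    y = 10 + 0.8 * d$coded[, "ACN"] + rnorm(nrow(d$runs), 0, 0.5)))
  fit <- fit_response_model(data, "y")
  an <- fit$anova
  df_res <- an$df[an$source == "residual"]
  f_density <- function(x, d1, d2)
    (gamma((d1 + d2) / 2) / (gamma(d1 / 2) * gamma(d2 / 2))) *
    (d1 / d2)^(d1 / 2) * x^(d1 / 2 - 1) * (1 + d1 * x / d2)^(-(d1 + d2) / 2)
  for (src in c("pH", "ACN", "Temperature")) {
    fobs <- an$F[an$source == src]
    p_quad <- integrate(f_density, fobs, Inf, d1 = 1, d2 = df_res,
                        rel.tol = 1e-10)$value
    expect_equal(an$p[an$source == src], p_quad, tolerance = 1e-6)
  }
})

test_that("curvature term captures centre-vs-factorial offset", {
  d <- full_factorial(std_factors(), n_center = 4, seed = 9)
  mu <- 5 + 0.5 * d$coded[, "pH"] + 2 * d$runs$is_center  # pure curvature
  data <- response_table(d, data.frame(y = mu))
  fit <- fit_response_model(data, "y",
                            terms = default_terms(d, curvature = TRUE))
  expect_equal(unname(coef(fit)["curvature"]), 2, tolerance = 1e-10)
  expect_lt(sum(fit$residuals^2), 1e-18)
})

test_that("shifting responses by a constant moves only the intercept", {
  d <- full_factorial(std_factors(), n_center = 2, seed = 10)
  set.seed(10)
  y <- rnorm(nrow(d$runs), 50, 3)
  f0 <- fit_response_model(response_table(d, data.frame(y = y)), "y")
  f1 <- fit_response_model(response_table(d, data.frame(y = y + 7)), "y")
  expect_equal(unname(coef(f1)[1] - coef(f0)[1]), 7, tolerance = 1e-10)
  expect_equal(coef(f1)[-1], coef(f0)[-1], tolerance = 1e-10)
  expect_equal(f1$anova$SS[f1$anova$source == "residual"],
               f0$anova$SS[f0$anova$source == "residual"], tolerance = 1e-8)
})

test_that("row permutation leaves the fit unchanged", {
  d <- full_factorial(std_factors(), n_center = 2, seed = 11)
  set.seed(11)
  y <- rnorm(nrow(d$runs), 5)
  perm <- sample(nrow(d$runs))
  dp <- d
  dp$runs <- dp$runs[perm, ]; rownames(dp$runs) <- NULL
  dp$coded <- dp$coded[perm, ]
  f0 <- fit_response_model(response_table(d, data.frame(y = y)), "y")
  f1 <- fit_response_model(response_table(dp, data.frame(y = y[perm])), "y")
  expect_equal(coef(f1), coef(f0), tolerance = 1e-10)
  expect_equal(f1$anova$SS, f0$anova$SS, tolerance = 1e-8)
})

test_that("predictions match direct polynomial evaluation at random points", {
  d <- full_factorial(std_factors(), n_center = 1, seed = 12)
  set.seed(12)
  data <- response_table(d, data.frame(y = rnorm(nrow(d$runs), 3)))
  fit <- fit_response_model(data, "y")
  pts <- data.frame(pH = runif(20, 2.5, 3.5), ACN = runif(20, 50, 70),
                    Temperature = runif(20, 25, 35))
  cf <- coef(fit)
  cd <- sapply(names(d$factors), function(nm)
    code_levels(d$factors[[nm]], pts[[nm]]))
  manual <- cf["(Intercept)"] + cf["pH"] * cd[, "pH"] +
    cf["ACN"] * cd[, "ACN"] + cf["Temperature"] * cd[, "Temperature"] +
    cf["pH:ACN"] * cd[, "pH"] * cd[, "ACN"] +
    cf["pH:Temperature"] * cd[, "pH"] * cd[, "Temperature"] +
    cf["ACN:Temperature"] * cd[, "ACN"] * cd[, "Temperature"]
  expect_equal(predict(fit, pts), unname(manual), tolerance = 1e-10)
  expect_error(predict(fit, pts[, 1:2]), "missing factor")
})

test_that("synthetic screening studies land in the expected CV and signal bands", {
  # triplicated 2^3 with 3 centre points (33 runs), generator defaults
  d <- full_factorial(std_factors(), n_center = 3, n_replicates = 3, seed = 1)
  truth <- make_truth()
  ok_cv <- ok_ap <- logical(0)
  for (s in 1:100) {
    rt <- simulate_responses(truth, d, seed = s)
    for (cm in c("RS1", "RT_CMN", "TP_DMCMN")) {
      fit <- fit_response_model(rt, cm)
      ok_cv <- c(ok_cv, fit$stats$cv_percent > 1 & fit$stats$cv_percent < 10)
      ok_ap <- c(ok_ap, fit$stats$adeq_precision > 4)
    }
  }
  expect_gte(mean(ok_cv), 0.95)
  expect_gte(mean(ok_ap), 0.95)
})

test_that("replicate averaging collapses to one row per design point", {
  d <- full_factorial(std_factors(), n_center = 2, n_replicates = 3, seed = 3)
  truth <- make_truth()
  rt <- simulate_responses(truth, d, seed = 3)
  av <- average_replicates(rt)
  expect_equal(nrow(av$responses), 9L)  # 8 factorial + 1 centre point
  key_full <- apply(rt$design$coded, 1, paste, collapse = "/")
  key_av <- apply(av$design$coded, 1, paste, collapse = "/")
  means <- tapply(rt$responses$RT_CMN, key_full, mean)
  expect_equal(av$responses$RT_CMN, as.numeric(means[key_av]), tolerance = 1e-12)
})
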