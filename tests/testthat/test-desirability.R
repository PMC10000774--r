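test_that("individual desirability ramps behave per goal type", {
  # one-sided acceptance rule "resolution > 1.2" as an at_least ramp whose
  # span ends at the observed maximum 2.12
  g_rs <- desirability_goal("RS1", "at_least", lower = 1.2, upper = 2.12)
  expect_equal(individual_desirability(2.12, g_rs), 1)
  expect_equal(individual_desirability(1.2, g_rs), 0)
  expect_equal(individual_desirability(3, g_rs), 1)

  g_max <- desirability_goal("y", "maximize", lower = 0, upper = 2)
  expect_equal(individual_desirability(1, g_max), 0.5)   # midpoint, linear
  expect_equal(individual_desirability(-1, g_max), 0)
  g_w <- desirability_goal("y", "maximize", lower = 0, upper = 2, weight = 2)
  expect_equal(individual_desirability(1, g_w), 0.25)

  g_in <- desirability_goal("y", "in_range", lower = 2, upper = 7)
  expect_equal(individual_desirability(c(1.9, 2, 5, 7, 7.1), g_in),
               c(0, 1, 1, 1, 0))

  g_min <- desirability_goal("y", "minimize", lower = 0, upper = 2)
  expect_equal(individual_desirability(c(-1, 1, 3), g_min), c(1, 0.5, 0))

  g_t <- desirability_goal("y", "target", lower = 0, upper = 10, target = 4)
  expect_equal(individual_desirability(c(0, 2, 4, 7, 10), g_t),
               c(0, 0.5, 1, 0.5, 0))

  # d always within [0, 1]
  set.seed(1)
  for (g in list(g_rs, g_max, g_in, g_min, g_t)) {
    d <- individual_desirability(runif(100, -20, 20), g)
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("overall desirability is a weighted geometric mean with veto", {
  expect_equal(overall_desirability(c(1, 1, 1)), 1)
  expect_equal(overall_desirability(c(0.9, 0, 1)), 0)
  expect_equal(overall_desirability(c(0.25, 1)), 0.5)
  # permutation invariance and equal-importance geometric mean
  set.seed(2)
  d <- runif(5)
  expect_equal(overall_desirability(d), prod(d)^(1 / 5))
  expect_equal(overall_desirability(d), overall_desirability(rev(d)))
  # importance weighting
  expect_equal(overall_desirability(c(0.25, 1), importance = c(2, 1)),
               (0.25^2)^(1 / 3))
  expect_error(overall_desirability(c(0.5), importance = -1), "positive")
})

# Shared setup: exact linear models on a unit square, target goals with a
# unique interior optimum at (0.37, 0.81).
unit_models <- function() {
  fs <- list(cmp_factor("A", 0, 1), cmp_factor("B", 0, 1))
  d <- full_factorial(fs, n_center = 0)
  yA <- d$runs$A; yB <- d$runs$B
  data <- response_table(d, data.frame(yA = yA, yB = yB))
  list(models = list(yA = fit_response_model(data, "yA", terms = c("A", "B")),
                     yB = fit_response_model(data, "yB", terms = c("A", "B"))),
       factors = fs)
}

test_that("optimizer matches the exhaustive grid oracle and finds a constructed optimum", {
  um <- unit_models()
  goals <- list(desirability_goal("yA", "target", 0, 1, target = 0.37),
                desirability_goal("yB", "target", 0, 1, target = 0.81))
  opt <- optimize_desirability(um$models, goals, um$factors, n_grid = 51)

  # oracle: direct evaluation of D over the same 51x51 grid
  ax <- seq(0, 1, length.out = 51)
  gr <- expand.grid(A = ax, B = ax)
  dA <- individual_desirability(gr$A, goals[[1]])
  dB <- individual_desirability(gr$B, goals[[2]])
  D_oracle <- ifelse(dA * dB == 0, 0, sqrt(dA * dB))
  expect_equal(opt$grid_D, max(D_oracle), tolerance = 1e-6)

  step <- 1 / 50
  expect_lte(abs(opt$grid_best[["A"]] - 0.37), step + 1e-9)
  expect_lte(abs(opt$grid_best[["B"]] - 0.81), step + 1e-9)
  # polish reaches the exact constructed optimizer
  expect_equal(unname(opt$best), c(0.37, 0.81), tolerance = 1e-5)
  expect_equal(opt$D, 1, tolerance = 1e-6)
})

test_that("monotone surfaces optimize to the boundary and weights preserve the argmax", {
  um <- unit_models()
  goals <- list(desirability_goal("yA", "maximize", 0, 1))
  opt <- optimize_desirability(um$models, goals, um$factors, n_grid = 21)
  expect_equal(unname(opt$best[["A"]]), 1, tolerance = 1e-6)

  goals2 <- list(desirability_goal("yA", "target", 0, 1, target = 0.37,
                                   importance = 2),
                 desirability_goal("yB", "target", 0, 1, target = 0.81,
                                   importance = 2))
  base <- list(desirability_goal("yA", "target", 0, 1, target = 0.37),
               desirability_goal("yB", "target", 0, 1, target = 0.81))
  o1 <- optimize_desirability(um$models, base, um$factors, n_grid = 21,
                              polish = FALSE)
  o2 <- optimize_desirability(um$models, goals2, um$factors, n_grid = 21,
                              polish = FALSE)
  expect_equal(o1$best, o2$best)  # doubling all importances: argmax unchanged
})

test_that("finer nested grids never lower the achievable maximum", {
  um <- unit_models()
  goals <- list(desirability_goal("yA", "target", 0, 1, target = 0.33),
                desirability_goal("yB", "target", 0, 1, target = 0.67))
  # 11-point grid nests inside the 21-point grid (both include 0, 0.1, ...)
  o_coarse <- optimize_desirability(um$models, goals, um$factors,
                                    n_grid = 11, polish = FALSE)
  o_fine <- optimize_desirability(um$models, goals, um$factors,
                                  n_grid = 21, polish = FALSE)
  expect_gte(o_fine$D, o_coarse$D)
})

test_that("an everywhere-infeasible goal set reports D = 0 rather than failing", {
  um <- unit_models()
  goals <- list(desirability_goal("yA", "in_range", lower = 5, upper = 6))
  opt <- optimize_desirability(um$models, goals, um$factors, n_grid = 11)
  expect_equal(opt$D, 0)
  expect_error(optimize_desirability(um$models,
                                     list(desirability_goal("zz", "maximize",
                                                            0, 1)),
                                     um$factors), "zz")
})
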