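#' Declare a Derringer--Suich desirability goal for one CMA
#'
#' @param cma Response name the goal applies to.
#' @param goal One of `"maximize"`, `"minimize"`, `"in_range"`,
#'   `"at_least"`, `"at_most"`, `"target"`.  `"at_least"`/`"at_most"` are
#'   one-sided ramps whose hard threshold is `lower` (resp. `upper`) --
#'   the natural reading of acceptance rules like "resolution > 1.2".
#' @param lower,upper Ramp limits; `lower < upper`.
#' @param target For `"target"` goals: the peak of the two-sided ramp,
#'   inside `[lower, upper]`.
#' @param weight Ramp exponent (1 = linear; >1 demands values close to the
#'   best end).
#' @param importance Relative weight in the overall desirability geometric
#'   mean.
#' @return A `"desirability_goal"` object.
#' @export
desirability_goal <- function(cma, goal = c("maximize", "minimize", "in_range",
                                            "at_least", "at_most", "target"),
                              lower, upper, target = NULL, weight = 1,
                              importance = 1) {
  goal <- match.arg(goal)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!(lower < upper)) stop("lower must be strictly below upper", call. = FALSE)
  if (goal == "target") {
    if (is.null(target)) stop("'target' goal needs a target value", call. = FALSE)
    if (target < lower || target > upper)
      stop("target must lie within [lower, upper]", call. = FALSE)
  }
  if (weight <= 0 || importance <= 0)
    stop("weight and importance must be positive", call. = FALSE)
  structure(list(cma = cma, goal = goal, lower = lower, upper = upper,
                 target = target, weight = weight, importance = importance),
            class = "desirability_goal")
}

#' Individual desirability of a response value
#'
#' Maps a response to `d` in `[0, 1]` under a [desirability_goal()]:
#' `maximize` (and `at_least`) ramp up from `lower` to `upper`;
#' `minimize` (and `at_most`) ramp down; `in_range` is the 0/1 indicator
#' of the window; `target` is a two-sided ramp peaking at the target.
#' Ramps are raised to the goal's `weight`.
#'
#' @param y Numeric vector of response values.
#' @param goal A [desirability_goal()].
#' @return Numeric vector of desirabilities in `[0, 1]`.
#' @export
individual_desirability <- function(y, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  lo <- goal$lower; hi <- goal$upper; w <- goal$weight
  up <- function(y) pmin(pmax((y - lo) / (hi - lo), 0), 1)^w
  down <- function(y) pmin(pmax((hi - y) / (hi - lo), 0), 1)^w
  switch(goal$goal,
         maximize = ,
         at_least = up(y),
         minimize = ,
         at_most = down(y),
         in_range = as.numeric(y >= lo & y <= hi),
         target = {
           tg <- goal$target
           d <- numeric(length(y))
           left <- y <= tg
           d[left] <- pmin(pmax((y[left] - lo) / (tg - lo), 0), 1)^w
           d[!left] <- pmin(pmax((hi - y[!left]) / (hi - tg), 0), 1)^w
           d
         })
}

#' Overall desirability: weighted geometric mean
#'
#' `D = (prod d_i^v_i)^(1/sum v_i)`.  With equal importances this is the
#' plain geometric mean; any zero desirability vetoes the whole point.
#'
#' @param d Numeric vector of individual desirabilities in `[0, 1]`.
#' @param importance Positive importance weights, recycled to `length(d)`.
#' @return Scalar `D` in `[0, 1]`.
#' @export
overall_desirability <- function(d, importance = rep(1, length(d))) {
  if (any(importance <= 0)) stop("importances must be positive", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("d values must lie in [0, 1]", call. = FALSE)
  importance <- rep_len(importance, length(d))
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}

#' Multi-response optimization over the factor space
#'
#' Evaluates the overall desirability of the model predictions on a full
#' factor grid, then (optionally) polishes the best grid cell by cyclic
#' coordinate descent.  Ties on the grid are broken by first point in scan
#' order (last factor varying fastest).
#'
#' @param models Named list of `"aqbd_fit"` objects, one per CMA appearing
#'   in `goals`.
#' @param goals List of [desirability_goal()] objects.
#' @param factors List of [cmp_factor()] objects defining the search box.
#' @param n_grid Grid resolution per factor (default 51).
#' @param polish Run the coordinate-descent refinement (default TRUE);
#'   convergence tolerance 1e-8 in coded units.
#' @param seed Unused by the deterministic search; accepted so callers can
#'   treat all optimizers uniformly.
#' @return List with `best` (named natural-units setting), `D`,
#'   `predictions` (per-CMA values at the optimum), `grid_best` and
#'   `grid_D` (pre-polish solution).
#' @export
optimize_desirability <- function(models, goals, factors, n_grid = 51L,
                                  polish = TRUE, seed = NULL) {
  factors <- as_factor_list(factors)
  cmas <- vapply(goals, `[[`, character(1), "cma")
  missing_models <- setdiff(cmas, names(models))
  if (length(missing_models))
    stop("no model supplied for CMA(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  importance <- vapply(goals, `[[`, numeric(1), "importance")

  axes <- lapply(factors, function(f) seq(f$low, f$high, length.out = n_grid))
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(axes)),
                                                         drop = FALSE]
  names(grid) <- names(factors)

  D_at <- function(points) {
    dmat <- vapply(seq_along(goals), function(i) {
      yhat <- predict(models[[cmas[i]]], points)
      individual_desirability(yhat, goals[[i]])
    }, numeric(nrow(points)))
    dmat <- matrix(dmat, nrow = nrow(points))
    apply(dmat, 1L, overall_desirability, importance = importance)
  }

  Dg <- D_at(grid)
  best_i <- which.max(Dg)          # first maximum in scan order
  grid_best <- as.numeric(grid[best_i, ])
  names(grid_best) <- names(factors)
  best <- grid_best
  D_best <- Dg[best_i]

  if (polish && D_best > 0) {
    tol <- 1e-8
    repeat {
      moved <- FALSE
      for (j in seq_along(factors)) {
        f <- factors[[j]]
        obj <- function(v) {
          pt <- as.data.frame(as.list(best))
          pt[[j]] <- v
          -D_at(pt)
        }
        op <- stats::optimize(obj, lower = f$low, upper = f$high,
                              tol = tol * (f$high - f$low) / 2)
        if (-op$objective > D_best + 1e-12) {
          if (abs(code_levels(f, op$minimum) - code_levels(f, best[j])) > tol)
            moved <- TRUE
          best[j] <- op$minimum
          D_best <- -op$objective
        }
      }
      if (!moved) break
    }
  }

  preds <- vapply(unique(cmas), function(cm)
    predict(models[[cm]], as.data.frame(as.list(best))), numeric(1))
  list(best = best, D = D_best, predictions = preds,
       grid_best = grid_best, grid_D = Dg[best_i])
}
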