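# Shared builders for the suite.  Everything is generated in code; no
# stored binary fixtures.

std_factors <- function() {
  list(cmp_factor("pH", 2.5, 3.5),
       cmp_factor("ACN", 50, 70, "percent"),
       cmp_factor("Temperature", 25, 35, "degC"))
}

# Build a response_table with y = b0 + X beta (+ noise) on a design.
linear_response <- function(design, b0, beta, sd = 0, seed = NULL) {
  X <- chromaqbd:::build_model_matrix(design, names(beta))
  mu <- as.numeric(X %*% c(b0, beta))
  if (sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mu <- mu + rnorm(length(mu), 0, sd)
  }
  response_table(design, data.frame(y = mu))
}

# Coefficient standard errors of an aqbd_fit (from its stored X and MSE).
fit_coef_se <- function(fit) {
  sqrt(fit$stats$mse * diag(solve(crossprod(fit$X))))
}

# Brute-force maximum-volume all-TRUE lattice box: exhaustive enumeration
# over every index-interval triple.  Independent of the package search.
brute_force_box_volume <- function(mask, axes) {
  d <- dim(mask)
  best <- 0
  for (l1 in 1:d[1]) for (h1 in l1:d[1])
    for (l2 in 1:d[2]) for (h2 in l2:d[2])
      for (l3 in 1:d[3]) for (h3 in l3:d[3]) {
        if (all(mask[l1:h1, l2:h2, l3:h3])) {
          v <- (axes[[1]][h1] - axes[[1]][l1]) *
            (axes[[2]][h2] - axes[[2]][l2]) *
            (axes[[3]][h3] - axes[[3]][l3])
          if (v > best) best <- v
        }
      }
  best
}
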