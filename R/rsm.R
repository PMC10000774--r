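#' Join a design to its measured responses
#'
#' Binds per-run measurements of the critical method attributes (CMAs) --
#' peak resolutions `RS1`/`RS2`, retention times `RT_*` in minutes,
#' theoretical plate counts `TP_*` -- to the design that produced them.
#'
#' @param design An `"aqbd_design"`.
#' @param responses Data frame with one numeric column per CMA and one row
#'   per design run.
#' @return An object of class `"response_table"`.
#' @export
response_table <- function(design, responses) {
  stopifnot(inherits(design, "aqbd_design"))
  responses <- as.data.frame(responses)
  if (nrow(responses) != nrow(design$runs))
    stop("responses have ", nrow(responses), " rows but the design has ",
         nrow(design$runs), call. = FALSE)
  for (nm in names(responses)) {
    v <- responses[[nm]]
    if (!is.numeric(v) || anyNA(v))
      stop("response '", nm, "' must be numeric without NAs", call. = FALSE)
    if (startsWith(nm, "RS") && any(v < 0))
      stop("resolution '", nm, "' must be non-negative", call. = FALSE)
    if ((startsWith(nm, "RT") || startsWith(nm, "TP")) && any(v <= 0))
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  structure(list(design = design, responses = responses),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("Response table: %d runs, CMAs: %s\n", nrow(x$responses),
              paste(names(x$responses), collapse = ", ")))
  invisible(x)
}

#' Average replicate runs of a response table
#'
#' Collapses rows sharing identical factor settings and replicate structure
#' to their mean response.  Row-level modelling is the default elsewhere
#' (it preserves pure-error degrees of freedom); this is the averaging
#' switch for users who prefer modelling on run means.
#'
#' @param data A [response_table()].
#' @return A [response_table()] with one row per distinct design point.
#' @export
average_replicates <- function(data) {
  stopifnot(inherits(data, "response_table"))
  key <- apply(cbind(data$design$coded, data$design$runs$is_center), 1L,
               paste, collapse = "/")
  keep <- !duplicated(key)
  resp <- as.data.frame(lapply(data$responses, function(v)
    as.numeric(tapply(v, key, mean)[key[keep]])))
  des <- data$design
  des$runs <- des$runs[keep, , drop = FALSE]
  des$runs$replicate <- 1L
  des$runs$run_order <- seq_len(sum(keep))
  rownames(des$runs) <- NULL
  des$coded <- des$coded[keep, , drop = FALSE]
  response_table(des, resp)
}

# Expand a character term specification into a coded model matrix.
# Terms are factor names, colon-separated interactions ("pH:ACN"), or the
# special term "curvature" (centred centre-point indicator).
build_model_matrix <- function(design, terms) {
  coded <- design$coded
  cols <- lapply(terms, function(tm) {
    if (identical(tm, "curvature"))
      return(as.numeric(design$runs$is_center))
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    bad <- setdiff(parts, colnames(coded))
    if (length(bad))
      stop("unknown factor(s) in term '", tm, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    apply(coded[, parts, drop = FALSE], 1L, prod)
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

#' Default polynomial term set for a two-level design
#'
#' Main effects plus all two-factor interactions.  Pure quadratic terms are
#' not estimable on a two-level design, so the "second order" surface used
#' here is the interaction model; the three-factor interaction and a
#' centre-point curvature test can be added explicitly.
#'
#' @param design An `"aqbd_design"`.
#' @param interactions Highest interaction order to include (default 2).
#' @param curvature Add the `"curvature"` term (requires centre points).
#' @return Character vector of term labels (intercept implied).
#' @export
default_terms <- function(design, interactions = 2L, curvature = FALSE) {
  nms <- names(design$factors)
  terms <- nms
  ord <- min(as.integer(interactions), length(nms))
  if (ord >= 2L)
    for (o in 2:ord)
      terms <- c(terms, utils::combn(nms, o, paste, collapse = ":"))
  if (curvature) {
    if (!any(design$runs$is_center))
      stop("curvature term requires centre points", call. = FALSE)
    terms <- c(terms, "curvature")
  }
  terms
}

#' Fit a coded-unit polynomial model for one CMA
#'
#' Ordinary least squares on the coded design.  Coefficients are in coded
#' units, so on an orthogonal two-level design each main-effect coefficient
#' is half the classical factor effect and the intercept is the grand mean.
#'
#' @param data A [response_table()].
#' @param cma Name of the response column to model.
#' @param terms Character vector of term labels; default
#'   [default_terms()] (main effects + two-factor interactions).
#' @return An `"aqbd_fit"` holding coefficients, fitted values, residuals,
#'   the ANOVA table (see [anova_table()]) and fit statistics (see
#'   [fit_statistics()]).
#' @examples
#' fs <- list(cmp_factor("pH", 2.5, 3.5), cmp_factor("ACN", 50, 70))
#' d <- full_factorial(fs, n_center = 3)
#' y <- 5 + 0.4 * d$coded[, "pH"] - 1.1 * d$coded[, "ACN"]
#' fit <- fit_response_model(response_table(d, data.frame(y = y)), "y")
#' coef(fit)
#' @export
fit_response_model <- function(data, cma, terms = NULL) {
  stopifnot(inherits(data, "response_table"))
  if (!cma %in% names(data$responses))
    stop("no response named '", cma, "' (have: ",
         paste(names(data$responses), collapse = ", "), ")", call. = FALSE)
  if (is.null(terms)) terms <- default_terms(data$design)
  X <- build_model_matrix(data$design, terms)
  y <- data$responses[[cma]]

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("model terms not estimable on this design: ",
         paste(dropped, collapse = ", "),
         " (rank ", qrX$rank, " < ", ncol(X), " columns)", call. = FALSE)
  }
  fit <- lm.fit(X, y)
  out <- structure(list(cma = cma, terms = terms,
                        coefficients = fit$coefficients,
                        fitted = as.numeric(fit$fitted.values),
                        residuals = as.numeric(fit$residuals),
                        effects = fit$effects, X = X, y = y,
                        factors = data$design$factors,
                        anova = NULL, stats = NULL, lof_omitted = NA),
                   class = "aqbd_fit")
  out <- anova_table(out, data)
  out$stats <- compute_fit_stats(out, zero_mean_ok = TRUE)
  out
}

#' @export
coef.aqbd_fit <- function(object, ...) object$coefficients

#' @export
print.aqbd_fit <- function(x, ...) {
  cat(sprintf("Response model for %s (%d runs, %d terms)\n", x$cma,
              length(x$y), length(x$terms)))
  print(round(x$coefficients, 6))
  cat(sprintf("R2 = %.4f, adj R2 = %.4f, CV%% = %.2f, adeq precision = %.2f\n",
              x$stats$r_squared, x$stats$adj_r_squared, x$stats$cv_percent,
              x$stats$adeq_precision))
  invisible(x)
}

#' ANOVA decomposition of a fitted response model
#'
#' Sequential (type I) sums of squares per term; on the orthogonal coded
#' designs generated by this package these equal partial sums of squares.
#' The residual is split into lack of fit and pure error using replicate
#' groups (rows with identical coded settings); with no replicates the
#' lack-of-fit row is omitted and `lof_omitted` is set.  Term and model
#' F-tests use the residual mean square; the lack-of-fit F uses pure error.
#'
#' @param model An `"aqbd_fit"`.
#' @param data The [response_table()] the model was fitted on.
#' @return The model with its `anova` data frame populated
#'   (columns source, SS, df, MS, F, p).
#' @export
anova_table <- function(model, data) {
  stopifnot(inherits(model, "aqbd_fit"), inherits(data, "response_table"))
  y <- model$y
  n <- length(y)
  p <- length(model$coefficients)
  ss_total <- sum((y - mean(y))^2)
  # squared QR effects after the intercept = sequential SS of the 1-df terms
  seq_ss <- model$effects[seq_len(p)][-1L]^2
  names(seq_ss) <- model$terms
  ss_model <- sum(seq_ss)
  df_model <- p - 1L
  ss_res <- sum(model$residuals^2)
  df_res <- n - p

  key <- apply(cbind(data$design$coded, data$design$runs$is_center), 1L,
               paste, collapse = "/")
  groups <- split(y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- n - length(groups)

  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  rows <- data.frame(source = "model", SS = ss_model, df = df_model,
                     MS = ss_model / df_model,
                     F = if (df_res > 0) (ss_model / df_model) / ms_res else NA_real_,
                     p = NA_real_, stringsAsFactors = FALSE)
  rows$p <- if (df_res > 0) stats::pf(rows$F, df_model, df_res,
                                      lower.tail = FALSE) else NA_real_
  term_rows <- data.frame(source = model$terms, SS = as.numeric(seq_ss),
                          df = 1L, MS = as.numeric(seq_ss),
                          F = if (df_res > 0) as.numeric(seq_ss) / ms_res else NA_real_,
                          p = NA_real_)
  if (df_res > 0)
    term_rows$p <- stats::pf(term_rows$F, 1L, df_res, lower.tail = FALSE)

  lof_omitted <- df_pe <= 0L
  lof_rows <- NULL
  if (!lof_omitted) {
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    ms_pe <- ss_pe / df_pe
    f_lof <- if (df_lof > 0 && ms_pe > 0) (ss_lof / df_lof) / ms_pe else NA_real_
    lof_rows <- data.frame(
      source = c("lack-of-fit", "pure error"),
      SS = c(max(ss_lof, 0), ss_pe), df = c(df_lof, df_pe),
      MS = c(if (df_lof > 0) ss_lof / df_lof else NA_real_, ms_pe),
      F = c(f_lof, NA_real_),
      p = c(if (is.finite(f_lof)) stats::pf(f_lof, df_lof, df_pe,
                                            lower.tail = FALSE) else NA_real_,
            NA_real_))
  }
  resid_row <- data.frame(source = "residual", SS = ss_res, df = df_res,
                          MS = ms_res, F = NA_real_, p = NA_real_)
  total_row <- data.frame(source = "total", SS = ss_total, df = n - 1L,
                          MS = NA_real_, F = NA_real_, p = NA_real_)
  model$anova <- rbind(rows, term_rows, resid_row, lof_rows, total_row)
  rownames(model$anova) <- NULL
  model$lof_omitted <- lof_omitted
  model
}

#' Summary fit statistics of a response model
#'
#' `R2 = 1 - SS_res/SS_total`; adjusted R2 uses the residual and total
#' mean squares; `CV% = 100 * sqrt(MSE) / mean(y)`; adequate precision is
#' the signal-to-noise ratio `(max(yhat) - min(yhat)) / sqrt(p * MSE / n)`
#' over the design points (values above 4 indicate a model usable for
#' navigating the design space).
#'
#' @param model An `"aqbd_fit"` with its ANOVA populated.
#' @param data The [response_table()] used for the fit.
#' @return List with `r_squared`, `adj_r_squared`, `cv_percent`,
#'   `adeq_precision`, `mse`.
#' @export
fit_statistics <- function(model, data) {
  compute_fit_stats(model, zero_mean_ok = FALSE)
}

compute_fit_stats <- function(model, zero_mean_ok = FALSE) {
  stopifnot(inherits(model, "aqbd_fit"))
  an <- model$anova
  if (is.null(an)) stop("ANOVA not populated; run anova_table() first",
                        call. = FALSE)
  ss_res <- an$SS[an$source == "residual"]
  df_res <- an$df[an$source == "residual"]
  ss_tot <- an$SS[an$source == "total"]
  df_tot <- an$df[an$source == "total"]
  y <- model$y
  n <- length(y)
  p <- length(model$coefficients)
  mse <- if (df_res > 0) ss_res / df_res else 0
  zero_mean <- abs(mean(y)) < .Machine$double.eps * max(1, max(abs(y)))
  if (zero_mean && !zero_mean_ok)
    stop("mean response is zero: CV% undefined", call. = FALSE)
  list(r_squared = 1 - ss_res / ss_tot,
       adj_r_squared = 1 - (ss_res / max(df_res, 1)) / (ss_tot / df_tot),
       cv_percent = if (zero_mean) NA_real_ else 100 * sqrt(mse) / mean(y),
       adeq_precision = (max(model$fitted) - min(model$fitted)) /
         sqrt(p * mse / n),
       mse = mse)
}

#' Predict CMA values at natural-unit factor settings
#'
#' @param object An `"aqbd_fit"`.
#' @param newdata Data frame with one column per model factor, in natural
#'   units.  Coding happens internally.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.aqbd_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  fac_names <- names(object$factors)
  bad <- setdiff(fac_names, names(newdata))
  if (length(bad))
    stop("newdata is missing factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(newdata), fac_names)
  if (length(extra))
    newdata <- newdata[fac_names]
  coded <- vapply(fac_names, function(nm)
    code_levels(object$factors[[nm]], newdata[[nm]]),
    numeric(nrow(newdata)))
  coded <- matrix(coded, nrow = nrow(newdata),
                  dimnames = list(NULL, fac_names))
  vals <- vapply(object$terms, function(tm) {
    if (identical(tm, "curvature")) return(rep(0, nrow(newdata)))
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    apply(coded[, parts, drop = FALSE], 1L, prod)
  }, numeric(nrow(newdata)))
  vals <- matrix(vals, nrow = nrow(newdata))
  as.numeric(cbind(1, vals) %*% object$coefficients)
}
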