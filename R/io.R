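#' Write / read a design as CSV
#'
#' One row per run; columns `run_order`, `is_center` (0/1), `replicate`,
#' then one natural-units column per factor.  Values are written at full
#' precision so the coded/natural round trip survives the file.
#'
#' @param design An `"aqbd_design"`.
#' @param path Output file path.
#' @return `write_design_csv`: the path, invisibly.  `read_design_csv`:
#'   an `"aqbd_design"` (factor ranges must be supplied, since a run list
#'   does not identify them when levels are off the endpoints).
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "aqbd_design"))
  df <- design$runs
  df$is_center <- as.integer(df$is_center)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param factors List of [cmp_factor()] objects naming the design's
#'   factor columns.
#' @export
read_design_csv <- function(path, factors) {
  factors <- as_factor_list(factors)
  df <- read_checked_csv(path, c("run_order", "is_center", "replicate",
                                 names(factors)))
  coded <- vapply(factors, function(f) code_levels(f, as.numeric(df[[f$name]])),
                  numeric(nrow(df)))
  new_design(factors, matrix(coded, ncol = length(factors)),
             df$is_center != 0, df$replicate, df$run_order)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("'", basename(path), "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Write / read a response table as CSV
#'
#' Design columns (as in [write_design_csv()]) followed by one column per
#' CMA.  Reading requires the factor definitions and treats every
#' non-design column as a response.
#'
#' @param data A [response_table()].
#' @param path File path.
#' @param factors List of [cmp_factor()] objects (reader only).
#' @return The path (writer, invisibly) or a [response_table()] (reader).
#' @export
write_response_csv <- function(data, path) {
  stopifnot(inherits(data, "response_table"))
  df <- data$design$runs
  df$is_center <- as.integer(df$is_center)
  df <- cbind(df, data$responses)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path, factors) {
  factors <- as_factor_list(factors)
  design_cols <- c("run_order", "is_center", "replicate", names(factors))
  df <- read_checked_csv(path, design_cols)
  cma_cols <- setdiff(names(df), design_cols)
  if (!length(cma_cols))
    stop("'", basename(path), "' has no response columns", call. = FALSE)
  coded <- vapply(factors, function(f) code_levels(f, as.numeric(df[[f$name]])),
                  numeric(nrow(df)))
  des <- new_design(factors, matrix(coded, ncol = length(factors)),
                    df$is_center != 0, df$replicate, df$run_order)
  response_table(des, df[cma_cols])
}

#' Export an ANOVA table as CSV
#'
#' @param model An `"aqbd_fit"`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_anova_csv <- function(model, path) {
  stopifnot(inherits(model, "aqbd_fit"))
  utils::write.csv(model$anova, path, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration from JSON
#'
#' The configuration declares the factors (name, low, high, units), the
#' CMA list, desirability goals, specification windows, Monte Carlo
#' settings and robustness settings.  Validation is eager: every goal and
#' window must reference a declared CMA, ranges must be ordered, and
#' seeds must be integers.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `"run_config"` list with elements `factors`
#'   (cmp_factor list), `cmas`, `goals`, `windows`, `monte_carlo`,
#'   `robustness`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading configurations requires the 'jsonlite' package",
         call. = FALSE)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  fail <- function(...) stop("config '", basename(path), "': ", ...,
                             call. = FALSE)
  if (is.null(cfg$factors)) fail("no 'factors' declared")
  fdf <- as.data.frame(cfg$factors)
  if (!all(c("name", "low", "high") %in% names(fdf)))
    fail("factors need 'name', 'low', 'high'")
  factors <- lapply(seq_len(nrow(fdf)), function(i)
    cmp_factor(fdf$name[i], fdf$low[i], fdf$high[i],
               if ("units" %in% names(fdf) && !is.na(fdf$units[i]))
                 fdf$units[i] else ""))
  factors <- as_factor_list(factors)

  cmas <- as.character(cfg$cmas %||% character())
  goals <- list()
  if (!is.null(cfg$goals)) {
    gdf <- as.data.frame(cfg$goals)
    for (i in seq_len(nrow(gdf))) {
      if (length(cmas) && !gdf$cma[i] %in% cmas)
        fail("goal ", i, " references undeclared CMA '", gdf$cma[i], "'")
      goals[[i]] <- desirability_goal(
        gdf$cma[i], gdf$goal[i], gdf$lower[i], gdf$upper[i],
        target = if ("target" %in% names(gdf) && !is.na(gdf$target[i]))
          gdf$target[i] else NULL,
        weight = if ("weight" %in% names(gdf) && !is.na(gdf$weight[i]))
          gdf$weight[i] else 1,
        importance = if ("importance" %in% names(gdf) &&
                         !is.na(gdf$importance[i])) gdf$importance[i] else 1)
    }
  }
  windows <- list()
  if (!is.null(cfg$windows)) {
    wdf <- as.data.frame(cfg$windows)
    for (i in seq_len(nrow(wdf))) {
      if (length(cmas) && !wdf$cma[i] %in% cmas)
        fail("window ", i, " references undeclared CMA '", wdf$cma[i], "'")
      windows[[i]] <- spec_window(wdf$cma[i],
                                  lsl = wdf$lsl[i] %||% NA_real_,
                                  usl = wdf$usl[i] %||% NA_real_)
    }
  }
  mc <- cfg$monte_carlo
  if (!is.null(mc$seed) && mc$seed != as.integer(mc$seed))
    fail("monte_carlo seed must be an integer")
  rob <- cfg$robustness
  structure(list(factors = factors, cmas = cmas, goals = goals,
                 windows = windows, monte_carlo = mc, robustness = rob),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plain-text summary report of pipeline results
#'
#' Writes the optimization, capability and robustness results in the
#' layout of a method-development report: per-CMA fit summaries, the
#' optimal conditions with predicted CMAs, the MODR box, per-CMA Cpk and
#' the robustness effect tests.
#'
#' @param results Named list; any of `models`, `optimum`, `modr`, `mc`,
#'   `robustness` are reported if present.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("AQbD method-development report")
  w("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(results$models)) {
    w("\n== Model fit summary ==")
    w("%-12s %10s %10s %8s %8s", "CMA", "R2", "adjR2", "CV%", "AdeqP")
    for (m in results$models)
      w("%-12s %10.4f %10.4f %8.2f %8.2f", m$cma, m$stats$r_squared,
        m$stats$adj_r_squared, m$stats$cv_percent, m$stats$adeq_precision)
  }
  if (!is.null(results$optimum)) {
    w("\n== Desirability optimum (D = %.4f) ==", results$optimum$D)
    for (nm in names(results$optimum$best))
      w("  %-12s %g", nm, results$optimum$best[[nm]])
    w("  predicted CMAs:")
    for (nm in names(results$optimum$predictions))
      w("  %-12s %g", nm, results$optimum$predictions[[nm]])
  }
  if (!is.null(results$modr)) {
    w("\n== Method Operable Design Region ==")
    for (i in seq_len(nrow(results$modr)))
      w("  %-12s [%g, %g]", results$modr$factor[i], results$modr$lower[i],
        results$modr$upper[i])
  }
  if (!is.null(results$mc)) {
    w("\n== Monte Carlo capability (%d draws) ==", results$mc$n_draws)
    s <- results$mc$summary
    w("%-12s %12s %12s %8s %10s", "CMA", "mean", "sd", "Cpk", "frac.out")
    for (i in seq_len(nrow(s)))
      w("%-12s %12.4f %12.4f %8.3f %10.2e", s$cma[i], s$mean[i], s$sd[i],
        s$cpk[i], s$frac_out[i])
  }
  if (!is.null(results$robustness)) {
    w("\n== Robustness effects ==")
    r <- results$robustness
    w("%-12s %-12s %12s %10s %10s", "factor", "CMA", "effect", "t", "p")
    for (i in seq_len(nrow(r)))
      w("%-12s %-12s %12.5f %10.3f %10.4f", r$factor[i], r$cma[i],
        r$effect[i], r$t[i], r$p_value[i])
  }
  invisible(path)
}
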