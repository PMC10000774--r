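#' Packaged reference data for the curcuminoid HPLC assay
#'
#' Small CSV fixtures transcribed from the development and validation of
#' the HPLC curcuminoid assay this package models: the factor levels of
#' the screening design, the per-CMA optimization goals and observed
#' ranges, the CMA specification windows, the operable-region CMP ranges
#' used for Monte Carlo simulation, the 14-run robustness plan with its
#' measured responses, the calibration-curve statistics, and the
#' dosage-form content comparison with its printed t/F values.
#'
#' @param name One of `"factor_levels"`, `"desirability_goals"`,
#'   `"spec_windows"`, `"mc_cmp_ranges"`, `"pb_robustness"`,
#'   `"calibration_stats"`, `"content_comparison"`.  Omit to list the
#'   available names.
#' @return A data frame (or the character vector of names).
#' @examples
#' aqbd_fixture()
#' head(aqbd_fixture("pb_robustness"))
#' @export
aqbd_fixture <- function(name = NULL) {
  available <- c("factor_levels", "desirability_goals", "spec_windows",
                 "mc_cmp_ranges", "pb_robustness", "calibration_stats",
                 "content_comparison")
  if (is.null(name)) return(available)
  if (!name %in% available)
    stop("unknown fixture '", name, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".csv"), package = "chromaqbd",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference factors, goals and windows as package objects
#'
#' Convenience loaders turning the packaged fixtures into the domain
#' objects the pipeline consumes.
#'
#' `fixture_factors()` builds the three screening-design factors (pH,
#' %ACN, temperature) over their full experimental ranges.
#' `fixture_goals()` maps the printed optimization standards to
#' [desirability_goal()] objects: one-sided rules like ">1.2" become
#' `at_least` ramps from the threshold to the observed maximum;
#' Maximize/Minimize ramps span the observed response range; "In range"
#' is the window indicator.  `fixture_windows()` returns the
#' [spec_window()] list, and `fixture_mc_ranges()` the operable-region
#' [cmp_factor()] list used for capability simulation.
#' `fixture_pb_table()` assembles the robustness plan and responses into
#' a [response_table()] over its four factors (pH, ACN, temperature,
#' buffer concentration).
#'
#' @return See each description.
#' @export
fixture_factors <- function() {
  tb <- aqbd_fixture("factor_levels")
  lapply(seq_len(nrow(tb)), function(i)
    cmp_factor(tb$name[i], tb$low[i], tb$high[i],
               ifelse(is.na(tb$units[i]), "", tb$units[i])))
}

#' @rdname fixture_factors
#' @export
fixture_goals <- function() {
  tb <- aqbd_fixture("desirability_goals")
  lapply(seq_len(nrow(tb)), function(i) {
    g <- tb$goal[i]
    if (startsWith(g, ">")) {
      thr <- as.numeric(sub(">", "", g))
      desirability_goal(tb$cma[i], "at_least", lower = thr,
                        upper = tb$upper_limit[i])
    } else if (g == "Maximize") {
      desirability_goal(tb$cma[i], "maximize", lower = tb$lower_limit[i],
                        upper = tb$upper_limit[i])
    } else if (g == "Minimize") {
      desirability_goal(tb$cma[i], "minimize", lower = tb$lower_limit[i],
                        upper = tb$upper_limit[i])
    } else {
      desirability_goal(tb$cma[i], "in_range", lower = tb$lower_limit[i],
                        upper = tb$upper_limit[i])
    }
  })
}

#' @rdname fixture_factors
#' @export
fixture_windows <- function() {
  tb <- aqbd_fixture("spec_windows")
  lapply(seq_len(nrow(tb)), function(i)
    spec_window(tb$cma[i], tb$lsl[i], tb$usl[i]))
}

#' @rdname fixture_factors
#' @export
fixture_mc_ranges <- function() {
  tb <- aqbd_fixture("mc_cmp_ranges")
  lapply(seq_len(nrow(tb)), function(i)
    cmp_factor(tb$factor[i], tb$low[i], tb$high[i]))
}

#' @rdname fixture_factors
#' @export
fixture_pb_table <- function() {
  tb <- aqbd_fixture("pb_robustness")
  factors <- list(cmp_factor("pH", 2.5, 2.9),
                  cmp_factor("ACN", 54, 57, "percent"),
                  cmp_factor("Temperature", 32, 35, "degC"),
                  cmp_factor("Buffer", 8, 12, "mM"))
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  coded <- vapply(factors, function(f) code_levels(f, tb[[f$name]]),
                  numeric(nrow(tb)))
  des <- new_design(factors, coded, tb$is_center == 1, rep(1L, nrow(tb)),
                    tb$run)
  cmas <- c("RS1", "RS2", "RT_BDMCMN", "RT_DMCMN", "RT_CMN",
            "TP_BDMCMN", "TP_DMCMN", "TP_CMN")
  response_table(des, tb[cmas])
}
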