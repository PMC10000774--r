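#' Specification window for a CMA
#'
#' Acceptance limits for a critical method attribute, e.g. resolution in
#' `[1.2, 12]`, retention time in `[2, 7]` minutes, plate count at least
#' 2000.  Either limit may be absent (one-sided window).  Feasibility at
#' the limits is closed: a prediction exactly on a limit passes.
#'
#' @param cma Response name.
#' @param lsl,usl Lower / upper specification limit; `NA` for absent.
#' @return A `"spec_window"` object.
#' @export
spec_window <- function(cma, lsl = NA_real_, usl = NA_real_) {
  lsl <- as.numeric(lsl); usl <- as.numeric(usl)
  if (is.na(lsl) && is.na(usl))
    stop("window for '", cma, "' needs at least one limit", call. = FALSE)
  if (!is.na(lsl) && !is.na(usl) && lsl >= usl)
    stop("LSL must be strictly below USL", call. = FALSE)
  structure(list(cma = cma, lsl = lsl, usl = usl), class = "spec_window")
}

in_window <- function(y, window) {
  # closed intervals, with a relative tolerance so a prediction that is
  # numerically on a limit counts as inside
  ok <- rep(TRUE, length(y))
  if (!is.na(window$lsl))
    ok <- ok & y >= window$lsl - 1e-9 * max(1, abs(window$lsl))
  if (!is.na(window$usl))
    ok <- ok & y <= window$usl + 1e-9 * max(1, abs(window$usl))
  ok
}

#' Design-space overlay: joint feasibility over a factor grid
#'
#' Evaluates every model over a full grid of factor settings and marks a
#' grid point feasible when every CMA prediction lies inside its
#' specification window (closed intervals).  This is the computational
#' form of the classical overlay plot whose all-windows-met region is the
#' candidate design space.
#'
#' @param models Named list of `"aqbd_fit"` objects covering every window's
#'   CMA.
#' @param windows List of [spec_window()] objects.
#' @param factors List of [cmp_factor()] objects spanning the region
#'   examined.
#' @param n_grid Points per axis (default 21).
#' @return An `"overlay_result"`: `axes` (per-factor grid values),
#'   `feasible` (logical array, dim = grid sizes), `coverage` (feasible
#'   fraction), plus the inputs needed by [extract_modr()].
#' @export
overlay_feasibility <- function(models, windows, factors, n_grid = 21L) {
  factors <- as_factor_list(factors)
  cmas <- vapply(windows, `[[`, character(1), "cma")
  missing_models <- setdiff(cmas, names(models))
  if (length(missing_models))
    stop("no model supplied for CMA(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  axes <- lapply(factors, function(f) seq(f$low, f$high, length.out = n_grid))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)  # axis 1 varies fastest
  names(grid) <- names(factors)
  ok <- rep(TRUE, nrow(grid))
  for (i in seq_along(windows)) {
    yhat <- predict(models[[cmas[i]]], grid)
    ok <- ok & in_window(yhat, windows[[i]])
  }
  feasible <- array(ok, dim = vapply(axes, length, integer(1)))
  structure(list(axes = axes, factors = factors, feasible = feasible,
                 coverage = mean(ok)),
            class = "overlay_result")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("Overlay over %s grid: %.1f%% of points feasible\n",
              paste(dim(x$feasible), collapse = " x "), 100 * x$coverage))
  invisible(x)
}

# Largest all-TRUE axis-aligned sub-box of a logical array (up to 3 axes
# exact; greedy expansion beyond).  Returns index ranges or NULL.
max_true_box <- function(mask, widths) {
  if (is.null(dim(mask))) mask <- array(mask, length(mask))
  nd <- length(dim(mask))
  if (!any(mask)) return(NULL)
  dims <- dim(mask)
  vol <- function(lo, hi) {      # natural-units volume; lattice-count tiebreak
    lens <- mapply(function(l, h, d) widths[[d]][h] - widths[[d]][l],
                   lo, hi, seq_len(nd))
    prod(lens)
  }
  npts <- function(lo, hi) prod(hi - lo + 1L)

  best <- NULL
  consider <- function(lo, hi) {
    cand <- list(lo = lo, hi = hi, vol = vol(lo, hi), n = npts(lo, hi))
    if (is.null(best) || cand$vol > best$vol + 1e-12 ||
        (abs(cand$vol - best$vol) <= 1e-12 && cand$n > best$n))
      best <<- cand
  }

  if (nd == 1L) {
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) consider(starts[i], ends[i])
  } else if (nd == 2L) {
    for (i1 in seq_len(dims[1])) {
      row_and <- rep(TRUE, dims[2])
      for (i2 in i1:dims[1]) {
        row_and <- row_and & mask[i2, ]
        r <- rle(row_and)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (j in which(r$values))
          consider(c(i1, starts[j]), c(i2, ends[j]))
      }
    }
  } else if (nd == 3L) {
    for (i1 in seq_len(dims[1])) {
      slab <- matrix(TRUE, dims[2], dims[3])
      for (i2 in i1:dims[1]) {
        slab <- slab & mask[i2, , ]
        for (j1 in seq_len(dims[2])) {
          col_and <- rep(TRUE, dims[3])
          for (j2 in j1:dims[2]) {
            col_and <- col_and & slab[j2, ]
            r <- rle(col_and)
            ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
            for (m in which(r$values))
              consider(c(i1, j1, starts[m]), c(i2, j2, ends[m]))
          }
        }
      }
    }
  } else {
    # greedy: grow alternately along each axis from the best single point
    idx <- which(mask, arr.ind = TRUE)
    seedpt <- idx[1L, ]
    lo <- hi <- as.integer(seedpt)
    repeat {
      grew <- FALSE
      for (d in seq_len(nd)) {
        for (dir in c(-1L, 1L)) {
          nlo <- lo; nhi <- hi
          if (dir < 0 && lo[d] > 1L) nlo[d] <- lo[d] - 1L
          else if (dir > 0 && hi[d] < dims[d]) nhi[d] <- hi[d] + 1L
          else next
          sl <- do.call(`[`, c(list(mask),
                               lapply(seq_len(nd), function(e)
                                 nlo[e]:nhi[e]), list(drop = FALSE)))
          if (all(sl)) { lo <- nlo; hi <- nhi; grew <- TRUE }
        }
      }
      if (!grew) break
    }
    consider(lo, hi)
  }
  best
}

#' Extract the Method Operable Design Region from an overlay
#'
#' Finds the maximum-volume axis-aligned box on the grid lattice whose
#' lattice points are all feasible -- an automated stand-in for drawing the
#' operating box on the overlay plot by hand.  Exact search up to three
#' factors; a documented greedy-expansion heuristic beyond that.  Supply
#' `manual` to override with a chosen box (it is validated against the
#' factor ranges).
#'
#' @param overlay An `"overlay_result"`.
#' @param manual Optional data frame (factor, lower, upper) to use instead
#'   of the automatic search.
#' @return Data frame with columns `factor`, `lower`, `upper` (natural
#'   units); zero rows, with a warning, if nothing is feasible.
#' @export
extract_modr <- function(overlay, manual = NULL) {
  stopifnot(inherits(overlay, "overlay_result"))
  fac_names <- names(overlay$factors)
  if (!is.null(manual)) {
    manual <- as.data.frame(manual)
    stopifnot(all(c("factor", "lower", "upper") %in% names(manual)))
    for (i in seq_len(nrow(manual))) {
      f <- overlay$factors[[manual$factor[i]]]
      if (is.null(f)) stop("manual box names unknown factor '",
                           manual$factor[i], "'", call. = FALSE)
      if (manual$lower[i] < f$low || manual$upper[i] > f$high)
        warning("manual box for '", f$name,
                "' extends beyond the examined factor range")
    }
    return(manual[, c("factor", "lower", "upper")])
  }
  box <- max_true_box(overlay$feasible, overlay$axes)
  if (is.null(box)) {
    warning("no feasible grid point: empty MODR")
    return(data.frame(factor = character(), lower = numeric(),
                      upper = numeric()))
  }
  data.frame(factor = fac_names,
             lower = unname(mapply(function(ax, i) ax[i], overlay$axes,
                                   box$lo)),
             upper = unname(mapply(function(ax, i) ax[i], overlay$axes,
                                   box$hi)),
             row.names = NULL)
}

#' Export an overlay mask as a long-format data frame
#'
#' One row per grid point: the natural-units factor values plus the
#' feasibility flag.  Suitable for writing to CSV.
#'
#' @param overlay An `"overlay_result"`.
#' @return Data frame with one column per factor and a `feasible` column.
#' @export
overlay_as_data_frame <- function(overlay) {
  grid <- expand.grid(overlay$axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(overlay$factors)
  grid$feasible <- as.vector(overlay$feasible)
  grid
}
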