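#' @keywords internal
new_design <- function(factors, coded, is_center, replicate, run_order) {
  k <- length(factors)
  coded <- matrix(as.numeric(coded), ncol = k,
                  dimnames = list(NULL, names(factors)))
  natural <- coded
  for (j in seq_len(k))
    natural[, j] <- decode_levels(factors[[j]], coded[, j])
  runs <- data.frame(run_order = as.integer(run_order),
                     is_center = as.logical(is_center),
                     replicate = as.integer(replicate))
  runs <- cbind(runs, as.data.frame(natural))
  structure(list(factors = factors, runs = runs, coded = coded),
            class = "aqbd_design")
}

#' @export
print.aqbd_design <- function(x, ...) {
  k <- length(x$factors)
  cat(sprintf("AQbD design: %d runs, %d factors (%s), %d centre point(s)\n",
              nrow(x$runs), k, paste(names(x$factors), collapse = ", "),
              sum(x$runs$is_center)))
  print(utils::head(x$runs, 12L))
  if (nrow(x$runs) > 12L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.aqbd_design <- function(x, ...) x$runs

#' Two-level full factorial design with centre points
#'
#' Generates the 2^k factorial in coded units (-1/+1), appends `n_center`
#' all-zero centre rows, replicates every run `n_replicates` times, and
#' randomizes the run order.  Randomization touches run order only: the
#' multiset of level combinations is identical for every seed.
#'
#' @param factors List of [cmp_factor()] objects (1 to 8 factors).
#' @param n_center Number of centre points (each replicated too).
#' @param n_replicates Replicates per run; replicate index is recorded so
#'   that pure-error degrees of freedom are available downstream.
#' @param seed Integer seed for run-order randomization; `NULL` leaves the
#'   standard Yates order.
#' @return An `"aqbd_design"`: a list with `factors`, a `runs` data frame
#'   (run_order, is_center, replicate, one natural-units column per factor)
#'   and the matching `coded` matrix.
#' @examples
#' fs <- list(cmp_factor("pH", 2.5, 3.5),
#'            cmp_factor("ACN", 50, 70, "percent"),
#'            cmp_factor("Temperature", 25, 35, "degC"))
#' d <- full_factorial(fs, n_center = 3, seed = 1)
#' nrow(d$runs)  # 8 factorial + 3 centre = 11
#' @export
full_factorial <- function(factors, n_center = 0L, n_replicates = 1L,
                           seed = NULL) {
  factors <- as_factor_list(factors)
  k <- length(factors)
  if (k > 8L) stop("at most 8 factors supported", call. = FALSE)
  n_center <- as.integer(n_center); n_replicates <- as.integer(n_replicates)
  stopifnot(n_center >= 0L, n_replicates >= 1L)

  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  if (n_center > 0L)
    base <- rbind(base, matrix(0, nrow = n_center, ncol = k))
  is_center <- c(rep(FALSE, 2L^k), rep(TRUE, n_center))

  idx <- rep(seq_len(nrow(base)), times = n_replicates)
  replicate <- rep(seq_len(n_replicates), each = nrow(base))
  coded <- base[idx, , drop = FALSE]
  n <- nrow(coded)
  ord <- with_seed(seed, if (is.null(seed)) seq_len(n) else sample.int(n))
  new_design(factors, coded[ord, , drop = FALSE], is_center[idx][ord],
             replicate[ord], seq_len(n))
}

# First row of the textbook 12-run Plackett-Burman cyclic generator.
pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' 12-run Plackett--Burman screening design with centre points
#'
#' Builds the standard cyclic 12-run Plackett--Burman layout (generator
#' `+ + - + + + - - - + -`, cyclically shifted, final row all low).  The
#' first `k` of the 11 orthogonal columns carry the supplied factors; the
#' remaining columns are retained as dummy columns so that effect standard
#' errors can be estimated from them.  Centre rows (all factors at
#' midpoint) are appended after the 12 two-level rows.
#'
#' @inheritParams full_factorial
#' @return An `"aqbd_design"` whose `coded` matrix has one column per
#'   factor; the unassigned dummy columns are kept in the `dummy_coded`
#'   attribute (12 x (11 - k), centre rows excluded).
#' @examples
#' fs <- list(cmp_factor("pH", 2.5, 2.9), cmp_factor("ACN", 54, 57),
#'            cmp_factor("Temperature", 32, 35), cmp_factor("Buffer", 8, 12))
#' d <- plackett_burman(fs, n_center = 2, seed = 1)
#' nrow(d$runs)  # 12 + 2
#' @export
plackett_burman <- function(factors, n_center = 0L, seed = NULL) {
  factors <- as_factor_list(factors)
  k <- length(factors)
  if (k > 11L)
    stop("the 12-run Plackett-Burman base design holds at most 11 factors",
         call. = FALSE)
  n_center <- as.integer(n_center)
  stopifnot(n_center >= 0L)

  pb <- matrix(NA_real_, 12L, 11L)
  for (i in 1:11)
    pb[i, ] <- pb12_generator[((seq_len(11L) - i) %% 11L) + 1L]
  pb[12L, ] <- -1
  coded <- pb[, seq_len(k), drop = FALSE]
  dummy <- pb[, setdiff(seq_len(11L), seq_len(k)), drop = FALSE]

  if (n_center > 0L)
    coded <- rbind(coded, matrix(0, n_center, k))
  is_center <- c(rep(FALSE, 12L), rep(TRUE, n_center))
  n <- nrow(coded)
  ord <- with_seed(seed, if (is.null(seed)) seq_len(n) else sample.int(n))
  des <- new_design(factors, coded[ord, , drop = FALSE], is_center[ord],
                    rep(1L, n), seq_len(n))
  # dummy rows aligned with the non-centre rows as they appear in run order
  original_rows <- ord[!is_center[ord]]
  attr(des, "dummy_coded") <- dummy[original_rows, , drop = FALSE]
  des
}
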