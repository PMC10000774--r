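#' Define a critical method parameter (CMP)
#'
#' A factor is a controllable chromatographic input -- mobile-phase pH,
#' organic-modifier percentage, column temperature, buffer concentration --
#' with a natural-units operating range.  Designs are laid out in coded
#' units (-1, 0, +1 for low, centre, high) and mapped back to natural units
#' through the usual linear coding.
#'
#' @param name Factor label, unique within a design.
#' @param low,high Natural-units range limits; `low < high`.
#' @param units Unit string (e.g. `"percent"`, `"degC"`, `"mM"`; pH is
#'   unitless and conventionally gets `""`).
#' @return An object of class `"cmp_factor"`.
#' @examples
#' cmp_factor("pH", 2.5, 3.5)
#' cmp_factor("ACN", 50, 70, units = "percent")
#' @export
cmp_factor <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high))
    stop("factor '", name, "': limits must be finite numbers", call. = FALSE)
  if (low >= high)
    stop("factor '", name, "': low (", low, ") must be strictly below high (",
         high, ")", call. = FALSE)
  structure(list(name = name, low = low, high = high, units = units),
            class = "cmp_factor")
}

#' @export
print.cmp_factor <- function(x, ...) {
  cat(sprintf("CMP factor '%s': [%g, %g]%s\n", x$name, x$low, x$high,
              if (nzchar(x$units)) paste0(" ", x$units) else ""))
  invisible(x)
}

as_factor_list <- function(factors) {
  if (inherits(factors, "cmp_factor")) factors <- list(factors)
  if (!length(factors)) stop("empty factor list", call. = FALSE)
  if (!all(vapply(factors, inherits, logical(1), "cmp_factor")))
    stop("'factors' must be a list of cmp_factor objects", call. = FALSE)
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate factor names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(factors) <- nms
  factors
}

#' Convert between natural and coded factor levels
#'
#' Coded units place the factor midpoint at 0 and the range endpoints at
#' -1/+1: `coded = (natural - (low + high)/2) / ((high - low)/2)`.  Values
#' outside the range are mapped linearly (coded magnitudes above 1), so the
#' pair is an exact inverse everywhere.
#'
#' @param factor A [cmp_factor()].
#' @param natural,coded Numeric vectors of levels.
#' @return Numeric vector of the converted levels.
#' @examples
#' ph <- cmp_factor("pH", 2.5, 3.5)
#' code_levels(ph, 3)      # 0: the centre level
#' decode_levels(ph, -1)   # 2.5
#' @export
code_levels <- function(factor, natural) {
  stopifnot(inherits(factor, "cmp_factor"))
  (natural - (factor$low + factor$high) / 2) / ((factor$high - factor$low) / 2)
}

#' @rdname code_levels
#' @export
decode_levels <- function(factor, coded) {
  stopifnot(inherits(factor, "cmp_factor"))
  (factor$low + factor$high) / 2 + coded * (factor$high - factor$low) / 2
}

# Evaluate an expression with a transient RNG state seeded by `seed`;
# the caller's .Random.seed is untouched.  seed = NULL means "use the
# current stream" (still restores it afterwards when save = FALSE).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
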