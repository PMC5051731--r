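#' Radially symmetric sigmoid drift field
#'
#' A drift field assigns every point a weight in (0, 1) that mixes directed
#' and Brownian motion in the random-walk-with-drift model. The weight is a
#' falling sigmoid of the distance `r` from the field's origin:
#' \deqn{\phi(r) = \frac{1}{1 + e^{(r - r_{1/2})/s}}}
#' where `r_half` is the half-maximal distance and `1/s` the steepness. For
#' an attractive field `r = 0` at the chromatin edge; for a repulsive field
#' `r = 0` at the cell boundary (repulsion from the cortex is centripetal, so
#' both fields direct motion toward the cell centre).
#'
#' `r_half = Inf` gives the degenerate all-drift field (weight 1 everywhere),
#' convenient for pure-drift controls.
#'
#' @param r_half Half-maximal distance (um).
#' @param s Inverse steepness (um); must be positive.
#' @param origin Where `r` is measured from: `"chromatin_edge"` (attractive)
#'   or `"cell_boundary"` (repulsive).
#' @return An object of class `drift_field`.
#' @examples
#' f <- drift_field(r_half = 10, s = 1)
#' field_weight(f, c(0, 10, 30))
#' @export
drift_field <- function(r_half, s, origin = c("chromatin_edge", "cell_boundary")) {
  origin <- match.arg(origin)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    abort("invalid drift field: steepness parameter `s` must be a positive number",
          class = "asterdrift_invalid_field")
  }
  if (!is.numeric(r_half) || length(r_half) != 1L || is.na(r_half) || r_half < 0) {
    abort("invalid drift field: `r_half` must be a non-negative number",
          class = "asterdrift_invalid_field")
  }
  structure(list(r_half = r_half, s = s, origin = origin), class = "drift_field")
}

#' Evaluate a drift field
#'
#' @param field A [drift_field()].
#' @param r Distances from the field origin (um), non-negative.
#' @return Weights in (0, 1), monotone non-increasing in `r`.
#' @export
field_weight <- function(field, r) {
  stopifnot(inherits(field, "drift_field"))
  if (any(r < 0, na.rm = TRUE)) {
    abort("`r` is measured from the field origin and must be >= 0",
          class = "asterdrift_domain_error")
  }
  1 / (1 + exp((r - field$r_half) / field$s))
}

#' @export
print.drift_field <- function(x, ...) {
  cat(sprintf("<drift_field> sigmoid, r_half = %g um, s = %g um, origin = %s\n",
              x$r_half, x$s, x$origin))
  invisible(x)
}
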