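# Evidence points live on a 0.05 grid (panels adjudicate in twentieths of a
# point).  Doubles cannot represent 0.05 exactly, so every subtotal is
# re-snapped to the grid; all sums arising here round-trip exactly.

POINTS_GRID <- 0.05

#' Snap a points value to the 0.05 grid
#'
#' @param x numeric vector of points.
#' @return `x` rounded to the nearest multiple of 0.05.
#' @keywords internal
round_points <- function(x) round(x / POINTS_GRID) * POINTS_GRID

#' Is a value on the 0.05 points grid?
#' @keywords internal
on_points_grid <- function(x) {
  is.numeric(x) & is.finite(x) & abs(x / POINTS_GRID - round(x / POINTS_GRID)) < 1e-6
}

# clamp to [0, cap]; caps are always nonnegative
clamp_cap <- function(x, cap) round_points(pmin(pmax(x, 0), cap))
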