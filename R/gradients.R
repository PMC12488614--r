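# Somato-apical parameter gradients: sigmoidal passive gradients, the linear
# A-type K+ gradient, sigmoidal h / T-type conductance gradients, and the
# piecewise-linear h-channel V1/2 map.

#' Sigmoidally decreasing passive gradient
#'
#' `value(x) = max + (min - max) / (1 + exp((d - x)/k))`: equal to `max` near
#' the soma, `min` at the distal limit, the midpoint exactly at `x = d`.
#' Used for specific membrane resistivity Rm (kOhm cm^2) and axial
#' resistivity Ra (Ohm cm).
#'
#' @param max_value,min_value somatic and distal asymptotes (same units).
#' @param d half-maximal distance (um).
#' @param k slope (um), non-zero.
#' @export
passive_gradient <- function(max_value, min_value, d, k) {
  if (k == 0) stop("gradient slope k must be non-zero", call. = FALSE)
  structure(list(max_value = max_value, min_value = min_value, d = d, k = k),
            class = "passive_gradient")
}

#' Evaluate a passive gradient at a path distance
#' @param grad a [passive_gradient()].
#' @param x path distance from the soma (um), `>= 0`, vectorized.
#' @export
passive_at <- function(grad, x) {
  stopifnot(inherits(grad, "passive_gradient"), all(x >= 0))
  grad$max_value + (grad$min_value - grad$max_value) /
    (1 + exp((grad$d - x) / grad$k))
}

#' Linearly increasing conductance gradient (A-type K+)
#'
#' `g(x) = g_base * (1 + fold * x / 100)`: the somatic density grows by
#' `fold`-fold every 100 um.
#'
#' @param g_base somatic density (S/cm^2).
#' @param fold fold increase per 100 um.
#' @export
linear_gradient <- function(g_base, fold) {
  structure(list(g_base = g_base, fold = fold), class = "linear_gradient")
}

#' Evaluate the linear conductance gradient
#' @param grad a [linear_gradient()].
#' @param x path distance (um), `>= 0`, vectorized.
#' @export
ka_density_at <- function(grad, x) {
  stopifnot(inherits(grad, "linear_gradient"), all(x >= 0))
  grad$g_base * (1 + grad$fold * x / 100)
}

#' Sigmoidally increasing conductance gradient (h, T-type Ca2+)
#'
#' `g(x) = g_base * (1 + fold / (1 + exp((d - x)/k)))`: rises from near
#' `g_base` at the soma to `g_base * (1 + fold)` distally, with the half rise
#' at `x = d`.
#'
#' @param g_base somatic density (S/cm^2).
#' @param fold saturating fold increase.
#' @param d half-maximal distance (um).
#' @param k slope (um), non-zero.
#' @export
sigmoid_gradient <- function(g_base, fold, d, k) {
  if (k == 0) stop("gradient slope k must be non-zero", call. = FALSE)
  structure(list(g_base = g_base, fold = fold, d = d, k = k),
            class = "sigmoid_gradient")
}

#' Evaluate a sigmoidal conductance gradient
#' @param grad a [sigmoid_gradient()].
#' @param x path distance (um), `>= 0`, vectorized.
#' @export
sigmoid_density_at <- function(grad, x) {
  stopifnot(inherits(grad, "sigmoid_gradient"), all(x >= 0))
  grad$g_base * (1 + grad$fold / (1 + exp((grad$d - x) / grad$k)))
}

#' h-channel activation V1/2 along the somato-apical axis
#'
#' Piecewise linear: `v_prox` for `x <= x0`, linear from `v_prox` to `v_dist`
#' over `x0..x1`, `v_dist` beyond. Defaults: -82 mV up to 100 um, -90 mV past
#' 300 um.
#'
#' @param x path distance (um), `>= 0`, vectorized.
#' @param v_prox,v_dist proximal and distal V1/2 (mV).
#' @param x0,x1 breakpoints (um).
#' @return V1/2 (mV).
#' @export
h_vhalf_at <- function(x, v_prox = -82, v_dist = -90, x0 = 100, x1 = 300) {
  stopifnot(all(x >= 0), x1 > x0)
  frac <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  v_prox + (v_dist - v_prox) * frac
}

#' Which A-type K+ model applies at a path distance
#'
#' The proximal model for `x < 100` um, the distal model at and beyond 100 um.
#'
#' @param x path distance (um), `>= 0`, vectorized.
#' @param switch_um proximal/distal boundary (um).
#' @return character vector, `"KA_prox"` or `"KA_dist"`.
#' @export
ka_model_at <- function(x, switch_um = 100) {
  stopifnot(all(x >= 0))
  ifelse(x < switch_um, "KA_prox", "KA_dist")
}
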