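# Gating-variable specifications and channel current laws.

FARADAY <- 96485.33212  # C/mol
GAS_R <- 8.31446        # J/(mol K)

#' Voltage-dependent gate specification
#'
#' A gate is a steady-state activation curve together with a voltage-dependent
#' time constant, plus the modifier hooks the parameter sweeps use: a
#' half-activation voltage shift (`v_half_shift`, mV, translates both curves),
#' a multiplicative time-constant scale (`tau_scale`) and an additive
#' time-constant offset (`tau_offset`, ms). Temperature dependence is a Q10
#' correction relative to the reference temperature `tref` at which the
#' time-constant parameters are stated.
#'
#' @param name gate label.
#' @param ss list describing the steady-state curve (see [eval_ss_form()]).
#' @param tau list describing the time-constant curve (see [eval_tau_form()]).
#' @param exponent integer power with which the gate enters the open fraction.
#' @param q10,tref Q10 factor and reference temperature (degC).
#' @param v_half_shift,tau_scale,tau_offset modifier hooks (mV, unitless, ms).
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(name, ss, tau, exponent = 1L, q10 = 1, tref = 34,
                      v_half_shift = 0, tau_scale = 1, tau_offset = 0) {
  stopifnot(is.character(name), is.list(ss), is.list(tau))
  if (!is.finite(tau_scale) || tau_scale <= 0) {
    stop("tau_scale must be a positive finite number", call. = FALSE)
  }
  structure(list(name = name, ss = ss, tau = tau,
                 exponent = as.integer(exponent),
                 q10 = q10, tref = tref,
                 v_half_shift = v_half_shift,
                 tau_scale = tau_scale, tau_offset = tau_offset),
            class = "gate_spec")
}

#' Evaluate a steady-state functional form
#'
#' Currently a single form is used: `boltzmann`,
#' `1 / (1 + exp((vhalf - v) / k))`; `k > 0` gives an activation curve,
#' `k < 0` an inactivation curve.
#'
#' @param ss list with `form` and its parameters.
#' @param v membrane voltage (mV), vectorized.
#' @return steady-state open fraction in \[0, 1\].
#' @export
eval_ss_form <- function(ss, v) {
  switch(ss$form,
    boltzmann = 1 / (1 + exp((ss$vhalf - v) / ss$k)),
    stop("unknown steady-state form: ", ss$form, call. = FALSE)
  )
}

#' Evaluate a time-constant functional form
#'
#' Forms: `constant`, `bell` (Gaussian bump on a pedestal), `recip2exp`
#' (pedestal plus the reciprocal of a sum of two exponentials), `texp_piecewise`
#' (piecewise exponential, continuous low-threshold-calcium inactivation form)
#' and `linclip` (linear in voltage with a floor). All return ms.
#'
#' @param tau list with `form` and its parameters.
#' @param v membrane voltage (mV), vectorized.
#' @return time constant (ms), strictly positive.
#' @export
eval_tau_form <- function(tau, v) {
  switch(tau$form,
    constant = rep_len(tau$tau, length(v)),
    bell = tau$base + tau$amp * exp(-((v - tau$vpeak) / tau$width)^2),
    recip2exp = tau$c0 +
      1 / (exp(-(v - tau$v1) / tau$b1) + exp((v - tau$v2) / tau$b2)),
    texp_piecewise = ifelse(v < tau$vsplit,
      exp((v - tau$v1) / tau$b1),
      tau$c0 + exp(-(v - tau$v2) / tau$b2)),
    linclip = pmax(tau$tmin, tau$a * (v - tau$v0)),
    stop("unknown time-constant form: ", tau$form, call. = FALSE)
  )
}

#' Gate steady state with modifier hooks applied
#'
#' Returns `steady_state(v - v_half_shift)`, bounded in \[0, 1\].
#'
#' @param gate a [gate_spec()].
#' @param v membrane voltage (mV), vectorized.
#' @export
gate_steady_state <- function(gate, v) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(v)))
  x <- eval_ss_form(gate$ss, v - gate$v_half_shift)
  pmin(pmax(x, 0), 1)
}

#' Gate time constant with modifiers and Q10 temperature correction
#'
#' Returns `(tau_scale * base_tau(v - v_half_shift) + tau_offset) /
#' q10^((temperature - tref)/10)` in ms. The V1/2 shift translates the time
#' constant curve together with the steady-state curve (the schemes used here
#' anchor their tau curves to V1/2).
#'
#' @param gate a [gate_spec()].
#' @param v membrane voltage (mV), vectorized.
#' @param temperature simulation temperature (degC).
#' @export
gate_time_constant <- function(gate, v, temperature = 34) {
  stopifnot(inherits(gate, "gate_spec"))
  if (gate$tau_scale <= 0) stop("tau_scale must be > 0", call. = FALSE)
  base <- eval_tau_form(gate$tau, v - gate$v_half_shift)
  qfac <- gate$q10^((temperature - gate$tref) / 10)
  out <- (gate$tau_scale * base + gate$tau_offset) / qfac
  if (any(out <= 0)) stop("non-positive time constant", call. = FALSE)
  out
}

#' Ionic environment for the GHK calcium current
#'
#' @param ca_out,ca_in extra-/intracellular calcium (mM); defaults 2 mM and
#'   100 nM (= 1e-4 mM).
#' @param temperature degC.
#' @param valence ion valence (2 for calcium).
#' @export
ghk_env <- function(ca_out = 2, ca_in = 1e-4, temperature = 34, valence = 2) {
  stopifnot(ca_out > 0, ca_in > 0)
  structure(list(ca_out = ca_out, ca_in = ca_in,
                 temperature = temperature, valence = valence),
            class = "ghk_env")
}

#' Goldman-Hodgkin-Katz current density (permeability form)
#'
#' The constant-field flux equation for a divalent ion,
#' `I = P z^2 F^2 V / (RT) * ((Ca_in - Ca_out exp(-zFV/RT)) / (1 - exp(-zFV/RT)))`,
#' with the removable singularity at `V = 0` replaced by its series limit.
#' Negative values are inward currents.
#'
#' @param v membrane voltage (mV), vectorized.
#' @param env a [ghk_env()].
#' @param permeability membrane permeability (cm/s), `>= 0`.
#' @return current density (mA/cm^2).
#' @export
ghk_current_density <- function(v, env = ghk_env(), permeability) {
  stopifnot(inherits(env, "ghk_env"), permeability >= 0)
  z <- env$valence
  tk <- env$temperature + 273.15
  ci <- env$ca_in * 1e-6   # mol/cm^3
  co <- env$ca_out * 1e-6
  xi <- z * FARADAY * (v * 1e-3) / (GAS_R * tk)  # dimensionless zFV/RT
  small <- abs(xi) < 1e-5
  frac <- numeric(length(v))
  xs <- xi[small]
  # xi * (ci - co e^-xi)/(1 - e^-xi) -> (ci - co) + xi (ci + co)/2 + O(xi^2)
  frac[small] <- (ci - co) + xs * (ci + co) / 2
  xl <- xi[!small]
  frac[!small] <- xl * (ci - co * exp(-xl)) / (1 - exp(-xl))
  1e3 * permeability * z * FARADAY * frac  # A/cm^2 -> mA/cm^2
}

#' GHK driving term in millivolts
#'
#' The NEURON-style driving function `-f (1 - (Ca_in/Ca_out) e^(v/f)) efun(v/f)`
#' with `f = RT/(zF)` in mV and `efun(x) = x/(e^x - 1)`. Multiplying by a
#' density in S/cm^2 and the open fraction gives the channel current in
#' mA/cm^2; this is the convention under which the printed T-type densities
#' pass through unchanged. Proportional to [ghk_current_density()] at fixed
#' concentrations.
#'
#' @param v membrane voltage (mV), vectorized.
#' @param ca_in,ca_out calcium concentrations (mM).
#' @param temperature degC.
#' @param valence ion valence.
#' @return driving term (mV); negative = inward.
#' @export
ghk_driving <- function(v, ca_in = 1e-4, ca_out = 2, temperature = 34,
                        valence = 2) {
  f <- 1e3 * GAS_R * (temperature + 273.15) / (valence * FARADAY)  # mV
  nu <- v / f
  ef <- ifelse(abs(nu) < 1e-6, 1 - nu / 2, nu / (exp(nu) - 1))
  -f * (1 - (ca_in / ca_out) * exp(nu)) * ef
}

#' Channel specification
#'
#' Assembles gates into a channel with either an ohmic current law
#' (`density * prod(state^exponent) * (v - erev)`) or a GHK law
#' (`density * prod(state^exponent) * ghk_driving(v)`).
#'
#' @param name channel label (`Na`, `KDR`, `KA_prox`, `KA_dist`, `h`, `CaT`).
#' @param current `"ohmic"` or `"ghk"`.
#' @param gates list of [gate_spec()] objects (their `exponent` fields are used).
#' @param erev reversal potential (mV) for ohmic channels.
#' @param valence ion valence for GHK channels.
#' @param density conductance density (S/cm^2); for GHK channels the density
#'   parameter in the mV-driving convention.
#' @export
channel_spec <- function(name, current = c("ohmic", "ghk"), gates,
                         erev = NA_real_, valence = 2, density = 0) {
  current <- match.arg(current)
  stopifnot(all(vapply(gates, inherits, logical(1), "gate_spec")))
  if (current == "ohmic" && !is.finite(erev)) {
    stop("ohmic channel needs a reversal potential", call. = FALSE)
  }
  structure(list(name = name, current = current, gates = gates,
                 erev = erev, valence = valence, density = density),
            class = "channel_spec")
}

#' Channel current density for given gate states
#'
#' @param chan a [channel_spec()].
#' @param v membrane voltage (mV), scalar.
#' @param gate_states open fractions, one per gate, each in \[0, 1\].
#' @param env a [ghk_env()] (used by GHK channels).
#' @return current density (mA/cm^2); negative = inward.
#' @export
channel_current <- function(chan, v, gate_states, env = ghk_env()) {
  stopifnot(inherits(chan, "channel_spec"))
  if (length(gate_states) != length(chan$gates)) {
    stop("gate_states length does not match the channel's gate list",
         call. = FALSE)
  }
  if (any(gate_states < 0 | gate_states > 1)) {
    stop("gate states must lie in [0, 1]", call. = FALSE)
  }
  open <- 1
  for (i in seq_along(chan$gates)) {
    open <- open * gate_states[[i]]^chan$gates[[i]]$exponent
  }
  if (chan$current == "ohmic") {
    chan$density * open * (v - chan$erev)
  } else {
    chan$density * open *
      ghk_driving(v, env$ca_in, env$ca_out, env$temperature, chan$valence)
  }
}
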