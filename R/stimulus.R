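# Chirp (ZAP) stimulus: constant-amplitude sinusoid with linearly increasing
# instantaneous frequency.

#' Chirp stimulus specification
#'
#' Constant-amplitude sinusoidal current whose instantaneous frequency rises
#' linearly from `f_start` to `f_end` over `duration_s`. Defaults are the
#' standard subthreshold characterization stimulus: 50 pA, 0 to 15 Hz in
#' 15 s.
#'
#' @param amplitude_pA peak current (pA).
#' @param f_start_hz,f_end_hz frequency ramp endpoints (Hz).
#' @param duration_s sweep duration (s).
#' @param delay_s onset delay of rest before the chirp (s, `>= 0`).
#' @export
chirp_stimulus <- function(amplitude_pA = 50, f_start_hz = 0, f_end_hz = 15,
                           duration_s = 15, delay_s = 0.5) {
  stopifnot(amplitude_pA >= 0, duration_s > 0, f_end_hz > f_start_hz,
            delay_s >= 0)
  structure(list(amplitude_pA = amplitude_pA, f_start_hz = f_start_hz,
                 f_end_hz = f_end_hz, duration_s = duration_s,
                 delay_s = delay_s),
            class = "chirp_stimulus")
}

#' Chirp current at a time point
#'
#' `amplitude * sin(phi(t))` with the phase the integral of the instantaneous
#' frequency: `phi(t) = 2 pi (f_start t + (f_end - f_start) t^2 / (2 D))`.
#' Zero outside the stimulus window `[0, duration]`.
#'
#' @param stim a [chirp_stimulus()].
#' @param t_s time since stimulus onset (s), vectorized.
#' @return current (pA).
#' @export
chirp_current <- function(stim, t_s) {
  stopifnot(inherits(stim, "chirp_stimulus"))
  phase <- 2 * pi * (stim$f_start_hz * t_s +
    (stim$f_end_hz - stim$f_start_hz) * t_s^2 / (2 * stim$duration_s))
  out <- stim$amplitude_pA * sin(phase)
  out[t_s < 0 | t_s > stim$duration_s] <- 0
  out
}

#' Instantaneous chirp frequency
#' @param stim a [chirp_stimulus()].
#' @param t_s time since onset (s), vectorized.
#' @return frequency (Hz).
#' @export
chirp_frequency <- function(stim, t_s) {
  stim$f_start_hz + (stim$f_end_hz - stim$f_start_hz) * t_s / stim$duration_s
}
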