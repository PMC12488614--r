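# Phenomenological resonant (RLC) circuit fixture: a linear two-variable
# system with a closed-form impedance, used as an independent oracle for the
# chirp-FFT analysis pipeline.

#' Resonant-circuit fixture
#'
#' Parallel RC membrane with an optional phenomenological inductive branch
#' (resistance `rl` in series with inductance `l`):
#' `Z(f) = 1 / (1/r + i w c + 1/(rl + i w l))`. With the inductive branch
#' active `|Z(f)|` has a unique interior maximum; without it the circuit is a
#' pure RC low-pass. Units: MOhm, nF, MOhm*ms (1 MOhm*ms = 1000 H); time in
#' ms, current in nA, voltage in mV.
#'
#' @param r membrane resistance (MOhm).
#' @param c membrane capacitance (nF).
#' @param rl inductive-branch resistance (MOhm).
#' @param l inductance (MOhm*ms).
#' @param inductive logical; include the inductive branch?
#' @export
rlc_fixture <- function(r = 100, c = 0.6, rl = 25, l = 1200,
                        inductive = TRUE) {
  stopifnot(r > 0, c > 0, rl > 0, l > 0)
  structure(list(r = r, c = c, rl = rl, l = l, inductive = inductive),
            class = "rlc_fixture")
}

#' Closed-form impedance of the RLC fixture
#'
#' @param fixture an [rlc_fixture()].
#' @param freq_hz frequencies (Hz), vectorized.
#' @return complex impedance (MOhm).
#' @export
rlc_impedance <- function(fixture, freq_hz) {
  w <- 2 * pi * freq_hz / 1e3  # rad/ms
  y <- 1 / fixture$r + 1i * w * fixture$c
  if (fixture$inductive) y <- y + 1 / (fixture$rl + 1i * w * fixture$l)
  1 / y
}

#' Closed-form resonance of the RLC fixture
#'
#' Argmax and Q of `|Z(f)|` on a dense grid over the analysis band; the
#' oracle the chirp-FFT pipeline is checked against.
#'
#' @param fixture an [rlc_fixture()].
#' @param band frequency band (Hz).
#' @param df grid spacing (Hz).
#' @return list with `f_R_hz`, `Q`, `peak_mag`.
#' @export
rlc_resonance <- function(fixture, band = c(0.5, 15), df = 0.001) {
  f <- seq(band[1], band[2], by = df)
  m <- Mod(rlc_impedance(fixture, f))
  list(f_R_hz = f[which.max(m)], Q = max(m) / m[1], peak_mag = max(m))
}

# exact matrix exponential of a 2x2 matrix (via complex eigen-split)
expm2 <- function(a) {
  m <- (a[1, 1] + a[2, 2]) / 2
  q <- sqrt(as.complex(m^2 - (a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1])))
  i2 <- diag(2)
  if (Mod(q) < 1e-12) {
    e <- exp(m) * (i2 + (a - m * i2))
  } else {
    e <- exp(m) * (cosh(q) * i2 + (sinh(q) / q) * (a - m * i2))
  }
  Re(e)
}

#' Integrate the RLC fixture under a chirp and package as a trace set
#'
#' Exact zero-order-hold discretization of the linear circuit (the per-step
#' propagator is the matrix exponential), so the only error is the piecewise-
#' constant sampling of the stimulus on the recording grid.
#'
#' @param fixture an [rlc_fixture()].
#' @param stim a [chirp_stimulus()].
#' @param dt_ms sampling step (ms).
#' @param pre_ms,post_ms stimulus-free padding (ms).
#' @return a `trace_set` (columns `time_ms`, `i_pA`, `v_mV`, `ca_nM` = 0).
#' @export
make_rlc_trace <- function(fixture, stim = chirp_stimulus(), dt_ms = 0.25,
                           pre_ms = 500, post_ms = 200) {
  a <- matrix(c(-1 / (fixture$r * fixture$c), -1 / fixture$c,
                1 / fixture$l, -fixture$rl / fixture$l),
              2, 2, byrow = TRUE)
  if (!fixture$inductive) {
    # decouple the inductive branch entirely
    a[2, ] <- c(0, -1)
    a[1, 2] <- 0
  }
  ad <- expm2(a * dt_ms)
  bd <- solve(a, (ad - diag(2)) %*% c(1 / fixture$c, 0))
  n_pre <- round(pre_ms / dt_ms)
  n_stim <- round(stim$duration_s * 1e3 / dt_ms)
  n_post <- round(post_ms / dt_ms)
  t_ms <- (seq_len(n_pre + n_stim + n_post) - 1) * dt_ms
  i_pA <- chirp_current(stim, (t_ms - pre_ms) / 1e3)
  u <- i_pA / 1e3  # nA
  x <- c(0, 0)
  v <- numeric(length(t_ms))
  for (k in seq_along(t_ms)) {
    v[k] <- x[1]
    x <- ad %*% x + bd * u[k]
  }
  df <- data.frame(time_ms = t_ms, i_pA = i_pA, v_mV = v, ca_nM = 0)
  structure(df, class = c("trace_set", "data.frame"),
            onset_ms = pre_ms, duration_ms = stim$duration_s * 1e3,
            record_dt_ms = dt_ms, site_um = 0,
            f_start_hz = stim$f_start_hz, f_end_hz = stim$f_end_hz)
}
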