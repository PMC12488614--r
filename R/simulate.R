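# Simulation protocols: model compilation into engine arrays, steady-state
# initialization at the holding potential, chirp/DC/sine injections, and
# trace-set containers with text and binary round-trip IO.

#' Simulation configuration
#'
#' @param dt_ms integration time step (ms); default 0.025 ms = 25 us.
#' @param temperature_c simulation temperature (degC).
#' @param hold_mV holding potential enforced at the injection site before the
#'   stimulus (mV).
#' @param settle_ms duration of the steady-state settling phase during which
#'   the injection site is clamped at `hold_mV` (ms).
#' @param pre_ms stimulus-free recording window between settling and stimulus
#'   onset (ms); its tail provides the impedance baseline.
#' @param post_ms stimulus-free padding after the stimulus (ms).
#' @param record_dt_ms recording grid (ms); must be a multiple of `dt_ms`.
#' @export
sim_config <- function(dt_ms = 0.025, temperature_c = 34, hold_mV = -65,
                       settle_ms = 2000, pre_ms = 500, post_ms = 200,
                       record_dt_ms = 0.25) {
  stopifnot(dt_ms > 0, settle_ms > 0, pre_ms >= 0, post_ms >= 0)
  re <- record_dt_ms / dt_ms
  if (abs(re - round(re)) > 1e-9) {
    stop("record_dt_ms must be an integer multiple of dt_ms", call. = FALSE)
  }
  list(dt_ms = dt_ms, temperature_c = temperature_c, hold_mV = hold_mV,
       settle_ms = settle_ms, pre_ms = pre_ms, post_ms = post_ms,
       record_dt_ms = record_dt_ms, record_every = as.integer(round(re)))
}

#' Advance the single-pool calcium concentration one step
#'
#' `d[Ca]/dt = -i_CaT / (2 F depth) - ([Ca] - rest) / tau`, advanced by the
#' exact exponential update for a constant current over the step (the same
#' update the integrator uses). Inward (negative) T-type current raises the
#' shell concentration.
#'
#' @param ca_mM current concentration (mM).
#' @param i_cat_mA_cm2 T-type calcium current density (mA/cm^2); negative =
#'   inward.
#' @param dt_ms time step (ms).
#' @param pool a [ca_settings()].
#' @return concentration after one step (mM), never below zero.
#' @export
update_calcium <- function(ca_mM, i_cat_mA_cm2, dt_ms, pool = ca_settings()) {
  flux <- -i_cat_mA_cm2 / (2 * FARADAY * pool$depth_um * 1e-4)  # mM/ms
  cinf <- pool$rest_mM + flux * pool$tau_ms
  out <- cinf + (ca_mM - cinf) * exp(-dt_ms / pool$tau_ms)
  pmax(out, 0)
}

# Voltage grid for the engine's kinetics lookup tables.
engine_vgrid <- function() seq(-150, 100, by = 0.025)

#' Compile a cable model into engine arrays
#'
#' Flattens geometry into per-compartment capacitances, leak and axial
#' conductances, and evaluates every active gate's steady-state and
#' time-constant curves (with modifiers and Q10 applied) on a fine voltage
#' grid; the C++ integrator only interpolates these tables, so the exported R
#' kinetics functions are the single source of truth.
#'
#' @param model a `cable_model`.
#' @param temperature_c simulation temperature (degC).
#' @return an opaque list consumed by the integrator.
#' @export
compile_model <- function(model, temperature_c = 34) {
  comp <- model$comp
  n <- nrow(comp)
  vgrid <- engine_vgrid()
  area <- comp$area_cm2
  cm_nF <- comp$cm_uF * area * 1e3          # uF/cm2 * cm2 -> uF -> nF
  gpas_uS <- area / (comp$rm_kohm * 1e3) * 1e6  # S -> uS
  # axial conductance between compartment centers (uS)
  gax_uS <- numeric(n)
  cross_cm2 <- pi * (comp$diam_um * 1e-4 / 2)^2
  half_r <- comp$ra_ohm * (comp$length_um * 1e-4 / 2) / cross_cm2  # Ohm
  for (i in seq_len(n)) {
    p <- comp$parent[i]
    if (p > 0) gax_uS[i] <- 1e6 / (half_r[i] + half_r[p])
  }
  chans <- list()
  for (nm in colnames(model$dens)) {
    dvec <- model$dens[, nm]
    if (all(dvec == 0)) next
    spec <- model$registry[[nm]]
    if (is.null(spec)) stop("registry lacks channel ", nm, call. = FALSE)
    gates <- lapply(spec$gates, function(g) {
      vs <- rep(0, n)
      ov <- model$gate_vshift[[nm]]
      if (!is.null(ov)) vs <- rep_len(ov, n)
      list(expo = g$exponent,
           vshift = vs,
           xinf = gate_steady_state(g, vgrid),
           tau = gate_time_constant(g, vgrid, temperature_c))
    })
    chans[[length(chans) + 1]] <- list(
      name = nm, ghk = spec$current == "ghk",
      erev = if (is.finite(spec$erev)) spec$erev else 0,
      dens_uS = dvec * area * 1e6, gates = gates)
  }
  ca <- model$ca
  ca_on <- as.integer(model$dens[, "CaT"] > 0)
  # nA -> mA/cm2 -> mM/ms in the shell: i_nA * 1e-6 / area / (2 F depth_cm)
  cafac <- 1e-6 / (area * 2 * 96485.33212 * ca$depth_um * 1e-4)
  f_mV <- 1e3 * 8.31446 * (temperature_c + 273.15) / (2 * 96485.33212)
  nu <- vgrid / f_mV
  efun <- ifelse(abs(nu) < 1e-6, 1 - nu / 2, nu / (exp(nu) - 1))
  list(parent = as.integer(comp$parent) - 1L, cm_nF = cm_nF,
       gpas_uS = gpas_uS, epas = model$e_pas, gax_uS = gax_uS,
       vmin = vgrid[1], dv = vgrid[2] - vgrid[1], chans = chans,
       ca = list(on = ca_on, tau_ms = ca$tau_ms, rest_mM = ca$rest_mM,
                 cao_mM = ca$cao_mM, cafac = cafac),
       ghk_fe = f_mV * efun, ghk_en = exp(nu),
       n = n, area_cm2 = area, temperature_c = temperature_c)
}

# Initial engine state: uniform voltage, gates at steady state, calcium at
# rest.
init_state <- function(em, model, v) {
  n <- em$n
  ngates <- sum(vapply(em$chans, function(c) length(c$gates), 1L))
  g <- matrix(0, n, max(ngates, 1))
  col <- 0
  for (ch in em$chans) {
    for (gt in ch$gates) {
      col <- col + 1
      idx <- round((v - gt$vshift - em$vmin) / em$dv) + 1
      idx <- pmin(pmax(idx, 1), length(gt$xinf))
      g[, col] <- gt$xinf[idx]
    }
  }
  if (ngates == 0) g <- matrix(0, n, 0)
  list(v = rep(v, n), gates = g, ca = rep(em$ca$rest_mM, n))
}

# Settle to steady state with the injection site clamped at the holding
# potential; returns the settled state and the constant bias current (nA)
# that holds the site there once the clamp is released.
settle_at_hold <- function(em, model, comp_idx, config) {
  st <- init_state(em, model, config$hold_mV)
  nsteps <- as.integer(round(config$settle_ms / config$dt_ms))
  out <- engine_run(em, st$v, st$gates, st$ca,
                    inj_nA = numeric(nsteps), inj_comp = -1L,
                    rec_comps = comp_idx - 1L,
                    record_every = config$record_every, dt = config$dt_ms,
                    clamp_comp = comp_idx - 1L, clamp_v = config$hold_mV)
  icl <- out$i_clamp_nA
  ntail <- max(2L, as.integer(round(100 / config$record_dt_ms)))
  bias_nA <- mean(utils::tail(icl, ntail))
  drift <- abs(icl[length(icl)] - mean(utils::tail(icl, ntail)))
  list(state = list(v = out$v_end, gates = out$gates_end, ca = out$ca_end),
       bias_nA = bias_nA, clamp_drift_nA = drift)
}

#' Map a path distance to the nearest compartment
#'
#' @param model a `cable_model`.
#' @param site_um path distance from the soma along the apical trunk (um);
#'   0 selects the soma.
#' @return compartment index.
#' @export
site_compartment <- function(model, site_um) {
  comp <- model$comp
  if (site_um <= 0) return(which(comp$type == "soma")[1])
  ap <- which(comp$type == "apical")
  if (length(ap) == 0) return(which(comp$type == "soma")[1])
  if (site_um > max(comp$x_um[ap] + comp$length_um[ap] / 2)) {
    stop("site beyond the end of the apical trunk", call. = FALSE)
  }
  ap[which.min(abs(comp$x_um[ap] - site_um))]
}

new_trace_set <- function(df, onset_ms, duration_ms, config, site_um,
                          comp_idx, bias_pA, suprathreshold, v_max,
                          f_start_hz = NA_real_, f_end_hz = NA_real_) {
  structure(df, class = c("trace_set", "data.frame"),
            onset_ms = onset_ms, duration_ms = duration_ms,
            record_dt_ms = config$record_dt_ms, site_um = site_um,
            comp = comp_idx, bias_pA = bias_pA,
            suprathreshold = suprathreshold, v_max = v_max,
            f_start_hz = f_start_hz, f_end_hz = f_end_hz)
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", nrow(x), "samples @", attr(x, "record_dt_ms"),
      "ms; site", attr(x, "site_um"), "um; stimulus",
      attr(x, "onset_ms"), "-", attr(x, "onset_ms") + attr(x, "duration_ms"),
      "ms\n")
  invisible(x)
}

# Shared protocol: settle at hold, then inject bias + stimulus at one site and
# record voltage and calcium locally.
run_injection <- function(model, stim_pA_fun, stim_dur_ms, site_um, config,
                          warn_init = TRUE, f_start_hz = NA_real_,
                          f_end_hz = NA_real_) {
  em <- compile_model(model, config$temperature_c)
  comp_idx <- site_compartment(model, site_um)
  settled <- settle_at_hold(em, model, comp_idx, config)
  dt <- config$dt_ms
  n_pre <- as.integer(round(config$pre_ms / dt))
  n_stim <- as.integer(round(stim_dur_ms / dt))
  n_post <- as.integer(round(config$post_ms / dt))
  t_stim <- (seq_len(n_stim) - 1) * dt
  inj <- c(numeric(n_pre), stim_pA_fun(t_stim) / 1e3, numeric(n_post)) +
    settled$bias_nA
  out <- engine_run(em, settled$state$v, settled$state$gates,
                    settled$state$ca, inj_nA = inj,
                    inj_comp = comp_idx - 1L, rec_comps = comp_idx - 1L,
                    record_every = config$record_every, dt = dt,
                    clamp_comp = -1L, clamp_v = 0)
  pre_idx <- which(out$t_ms < config$pre_ms)
  if (warn_init && length(pre_idx) > 1) {
    vend_pre <- out$v[max(pre_idx), 1]
    if (abs(vend_pre - config$hold_mV) > 0.1) {
      warning(sprintf(
        "initialization did not settle: V = %.2f mV at stimulus onset (hold %.1f mV)",
        vend_pre, config$hold_mV), call. = FALSE)
    }
  }
  supra <- out$v_max > -20
  if (supra) {
    warning("suprathreshold excursion during stimulus (V > -20 mV); analysis proceeds but is flagged",
            call. = FALSE)
  }
  df <- data.frame(time_ms = out$t_ms,
                   i_pA = (out$i_nA - settled$bias_nA) * 1e3,
                   v_mV = out$v[, 1],
                   ca_nM = out$ca[, 1] * 1e6)
  new_trace_set(df, onset_ms = config$pre_ms, duration_ms = stim_dur_ms,
                config = config, site_um = site_um, comp_idx = comp_idx,
                bias_pA = settled$bias_nA * 1e3, suprathreshold = supra,
                v_max = out$v_max, f_start_hz = f_start_hz,
                f_end_hz = f_end_hz)
}

#' Run a chirp-injection protocol
#'
#' Settles the model to steady state with the injection site held at the
#' holding potential (a voltage clamp whose final current becomes the
#' constant bias current), then injects bias + chirp at the site and records
#' the local voltage and intracellular calcium plus the injected current.
#'
#' @param model a `cable_model`.
#' @param stim a [chirp_stimulus()].
#' @param site_um injection/recording site as path distance from the soma
#'   (um); 0 = soma.
#' @param config a [sim_config()]. The stimulus `delay_s` overrides
#'   `pre_ms` when longer.
#' @return a `trace_set` with columns `time_ms`, `i_pA` (stimulus current,
#'   bias removed), `v_mV`, `ca_nM`.
#' @export
run_chirp <- function(model, stim = chirp_stimulus(), site_um = 0,
                      config = sim_config()) {
  config$pre_ms <- max(config$pre_ms, stim$delay_s * 1e3)
  run_injection(model,
                function(t_ms) chirp_current(stim, t_ms / 1e3),
                stim_dur_ms = stim$duration_s * 1e3,
                site_um = site_um, config = config,
                f_start_hz = stim$f_start_hz, f_end_hz = stim$f_end_hz)
}

#' Run a DC current step
#'
#' @param model a `cable_model`.
#' @param amp_pA step amplitude (pA).
#' @param dur_ms step duration (ms).
#' @param site_um injection/recording site (um).
#' @param config a [sim_config()].
#' @return a `trace_set`.
#' @export
run_step_current <- function(model, amp_pA = -10, dur_ms = 200, site_um = 0,
                             config = sim_config()) {
  run_injection(model, function(t_ms) rep(amp_pA, length(t_ms)),
                stim_dur_ms = dur_ms, site_um = site_um, config = config)
}

#' Run a single-frequency sinusoidal probe
#'
#' Steady-state single-frequency response; the per-frequency oracle against
#' which the chirp-FFT impedance estimate is validated.
#'
#' @param model a `cable_model`.
#' @param freq_hz probe frequency (Hz).
#' @param amp_pA amplitude (pA).
#' @param n_cycles number of cycles to run.
#' @param site_um injection/recording site (um).
#' @param config a [sim_config()].
#' @return a `trace_set`.
#' @export
run_sine <- function(model, freq_hz, amp_pA = 50, n_cycles = 12, site_um = 0,
                     config = sim_config()) {
  dur_ms <- n_cycles / freq_hz * 1e3
  run_injection(model,
                function(t_ms) amp_pA * sin(2 * pi * freq_hz * t_ms / 1e3),
                stim_dur_ms = dur_ms, site_um = site_um, config = config)
}

#' Measure DC input resistance from a current step
#'
#' @param model a `cable_model`.
#' @param amp_pA step amplitude (pA); small and hyperpolarizing by default.
#' @param dur_ms step duration (ms), long relative to the membrane time
#'   constant.
#' @param site_um site (um).
#' @param config a [sim_config()].
#' @return input resistance (MOhm).
#' @export
measure_input_resistance <- function(model, amp_pA = -10, dur_ms = 200,
                                     site_um = 0, config = sim_config()) {
  tr <- run_step_current(model, amp_pA, dur_ms, site_um, config)
  on <- attr(tr, "onset_ms")
  base <- mean(tr$v_mV[tr$time_ms >= on - 50 & tr$time_ms < on])
  tail_win <- tr$time_ms >= on + 0.9 * dur_ms & tr$time_ms < on + dur_ms
  vss <- mean(tr$v_mV[tail_win])
  (vss - base) / (amp_pA * 1e-3)  # mV/nA = MOhm
}

#' Write a trace set as tabular text
#'
#' One time column plus named trace columns, full double precision (%.17g):
#' the text round trip is bit-exact.
#'
#' @param traces a `trace_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  meta <- sprintf("# calres trace_set onset_ms=%.17g duration_ms=%.17g record_dt_ms=%.17g site_um=%.17g",
                  attr(traces, "onset_ms"), attr(traces, "duration_ms"),
                  attr(traces, "record_dt_ms"), attr(traces, "site_um"))
  cols <- names(traces)
  body <- do.call(paste, c(lapply(traces, function(x) sprintf("%.17g", x)),
                           sep = "\t"))
  writeLines(c(meta, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#' @param path input file.
#' @return a `trace_set`.
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  kv <- regmatches(first, gregexpr("[a-z_]+=[-0-9.e+]+", first))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          colClasses = "numeric")
  structure(df, class = c("trace_set", "data.frame"),
            onset_ms = meta[["onset_ms"]], duration_ms = meta[["duration_ms"]],
            record_dt_ms = meta[["record_dt_ms"]], site_um = meta[["site_um"]])
}

#' Binary trace-set round trip
#'
#' Compact container for long runs (RDS); bit-exact by construction.
#' @param traces a `trace_set`.
#' @param path output file.
#' @export
write_traces_bin <- function(traces, path) {
  saveRDS(traces, path)
  invisible(path)
}

#' @rdname write_traces_bin
#' @export
read_traces_bin <- function(path) readRDS(path)
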