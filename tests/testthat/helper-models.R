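# Shared model builders and a memo for expensive simulation runs reused
# across test files.

passive_single <- function(...) {
  build_single_compartment(channels = stats::setNames(numeric(0),
                                                      character(0)), ...)
}

cat_single <- function(scale = 1, extra = NULL, registry = default_channels(),
                       ...) {
  build_single_compartment(channels = c(c(CaT = 80e-6 * scale), extra),
                           registry = registry, ...)
}

.memo <- new.env(parent = emptyenv())

memo_run <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

# the default CaT-only chirp run, shared by several tests
default_cat_run <- function() {
  memo_run("cat_chirp", run_chirp(cat_single()))
}

passive_chirp_run <- function() {
  memo_run("passive_chirp", run_chirp(passive_single()))
}

# single-compartment passive constants used by analytic oracles
SC_AREA_CM2 <- pi * 60 * 60 * 1e-8
SC_RIN_MOHM <- 11e3 / SC_AREA_CM2 / 1e6   # Rm / (pi d L)
SC_TAU_MS <- 11                           # Rm * Cm

rc_closed_form <- function(f_hz, rin_mohm = SC_RIN_MOHM,
                           tau_ms = SC_TAU_MS) {
  rin_mohm / sqrt(1 + (2 * pi * f_hz * tau_ms * 1e-3)^2)
}

# synthetic trace set for analysis-only tests
synthetic_traces <- function(resp, stim, dt_ms = 0.25, onset_ms = 500,
                             duration_ms = 15000, f_end_hz = 15) {
  n <- length(resp)
  structure(
    data.frame(time_ms = (seq_len(n) - 1) * dt_ms, i_pA = stim,
               v_mV = resp, ca_nM = resp),
    class = c("trace_set", "data.frame"),
    onset_ms = onset_ms, duration_ms = duration_ms, record_dt_ms = dt_ms,
    site_um = 0, f_start_hz = 0, f_end_hz = f_end_hz)
}
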