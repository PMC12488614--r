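# Integrator physics: RC step response, convergence, conservation, calcium
# pool dynamics, initialization at the holding potential, trace IO.

test_that("the passive step response is the analytic RC charging curve", {
  m <- passive_single()
  tr <- run_step_current(m, amp_pA = 50, dur_ms = 100)
  on <- attr(tr, "onset_ms")
  v0 <- mean(tr$v_mV[tr$time_ms >= on - 50 & tr$time_ms < on])
  vss <- mean(tr$v_mV[tr$time_ms >= on + 90 & tr$time_ms < on + 100])
  expect_equal(vss - v0, 50e-3 * SC_RIN_MOHM, tolerance = 0.01)
  # one membrane time constant reaches 1 - 1/e of the step
  v_tau <- stats::approx(tr$time_ms, tr$v_mV, on + SC_TAU_MS)$y
  expect_equal((v_tau - v0) / (vss - v0), 1 - exp(-1), tolerance = 0.01)
  # passive model at its leak reversal needs no bias current
  expect_lt(abs(attr(tr, "bias_pA")), 1e-6)
})

test_that("DC input resistance reproduces Rm / (pi d L) = 97.3 MOhm", {
  rin <- memo_run("rin_sc", measure_input_resistance(passive_single()))
  expect_equal(rin, SC_RIN_MOHM, tolerance = 1e-3)
})

test_that("halving the time step leaves the passive trajectory unchanged", {
  m <- passive_single()
  cfg1 <- sim_config(dt_ms = 0.025, settle_ms = 200, pre_ms = 50,
                     post_ms = 0)
  cfg2 <- sim_config(dt_ms = 0.0125, settle_ms = 200, pre_ms = 50,
                     post_ms = 0)
  t1 <- run_step_current(m, 50, 1000, config = cfg1)
  t2 <- run_step_current(m, 50, 1000, config = cfg2)
  expect_lt(abs(t1$v_mV[nrow(t1)] - t2$v_mV[nrow(t2)]), 1e-6)
})

test_that("resonance measures converge in the time step", {
  m <- cat_single()
  r1 <- summarize_resonance(run_chirp(m, config = sim_config(dt_ms = 0.025)))
  r2 <- summarize_resonance(run_chirp(m, config = sim_config(dt_ms = 0.0125)))
  expect_true(all(abs(r1$f_R_hz - r2$f_R_hz) / r2$f_R_hz < 0.01))
  expect_true(all(abs(r1$Q - r2$Q) / r2$Q < 0.01))
})

test_that("with zero conductances and zero input, membrane charge is conserved", {
  cfg <- trunk_config(gna = 0, gkdr = 0, gka = linear_gradient(0, 0),
                      gh = sigmoid_gradient(0, 0, 320, 50),
                      gcat = sigmoid_gradient(0, 0, 350, 50))
  mm <- discretize(make_trunk(n_sections = 4), cfg)
  em <- compile_model(mm)
  em$gpas_uS <- rep(0, em$n)
  st <- calres:::init_state(em, mm, -65)
  st$v <- -65 + 5 * sin(seq_len(em$n))
  q0 <- sum(em$cm_nF * st$v)
  out <- calres:::engine_run(em, st$v, st$gates, st$ca, numeric(40000), -1L,
                             0L, 100L, 0.025, -1L, 0)
  expect_lt(abs(sum(em$cm_nF * out$v_end) - q0) / abs(q0), 1e-12)
  # and the voltages equilibrate toward a common value
  expect_lt(diff(range(out$v_end)), diff(range(st$v)))
})

test_that("the calcium pool decays exponentially and holds its fixed point", {
  pool <- ca_settings(tau_ms = 100)
  # pure decay from 200 nM: Ca(t) = 100 + 100 exp(-t/tau)
  ca <- 2e-4
  for (k in 1:1000) ca <- update_calcium(ca, 0, 0.1, pool)
  expect_equal(ca * 1e6, 100 + 100 * exp(-1), tolerance = 1e-6)
  expect_equal(update_calcium(1e-4, 0, 5, pool), 1e-4)
  # constant inward current: steady state rest + tau * influx
  i <- -1e-6
  flux <- -i / (2 * 96485.33212 * pool$depth_um * 1e-4)
  ca <- 1e-4
  for (k in 1:20000) ca <- update_calcium(ca, i, 0.5, pool)
  expect_equal(ca, 1e-4 + pool$tau_ms * flux, tolerance = 1e-9)
  # never negative, even under a strong outward (clearing) current
  expect_gte(update_calcium(1e-10, 1, 1000, pool), 0)
})

test_that("the engine's calcium matches the exported update on a zero-CaT model", {
  m <- passive_single()
  em <- compile_model(m)
  em$ca$on <- 1L
  st <- calres:::init_state(em, m, -65)
  st$ca <- 2e-4
  out <- calres:::engine_run(em, st$v, st$gates, st$ca, numeric(8000), -1L,
                             0L, 10L, 0.025, -1L, 0)
  cc <- out$ca[, 1] * 1e6
  expect_equal(stats::approx(out$t_ms, cc, 30)$y, 100 + 100 * exp(-30 / 30),
               tolerance = 1e-3)
})

test_that("initialization holds the site at -65 mV and calcium starts at rest", {
  m <- cat_single(extra = c(h = 25e-6, KA_prox = 3.1e-3))
  tr <- run_chirp(m)
  on <- attr(tr, "onset_ms")
  pre <- tr$time_ms < on & tr$time_ms >= on - 100
  expect_lt(max(abs(tr$v_mV[pre] + 65)), 0.1)
  expect_false(attr(tr, "suprathreshold"))
  # calcium is positive throughout and settles back toward its pre-stimulus
  # baseline after the chirp
  expect_true(all(tr$ca_nM > 0))
  base <- mean(tr$ca_nM[pre])
  tail_ca <- tr$ca_nM[tr$time_ms > on + attr(tr, "duration_ms") + 150]
  expect_lt(abs(mean(tail_ca) - base) / base, 0.01)
})

test_that("the subthreshold envelope stays within 5 mV for the default chirp", {
  tr <- default_cat_run()
  expect_lte(max(abs(tr$v_mV + 65)), 5)
})

test_that("trace sets round-trip bit-exactly through text and binary formats", {
  tr <- default_cat_run()
  f <- tempfile(fileext = ".tsv")
  write_traces(tr, f)
  back <- read_traces(f)
  expect_identical(unclass(back)$v_mV, unclass(tr)$v_mV)
  expect_identical(unclass(back)$ca_nM, unclass(tr)$ca_nM)
  expect_identical(unclass(back)$i_pA, unclass(tr)$i_pA)
  expect_equal(attr(back, "onset_ms"), attr(tr, "onset_ms"))
  fb <- tempfile(fileext = ".rds")
  write_traces_bin(tr, fb)
  expect_identical(read_traces_bin(fb), tr)
})

test_that("sites are mapped to trunk compartments and out-of-range sites rejected", {
  model <- build_trunk_model()
  expect_identical(site_compartment(model, 0),
                   which(model$comp$type == "soma")[1])
  i <- site_compartment(model, 200)
  expect_lt(abs(model$comp$x_um[i] - 200), model$comp$length_um[i])
  expect_error(site_compartment(model, 1e4), "beyond")
})
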