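# Gating curves, modifier hooks, GHK current law, channel assembly.

all_gates <- function() {
  reg <- default_channels()
  out <- list()
  for (ch in reg) for (g in ch$gates) {
    out[[paste(ch$name, g$name, sep = ".")]] <- g
  }
  out
}

test_that("steady-state curves are bounded, Boltzmann midpoints sit at V1/2", {
  v <- seq(-120, 60, by = 0.5)
  for (nm in names(all_gates())) {
    g <- all_gates()[[nm]]
    x <- gate_steady_state(g, v)
    expect_true(all(x >= 0 & x <= 1), info = nm)
    expect_equal(gate_steady_state(g, g$ss$vhalf), 0.5, tolerance = 1e-12,
                 info = nm)
    # activation curves rise, inactivation curves fall
    if (g$ss$k > 0) {
      expect_lt(gate_steady_state(g, -120), gate_steady_state(g, 40))
    } else {
      expect_gt(gate_steady_state(g, -120), gate_steady_state(g, 40))
    }
  }
})

test_that("a V1/2 shift translates both gating curves", {
  set.seed(42)
  vs <- stats::runif(20, -110, 40)
  for (g in all_gates()) {
    for (s in c(-10, 3.5, 10)) {
      gs <- g
      gs$v_half_shift <- s
      expect_equal(gate_steady_state(gs, vs + s), gate_steady_state(g, vs),
                   tolerance = 1e-12)
      expect_equal(gate_time_constant(gs, vs + s), gate_time_constant(g, vs),
                   tolerance = 1e-12)
    }
  }
})

test_that("time constants are positive, scale multiplicatively, and obey Q10", {
  v <- seq(-120, 60, by = 1)
  for (g in all_gates()) {
    tau <- gate_time_constant(g, v, temperature = 34)
    expect_true(all(tau > 0))
    g2 <- g
    g2$tau_scale <- 2
    expect_equal(gate_time_constant(g2, v), 2 * gate_time_constant(g, v),
                 tolerance = 1e-12)
    # at the scheme's reference temperature the base curve is returned
    expect_equal(gate_time_constant(g, v, temperature = g$tref),
                 g$tau_scale * eval_tau_form(g$tau, v), tolerance = 1e-12)
    # q10 = 3, ten degrees above reference -> tau / 3
    g3 <- g
    g3$q10 <- 3
    expect_equal(gate_time_constant(g3, v, temperature = g$tref + 10),
                 eval_tau_form(g$tau, v) / 3, tolerance = 1e-12)
  }
  bad <- all_gates()[[1]]
  bad$tau_scale <- 0
  expect_error(gate_time_constant(bad, -65), "tau_scale")
})

test_that("GHK current density has the right equilibria, sign and V->0 limit", {
  env_eq <- ghk_env(ca_out = 1, ca_in = 1)
  expect_equal(ghk_current_density(0, env_eq, 1e-6), 0)
  # physiological gradient at rest: inward (negative) current
  env <- ghk_env()
  expect_lt(ghk_current_density(-65, env, 1e-6), 0)
  # analytic V->0 limit: P z F (ci - co), concentrations in mol/cm^3
  p <- 1e-6
  lim <- 1e3 * p * 2 * 96485.33212 * (env$ca_in - env$ca_out) * 1e-6
  for (v in c(-1e-9, 1e-9)) {
    expect_equal(ghk_current_density(v, env, p), lim, tolerance = 1e-9)
  }
  # continuity across the removable singularity (finite relative slope,
  # ~(ci+co)/(2(ci-co)) * zF/RT per mV, no jump at V = 0)
  v <- seq(-0.01, 0.01, length.out = 2001)
  i <- ghk_current_density(v, env, p)
  expect_true(all(abs(diff(i)) < 1e-5 * max(abs(i))))
  expect_true(all(is.finite(ghk_driving(seq(-120, 60, 0.1)))))
})

test_that("channel currents: closed channels, reversal, h-current sign, errors", {
  reg <- default_channels()
  hch <- reg$h
  hch$density <- 25e-6
  expect_equal(channel_current(hch, -65, 0), 0)
  expect_equal(channel_current(hch, -30, 1), 0)  # at reversal
  expect_lt(channel_current(hch, -65, 1), 0)     # inward below -30 mV
  na <- reg$Na
  na$density <- 1e-3
  expect_error(channel_current(na, -65, c(0.5)), "gate")
  expect_error(channel_current(na, -65, c(0.5, 1.5)), "0, 1")
  cat_ch <- reg$CaT
  cat_ch$density <- 80e-6
  expect_equal(channel_current(cat_ch, -65, c(0, 0)), 0)
  expect_lt(channel_current(cat_ch, -65, c(0.5, 0.5)), 0)
  # total current continuous in v across [-120, 60], including v = 0
  v <- seq(-120, 60, by = 0.05)
  i <- vapply(v, function(vv) {
    st <- vapply(cat_ch$gates, gate_steady_state, numeric(1), v = vv)
    channel_current(cat_ch, vv, st)
  }, numeric(1))
  expect_true(all(abs(diff(i)) < 0.05 * (max(abs(i)) + 1e-12)))
})

test_that("the T-type window: activation and inactivation overlap subthreshold", {
  cat_ch <- default_channels()$CaT
  v <- seq(-120, 20, by = 0.25)
  act <- gate_steady_state(cat_ch$gates[[1]], v)
  inact <- gate_steady_state(cat_ch$gates[[2]], v)
  expect_true(any(act > 0.01 & inact > 0.01))
})

test_that("the registry loads, caches, and rejects bad modifier targets", {
  reg <- load_channel_registry()
  expect_setequal(names(reg), c("Na", "KDR", "KA_prox", "KA_dist", "h", "CaT"))
  expect_identical(default_channels(), default_channels())
  # printed reversal potentials
  expect_equal(reg$Na$erev, 55)
  expect_equal(reg$KDR$erev, -90)
  expect_equal(reg$KA_prox$erev, -90)
  expect_equal(reg$h$erev, -30)
  expect_identical(reg$CaT$current, "ghk")
  expect_equal(reg$CaT$valence, 2)
  # distal KA = proximal model with a hyperpolarized activation V1/2
  expect_lt(reg$KA_dist$gates[[1]]$ss$vhalf, reg$KA_prox$gates[[1]]$ss$vhalf)
  expect_error(modify_gate(reg, "CaT", "zz", tau_scale = 2), "gate")
  expect_error(modify_gate(reg, "Nope", "m", tau_scale = 2), "channel")
  expect_error(modify_gate(reg, "CaT", "m", tau_scale = -1), "tau_scale")
  m2 <- modify_gate(reg, "CaT", "m", v_half_shift = 5, tau_scale = 2)
  expect_equal(m2$CaT$gates[[1]]$v_half_shift, 5)
  expect_equal(m2$CaT$gates[[1]]$tau_scale, 2)
})
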