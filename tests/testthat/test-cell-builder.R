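# d-lambda discretization, the single-compartment cylinder, and gradient
# placement on the compartmental model.

test_that("lambda_100 follows its closed form and square-root scalings", {
  d <- 2; ra <- 120; cm <- 1
  expected <- 1e4 * 0.5 * sqrt(d * 1e-4 / (pi * 100 * ra * cm * 1e-6))
  expect_equal(lambda_100(d, ra, cm), expected, tolerance = 1e-12)
  expect_equal(lambda_100(4 * d, ra, cm), 2 * lambda_100(d, ra, cm),
               tolerance = 1e-12)
  expect_equal(lambda_100(d, 4 * ra, cm), lambda_100(d, ra, cm) / 2,
               tolerance = 1e-12)
  expect_error(lambda_100(0, ra, cm), "positive")
})

test_that("the d-lambda rule gives one compartment for electrically short sections", {
  lam <- lambda_100(60, 100, 1)
  expect_gt(0.1 * lam, 60)
  expect_equal(dlambda_nseg(60, lam), 1L)
  expect_equal(dlambda_nseg(0.05 * lam, lam), 1L)
  # counts are odd and grow with section length
  ns <- vapply(c(0.5, 1, 2, 5) * lam, dlambda_nseg, integer(1), lam = lam)
  expect_true(all(ns %% 2 == 1))
  expect_true(all(diff(ns) >= 0))
})

test_that("every discretized compartment is shorter than 0.1 lambda_100", {
  model <- build_trunk_model()
  comp <- model$comp
  lam <- lambda_100(comp$diam_um, comp$ra_ohm, comp$cm_uF)
  expect_true(all(comp$length_um < 0.1 * lam))
  expect_true(all(diff(comp$x_um[comp$type == "apical"]) >= 0))
  expect_identical(build_trunk_model(), build_trunk_model())
})

test_that("gradients land on the compartments: densities, KA switch, h V1/2", {
  model <- build_trunk_model()
  comp <- model$comp
  ap <- comp$type == "apical"
  x <- comp$x_um
  cfg <- trunk_config()
  expect_equal(model$dens[ap, "CaT"],
               sigmoid_density_at(cfg$gcat, x[ap]), tolerance = 1e-12)
  expect_equal(model$dens[ap, "h"],
               sigmoid_density_at(cfg$gh, x[ap]), tolerance = 1e-12)
  prox <- ap & x < 100
  dist <- ap & x >= 100
  expect_true(all(model$dens[prox, "KA_prox"] > 0))
  expect_true(all(model$dens[prox, "KA_dist"] == 0))
  expect_true(all(model$dens[dist, "KA_dist"] > 0))
  expect_true(all(model$dens[dist, "KA_prox"] == 0))
  expect_equal(model$gate_vshift$h[ap], h_vhalf_at(x[ap]) - (-82),
               tolerance = 1e-12)
  soma <- comp$type == "soma"
  expect_equal(unname(model$dens[soma, "KA_prox"]), 3.1e-3)
  expect_equal(unname(model$dens[soma, "CaT"]),
               sigmoid_density_at(cfg$gcat, 0))
  expect_equal(comp$rm_kohm[soma], passive_at(cfg$rm, 0))
  # passive gradients decrease along the trunk
  expect_true(all(diff(comp$rm_kohm[ap]) <= 0))
  expect_true(all(diff(comp$ra_ohm[ap]) <= 0))
})

test_that("basal and axonal compartments inherit somatic values as specified", {
  m <- make_trunk(basal = list(length_um = 150, diam_um = 2),
                  axon = list(length_um = 100, diam_um = 1))
  model <- discretize(m, trunk_config())
  comp <- model$comp
  bas <- comp$type == "basal"
  axn <- comp$type == "axon"
  expect_true(all(model$dens[bas, "KA_prox"] == 3.1e-3))
  expect_true(all(model$dens[bas, "h"] > 0))
  expect_true(all(model$dens[bas, "CaT"] > 0))
  expect_true(all(model$dens[axn, "Na"] > 0))
  expect_true(all(model$dens[axn, c("KA_prox", "KA_dist", "h", "CaT")] == 0))
  expect_equal(comp$rm_kohm[bas], rep(passive_at(trunk_config()$rm, 0),
                                      sum(bas)))
})

test_that("the single-compartment cylinder has the printed passive fingerprint", {
  m <- passive_single()
  expect_equal(nrow(m$comp), 1)
  expect_equal(m$comp$area_cm2, pi * 60 * 60 * 1e-8)
  expect_equal(input_resistance_closed_form(m), 97.26, tolerance = 1e-3)
  expect_equal(m$comp$rm_kohm * m$comp$cm_uF, 11)  # membrane tau, ms
  expect_error(build_single_compartment(channels = c(Bogus = 1)), "unknown")
})

test_that("trunk input resistance agrees with the sealed-end cable closed form", {
  cfg <- trunk_config(gna = 0, gkdr = 0, gka = linear_gradient(0, 0),
                      gh = sigmoid_gradient(0, 0, 320, 50),
                      gcat = sigmoid_gradient(0, 0, 350, 50),
                      rm = passive_gradient(125, 125, 300, 50),
                      ra = passive_gradient(120, 120, 300, 14))
  model <- discretize(make_trunk(), cfg)
  rin <- measure_input_resistance(model, dur_ms = 1000)
  rm <- 125e3; ra <- 120
  d_cm <- 1.75e-4                    # mean trunk diameter
  lam <- sqrt((rm / ra) * (d_cm / 4))
  r_inf <- 4 * ra / (pi * d_cm^2) * lam
  r_cable <- r_inf / tanh(425e-4 / lam)
  r_soma <- rm / (pi * 20 * 20 * 1e-8)
  r_par <- 1 / (1 / r_soma + 1 / r_cable) / 1e6
  expect_lt(abs(rin - r_par) / r_par, 0.2)
})
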