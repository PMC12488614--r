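# Impedance estimators and resonance measures: scaling, linearity, synthetic
# argmax, no-resonance flagging, and the RLC fixture oracle.

test_that("an instantaneous linear response gives a flat profile at the gain", {
  stim <- chirp_current(chirp_stimulus(), seq(0, 15, by = 0.25e-3))
  n_pre <- 2000; n_post <- 800
  s <- c(numeric(n_pre), stim, numeric(n_post))
  tr <- synthetic_traces(resp = 3 * s, stim = s)
  for (meth in c("fft", "swept")) {
    p <- impedance(tr, "calcium", method = meth)  # ca: no unit rescale
    expect_true(all(abs(p$mag - 3) < 0.02 * 3), info = meth)
    expect_equal(resonance_strength(p), 1, tolerance = 0.02)
  }
})

test_that("impedance is linear: doubling the response doubles |Z| only", {
  tr <- default_cat_run()
  tr2 <- tr
  tr2$v_mV <- -65 + 2 * (tr$v_mV + 65)
  p1 <- impedance(tr, "voltage")
  p2 <- impedance(tr2, "voltage")
  expect_equal(p2$mag, 2 * p1$mag, tolerance = 1e-9)
  expect_equal(as.numeric(resonance_frequency(p2)),
               as.numeric(resonance_frequency(p1)), tolerance = 1e-9)
  expect_equal(resonance_strength(p2), resonance_strength(p1),
               tolerance = 1e-9)
})

test_that("peak extraction: synthetic bump, ties, and low-pass flagging", {
  f <- seq(0.5, 15, by = 1 / 15)
  bump <- exp(-((f - 6) / 2)^2)
  prof <- structure(
    data.frame(freq_hz = f, mag = bump, mag_smooth = bump),
    class = c("impedance_profile", "data.frame"),
    resolution_hz = 1 / 15, band = c(0.5, 15))
  fr <- resonance_frequency(prof)
  expect_equal(as.numeric(fr), 6, tolerance = 0.01)
  expect_false(attr(fr, "no_resonance"))
  # strictly decreasing (passive-like) profile: band edge + flag
  dec <- structure(
    data.frame(freq_hz = f, mag = 1 / (1 + f), mag_smooth = 1 / (1 + f)),
    class = c("impedance_profile", "data.frame"),
    resolution_hz = 1 / 15, band = c(0.5, 15))
  fd <- resonance_frequency(dec)
  expect_equal(as.numeric(fd), 0.5)
  expect_true(attr(fd, "no_resonance"))
  # flat profile: Q exactly 1
  flat <- dec
  flat$mag <- flat$mag_smooth <- rep(2, length(f))
  expect_equal(resonance_strength(flat), 1)
})

test_that("a passive chirp run is flagged as non-resonant", {
  # both estimators: any apparent maximum is within estimator ripple of the
  # band edge -> flagged, and located at the bottom of the band
  for (meth in c("swept", "fft")) {
    p <- impedance(passive_chirp_run(), "voltage", method = meth)
    fr <- resonance_frequency(p)
    expect_true(attr(fr, "no_resonance"), info = meth)
    expect_lt(as.numeric(fr), 2)
    expect_lt(resonance_strength(p), 1.01)
  }
})

test_that("zero stimulus content inside the band is rejected", {
  n <- 63000
  tr <- synthetic_traces(resp = rep(1, n), stim = rep(0, n))
  expect_error(impedance(tr, "voltage"), "spectral content")
})

test_that("the RLC fixture oracle: analysis recovers the closed form", {
  fx <- rlc_fixture()
  oracle <- rlc_resonance(fx)
  tr <- make_rlc_trace(fx)
  p <- impedance(tr, "voltage", method = "fft")
  # |Z| magnitude against the closed form at every band frequency
  zc <- Mod(rlc_impedance(fx, p$freq_hz))
  interior <- p$freq_hz <= 14
  expect_true(all(abs(p$mag - zc)[interior] / zc[interior] < 0.05))
  expect_lt(abs(as.numeric(resonance_frequency(p)) - oracle$f_R_hz),
            3 * attr(p, "resolution_hz"))
  expect_equal(resonance_strength(p), oracle$Q, tolerance = 0.02)
  # the swept estimator agrees with the closed form on this linear fixture
  ps <- impedance(tr, "voltage", method = "swept")
  zs <- Mod(rlc_impedance(fx, ps$freq_hz))
  mid <- ps$freq_hz > 1 & ps$freq_hz < 14
  expect_true(all(abs(ps$mag - zs)[mid] / zs[mid] < 0.03))
  # inductive branch off: the pure RC low-pass closed form, at the FFT
  # chirp estimator's accuracy floor (same 2% bound as the membrane RC
  # oracle)
  fx0 <- rlc_fixture(c = 0.1, inductive = FALSE)
  tr0 <- make_rlc_trace(fx0)
  p0 <- impedance(tr0, "voltage", method = "fft")
  z0 <- Mod(rlc_impedance(fx0, p0$freq_hz))
  int0 <- p0$freq_hz <= 14
  expect_true(all(abs(p0$mag - z0)[int0] / z0[int0] < 0.02))
  # the swept estimator on the same trace
  ps0 <- impedance(tr0, "voltage", method = "swept")
  zs0 <- Mod(rlc_impedance(fx0, ps0$freq_hz))
  mid0 <- ps0$freq_hz > 1 & ps0$freq_hz < 14
  expect_true(all(abs(ps0$mag - zs0)[mid0] / zs0[mid0] < 0.02))
  expect_true(attr(resonance_frequency(impedance(tr0, "voltage",
                                                 method = "swept")),
                   "no_resonance"))
})

test_that("the RLC fixture itself has a unique interior maximum when inductive", {
  f <- seq(0.5, 15, by = 0.01)
  m <- Mod(rlc_impedance(rlc_fixture(), f))
  i <- which.max(m)
  expect_gt(i, 1)
  expect_lt(i, length(f))
  expect_true(all(diff(m[1:i]) > 0))
  expect_true(all(diff(m[i:length(m)]) < 0))
})
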