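mk_raw <- function(v, fs = 400, t = seq(0, 20, by = 1 / fs)) {
  structure(data.frame(time_s = t, v_mV = v), sample_rate_hz = fs,
            class = c("raw_signal", "data.frame"))
}
valid_of <- function(d) d[d$valid, ]

test_that("lock-in separates DC, in-phase and quadrature components", {
  fs <- 400
  t <- seq(0, 20, by = 1 / fs)
  car <- carrier_config()
  cfg <- demod_config()

  d1 <- valid_of(lockin_demodulate(mk_raw(rep(0.5, length(t))), car, cfg))
  expect_equal(mean(d1$dc_mV), 0.5, tolerance = 1e-6)
  expect_lt(max(abs(d1$v_inphase_mV)), 1e-6)
  expect_lt(max(abs(d1$v_quad_mV)), 1e-6)

  d2 <- valid_of(lockin_demodulate(mk_raw(0.2 * sin(2 * pi * 20 * t)),
                                   car, cfg))
  expect_equal(mean(d2$v_inphase_mV), 0.2, tolerance = 1e-4)
  expect_lt(max(abs(d2$v_quad_mV)), 0.002)
  expect_lt(max(abs(d2$dc_mV)), 0.002)

  d3 <- valid_of(lockin_demodulate(
    mk_raw(0.1 * cos(2 * pi * 20 * t) + 0.3), car, cfg))
  expect_equal(mean(d3$dc_mV), 0.3, tolerance = 1e-4)
  expect_equal(mean(d3$v_quad_mV), 0.1, tolerance = 1e-4)
  expect_lt(max(abs(d3$v_inphase_mV)), 0.002)
})

test_that("a pure quadrature tone leaks under 1% into the in-phase channel", {
  fs <- 400
  t <- seq(0, 20, by = 1 / fs)
  d <- valid_of(lockin_demodulate(mk_raw(cos(2 * pi * 20 * t)),
                                  carrier_config(), demod_config()))
  expect_lt(max(abs(d$v_inphase_mV)), 0.01)
  d2 <- valid_of(lockin_demodulate(mk_raw(sin(2 * pi * 20 * t)),
                                   carrier_config(), demod_config()))
  expect_lt(max(abs(d2$v_quad_mV)), 0.01)
})

test_that("a DC offset moves only the DC output", {
  fs <- 400
  t <- seq(0, 20, by = 1 / fs)
  v <- 0.7 * sin(2 * pi * 20 * t + 0.3)
  a <- valid_of(lockin_demodulate(mk_raw(v), carrier_config(),
                                  demod_config()))
  b <- valid_of(lockin_demodulate(mk_raw(v + 2.5), carrier_config(),
                                  demod_config()))
  # offset leakage into the AC channels is bounded by the stopband: < 1e-5
  # of the 2.5 mV offset
  expect_lt(max(abs(b$v_inphase_mV - a$v_inphase_mV)), 2.5e-5)
  expect_lt(max(abs(b$v_quad_mV - a$v_quad_mV)), 2.5e-5)
  expect_equal(mean(b$dc_mV[b$valid] - a$dc_mV[a$valid]), 2.5,
               tolerance = 1e-6)
})

test_that("recovered carrier amplitude is independent of the reference phase", {
  fs <- 400
  t <- seq(0, 20, by = 1 / fs)
  v <- 0.8 * sin(2 * pi * 20 * t + 1.1)
  for (ph in c(0, 0.7, -2)) {
    d <- valid_of(lockin_demodulate(mk_raw(v),
                                    carrier_config(phase_ref_rad = ph),
                                    demod_config()))
    expect_equal(mean(sqrt(d$v_inphase_mV^2 + d$v_quad_mV^2)), 0.8,
                 tolerance = 1e-4)
  }
})

test_that("a slow amplitude ramp is tracked, matching an STFT oracle", {
  fs <- 400
  t <- seq(0, 60, by = 1 / fs)
  env <- 1 + 0.05 * t  # slow ramp in carrier amplitude (mV)
  v <- env * sin(2 * pi * 20 * t)
  d <- lockin_demodulate(mk_raw(v, t = t), carrier_config(), demod_config())
  # oracle: windowed DFT magnitude at 20 Hz around a few interior times
  stft_amp <- function(t0, half = 1) {
    i <- which(t >= t0 - half & t < t0 + half)
    2 * Mod(sum(v[i] * exp(-2i * pi * 20 * t[i]))) / length(i)
  }
  for (t0 in c(15, 30, 45)) {
    got <- d$v_inphase_mV[which.min(abs(d$time_s - t0))]
    expect_equal(got, stft_amp(t0), tolerance = 0.01)
  }
})

test_that("phasors convert to admittance by complex division", {
  adm <- phasor_to_admittance(1000, 0, carrier_config())
  expect_equal(adm$g_uS, 20)
  expect_equal(adm$b_uS, 0)
  # V = 1000/sqrt(2) mV at -45 degrees -> G = B = 20 uS
  adm2 <- phasor_to_admittance(500, -500, carrier_config())
  expect_equal(adm2$g_uS, 20)
  expect_equal(adm2$b_uS, 20)
  expect_error(phasor_to_admittance(0, 0), "undefined")
})

test_that("carrier round trip recovers stationary admittance within 1%", {
  fs <- 400
  t <- seq(0, 30, by = 1 / fs)
  n <- length(t)
  tr <- structure(data.frame(time_s = t, sc_uS = rep(12, n),
                             ss_uS = rep(4, n), sp_mV = rep(-18, n)),
                  sample_rate_hz = fs,
                  class = c("component_traces", "data.frame"))
  raw <- synthesize_raw_carrier(tr, carrier_config())
  dm <- demodulate_to_traces(raw, carrier_config(), demod_config())
  dm <- dm[dm$time_s > 5 & dm$time_s < 25, ]
  expect_lt(max(abs(dm$sc_uS / 12 - 1)), 0.01)
  expect_lt(max(abs(dm$ss_uS / 4 - 1)), 0.01)
  expect_lt(max(abs(dm$sp_mV - (-18))), 0.1)
})

test_that("reference phase can be calibrated from a stationary segment", {
  fs <- 400
  t <- seq(0, 20, by = 1 / fs)
  true_ph <- 0.6
  v <- 0.9 * sin(2 * pi * 20 * t + true_ph)
  est <- estimate_phase_ref(mk_raw(v), carrier_config(), demod_config(),
                            segment_s = c(6, 18))
  expect_equal(est, true_ph, tolerance = 1e-3)
})

test_that("inseparable configurations are rejected", {
  expect_error(demod_config(lp_cutoff_hz = 0), "> 0")
  fs <- 30
  t <- seq(0, 2, by = 1 / fs)
  expect_error(
    lockin_demodulate(mk_raw(sin(2 * pi * 20 * t), fs = fs, t = t),
                      carrier_config(), demod_config()),
    "twice the carrier")
  t400 <- seq(0, 2, by = 1 / 400)
  expect_error(
    lockin_demodulate(mk_raw(sin(2 * pi * 20 * t400), fs = 400, t = t400),
                      carrier_config(),
                      demod_config(lp_cutoff_hz = 25)),
    "below the carrier")
})
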