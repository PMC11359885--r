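test_that("SPRET follows its defining formula", {
  scr <- mk_response("SC", onset_t = 1, onset_v = 2, peak_t = 4, peak_v = 3)
  spr <- mk_response("SP", onset_t = 1.5, onset_v = -20, peak_t = 5,
                     peak_v = -21, shape = "monophasic_neg")
  expect_equal(spret(scr, spr), 100 * (5 - 4) / 3)  # +33.33%

  spr_eq <- mk_response("SP", 1.5, -20, 4, -21, shape = "monophasic_neg")
  expect_equal(spret(scr, spr_eq), 0)

  scr2 <- mk_response("SC", 2, 2, 6, 3)
  spr2 <- mk_response("SP", 2.5, -20, 5, -21, shape = "monophasic_neg")
  expect_equal(spret(scr2, spr2), -25)

  # biphasic SPR anchors on the second (terminal) peak
  spr_b <- mk_response("SP", 1.5, -20, 4.5, -19.5, shape = "biphasic",
                       second_t = 5, second_v = -21)
  expect_equal(spret(scr, spr_b), 100 * (5 - 4) / 3)
})

test_that("amplitudes follow the onset-to-peak and peak-to-peak rules", {
  sc <- mk_response("SC", 1, 2.0, 4, 3.5)
  expect_equal(response_amplitude(sc), 1.5)
  sp <- mk_response("SP", 1, -20.0, 4, -21.4, shape = "monophasic_neg")
  expect_equal(response_amplitude(sp), -1.4)
  # biphasic: first peak +0.5, second -1.0 (relative to onset) -> -1.5
  spb <- mk_response("SP", 1, 0, 2, 0.5, shape = "biphasic",
                     second_t = 4, second_v = -1.0)
  expect_equal(response_amplitude(spb), -1.5)
})

test_that("SCR rise time is peak minus onset time", {
  sc <- mk_response("SC", 61.5, 2, 64.5, 3.2)
  expect_equal(scr_tris(sc), 3.0)
  expect_error(scr_tris(mk_response("SP", 1, 0, 2, 1)), "SC")
})

test_that("flat traces yield no responses but a complete record set", {
  p <- build_protocol()
  fs <- 20
  t <- seq(0, p$total_s, by = 1 / fs)
  tr <- structure(data.frame(time_s = t, sc_uS = rep(10, length(t)),
                             ss_uS = rep(5, length(t)),
                             sp_mV = rep(-20, length(t))),
                  sample_rate_hz = fs,
                  class = c("component_traces", "data.frame"))
  ev <- p$events[1, ]; ev$event_index <- 1L
  expect_null(detect_response(tr, "sc", ev))
  ft <- build_feature_table(tr, p, subject_id = 7L)
  expect_equal(nrow(ft), 5)
  expect_true(all(is.na(ft$scr_amp_uS)))
  expect_true(all(is.na(ft$spret_pct)))
  expect_equal(ft$subject_id, rep(7L, 5))
})

test_that("an empty protocol gives an empty feature table", {
  p <- build_protocol()
  p$events <- p$events[0, ]
  t <- seq(0, 10, by = 0.05)
  tr <- structure(data.frame(time_s = t, sc_uS = rep(10, length(t)),
                             ss_uS = rep(5, length(t)),
                             sp_mV = rep(-20, length(t))),
                  sample_rate_hz = 20,
                  class = c("component_traces", "data.frame"))
  ft <- build_feature_table(tr, p)
  expect_equal(nrow(ft), 0)
})

test_that("a missing channel column is reported by name", {
  p <- build_protocol()
  tr <- data.frame(time_s = seq(0, 385, 0.05), sc_uS = 10, ss_uS = 5)
  expect_error(build_feature_table(tr, p), "sp_mV")
})

test_that("detection recovers generator ground truth on clean traces", {
  co <- cached_cohort("rt6", generator_config(n_subjects = 6, seed = 42))
  fs <- co$config$sample_rate_hz
  n_ev <- 0; n_time_ok <- 0
  for (s in 1:6) {
    tr <- synthesize_traces(co$protocol, co$truth, co$config, subject = s)
    ft <- build_feature_table(tr, co$protocol, subject_id = s)
    tru <- co$truth[co$truth$subject_id == s, ]
    rs <- attr(ft, "responses")
    # amplitudes within 5% relative
    expect_equal(ft$scr_amp_uS, tru$scr_amp_uS, tolerance = 0.05)
    expect_equal(ft$spr_amp_mV, tru$spr_amp_mV, tolerance = 0.05)
    expect_equal(ft$ssr_amp_uS, tru$ssr_amp_uS, tolerance = 0.05)
    expect_equal(ft$spr_shape, tru$spr_shape)
    onset_err <- abs(vapply(rs, function(r) r$sc$onset_t_s, 1) -
                       tru$scr_onset_s)
    peak_err <- abs(vapply(rs, function(r) r$sc$peak_t_s, 1) -
                      tru$scr_peak_s)
    n_ev <- n_ev + 2 * length(onset_err)
    n_time_ok <- n_time_ok + sum(onset_err <= 1 / fs + 1e-9) +
      sum(peak_err <= 1 / fs + 1e-9)
  }
  # onset/peak located within one sample period for >= 99% of events
  expect_gte(n_time_ok / n_ev, 0.99)
})

test_that("features are invariant to a joint time shift", {
  co <- cached_cohort("rt6", generator_config(n_subjects = 6, seed = 42))
  tr <- synthesize_traces(co$protocol, co$truth, co$config, subject = 1)
  ft0 <- build_feature_table(tr, co$protocol, subject_id = 1)
  dt <- 13.7
  tr2 <- tr
  tr2$time_s <- tr$time_s + dt
  p2 <- co$protocol
  p2$events$onset_s <- p2$events$onset_s + dt
  ft1 <- build_feature_table(tr2, p2, subject_id = 1)
  for (cl in c("scr_amp_uS", "spr_amp_mV", "ssr_amp_uS", "scr_tris_s",
               "spret_pct"))
    expect_equal(ft1[[cl]], ft0[[cl]], tolerance = 1e-9)
})

test_that("scaling a channel's phasic part scales only its amplitude", {
  co <- cached_cohort("rt6", generator_config(n_subjects = 6, seed = 42))
  tr <- synthesize_traces(co$protocol, co$truth, co$config, subject = 3)
  ft0 <- build_feature_table(tr, co$protocol, subject_id = 3)
  cc <- 1.8
  tr2 <- tr
  tr2$sc_uS <- co$config$tonic_sc_uS + cc * (tr$sc_uS - co$config$tonic_sc_uS)
  ft1 <- build_feature_table(tr2, co$protocol, subject_id = 3)
  expect_equal(ft1$scr_amp_uS, cc * ft0$scr_amp_uS, tolerance = 1e-6)
  expect_equal(ft1$scr_tris_s, ft0$scr_tris_s, tolerance = 1e-9)
  expect_equal(ft1$spret_pct, ft0$spret_pct, tolerance = 1e-9)
  expect_equal(ft1$spr_amp_mV, ft0$spr_amp_mV, tolerance = 1e-9)
})
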