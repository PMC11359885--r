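mk_features <- function(means, levels_db = c(70, 75, 80, 85, 90)) {
  data.frame(subject_id = 1L, event_index = seq_along(levels_db),
             level_db = levels_db, scr_amp_uS = means)
}

test_that("linear amplitude-level fit recovers exact coefficients", {
  x <- 0:4
  m <- fit_amplitude_vs_level(mk_features(1.5 + 0.8 * x), "linear")
  expect_equal(unname(m$params["a"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(m$params["b"]), 0.8, tolerance = 1e-12)
  expect_equal(m$fit_rss, 0, tolerance = 1e-20)
  expect_equal(unname(predict(m, 85)), 1.5 + 0.8 * 3)
})

test_that("exponential fit recovers exact coefficients from clean means", {
  x <- 0:4
  m <- fit_amplitude_vs_level(mk_features(0.5 * exp(0.4 * x)),
                              "exponential")
  expect_equal(unname(m$params["a"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(m$params["b"]), 0.4, tolerance = 1e-6)
})

test_that("exponential fit beats a brute-force parameter grid", {
  co <- cached_cohort("preset_s3", generator_config(seed = 3))
  m <- fit_amplitude_vs_level(co$features, "exponential")
  ok <- !is.na(co$features$scr_amp_uS)
  means <- tapply(co$features$scr_amp_uS[ok], co$features$level_db[ok],
                  mean)
  x <- (as.numeric(names(means)) - 70) / 5
  y <- as.numeric(means)
  grid_rss <- min(outer(seq(0.1, 10, by = 0.02), seq(-1, 1, by = 0.005),
                        Vectorize(function(a, b)
                          sum((y - a * exp(b * x))^2))))
  expect_lte(m$fit_rss, grid_rss + 1e-8)
})

test_that("exponential form falls back to linear on non-positive means", {
  expect_warning(
    m <- fit_amplitude_vs_level(mk_features(c(-1, 0, 1, 2, 3)),
                                "exponential"),
    "falling back")
  expect_equal(m$form, "linear")
  expect_equal(m$status, "fallback_linear")
})

test_that("fewer than 3 levels is rejected", {
  expect_error(fit_amplitude_vs_level(mk_features(c(1, 2), c(70, 75))),
               ">= 3")
})

test_that("responses attribute to the nearest preceding event", {
  ev <- data.frame(onset_s = c(10, 13), level_db = c(70, 80))
  # no events
  r0 <- attribute_responses(data.frame(onset_t_s = 12), ev[0, ])
  expect_true(is.na(r0$attributed_event))
  # response 2 s after a lone event
  r1 <- attribute_responses(data.frame(onset_t_s = 12), ev[1, , drop = FALSE])
  expect_equal(r1$attributed_event, 1L)
  # two events 3 s apart, response 4 s after the first -> nearest preceding
  r2 <- attribute_responses(data.frame(onset_t_s = 14), ev)
  expect_equal(r2$attributed_event, 2L)
  expect_equal(r2$attributed_level_db, 80)
  # outside the latency window -> unattributed
  r3 <- attribute_responses(data.frame(onset_t_s = 30), ev)
  expect_true(is.na(r3$attributed_event))
})

test_that("binned correction obeys its defining identity", {
  ev <- data.frame(onset_s = c(50, 400), level_db = c(70, 90))
  model <- fit_amplitude_vs_level(mk_features(2 + 1 * (0:4)), "linear")
  resp <- data.frame(onset_t_s = c(52, 200, 402), amplitude = c(2, 5, 6))
  cr <- correct_bins(resp, ev, model, bin_s = 300, total_s = 600)
  expect_equal(cr$corrected_score, cr$raw_score - cr$noise_elicited_score)
  expect_true(all(cr$n_attributed <= cr$n_responses))
  # bin 1: responses 2 (attributed, predicted 2) + 5 (intrinsic)
  expect_equal(cr$raw_score[1], 7)
  expect_equal(cr$noise_elicited_score[1], 2)
  expect_equal(cr$corrected_score[1], 5)
  # bin 2: one attributed response at 90 dB, prediction 6 -> corrected 0
  expect_equal(cr$corrected_score[2], 0)
})

test_that("with no attributed responses correction is the identity", {
  ev <- data.frame(onset_s = numeric(0), level_db = numeric(0))
  model <- fit_amplitude_vs_level(mk_features(2 + 1 * (0:4)), "linear")
  resp <- data.frame(onset_t_s = c(10, 350), amplitude = c(1, 2))
  cr <- correct_bins(resp, ev, model, bin_s = 300, total_s = 600)
  expect_equal(cr$corrected_score, cr$raw_score)
  expect_equal(cr$n_attributed, c(0L, 0L))
})

test_that("perfect model on noise-only activity cancels the score", {
  cfg <- noise_free_config(n_subjects = 1, seed = 5)
  co <- generate_feature_table(cfg)
  model <- fit_amplitude_vs_level(co$features, "linear")
  resp <- data.frame(onset_t_s = co$truth$scr_onset_s,
                     amplitude = co$truth$scr_amp_uS)
  cr <- correct_bins(resp, co$protocol$events, model, bin_s = 300,
                     total_s = co$protocol$total_s)
  expect_lt(mean(abs(cr$corrected_score)), 0.05 * mean(cr$raw_score))
})

test_that("correction is additive over disjoint recordings", {
  model <- fit_amplitude_vs_level(mk_features(2 + 1 * (0:4)), "linear")
  ev_a <- data.frame(onset_s = c(40, 110), level_db = c(70, 85))
  ev_b <- data.frame(onset_s = c(640, 820), level_db = c(75, 90))
  r_a <- data.frame(onset_t_s = c(42, 113, 250), amplitude = c(2, 4, 1))
  r_b <- data.frame(onset_t_s = c(642, 822.5, 901), amplitude = c(3, 6, 2))
  both <- correct_bins(rbind(r_a, r_b), rbind(ev_a, ev_b), model,
                       bin_s = 300, total_s = 1200)
  a <- correct_bins(r_a, ev_a, model, bin_s = 300, total_s = 1200)
  b <- correct_bins(r_b, ev_b, model, bin_s = 300, total_s = 1200)
  expect_equal(both$raw_score, a$raw_score + b$raw_score)
  expect_equal(both$corrected_score, a$corrected_score + b$corrected_score)
})

test_that("both model forms are monotone in dB for positive rate", {
  lin <- fit_amplitude_vs_level(mk_features(1 + 0.5 * (0:4)), "linear")
  ex <- fit_amplitude_vs_level(mk_features(0.5 * exp(0.3 * (0:4))),
                               "exponential")
  lv <- seq(70, 90, by = 1)
  expect_true(all(diff(predict(lin, lv)) >= 0))
  expect_true(all(diff(predict(ex, lv)) >= 0))
})

test_that("extrapolation beyond the fitted range warns", {
  m <- fit_amplitude_vs_level(mk_features(1 + 0.5 * (0:4)), "linear")
  expect_warning(predict(m, 95), "extrapolation")
})
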