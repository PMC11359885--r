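# shared fixtures: built in code, cached per test run

zero_sd_vec <- function() {
  stats::setNames(rep(0, 5), c("scr_amp_uS", "spr_amp_mV", "ssr_amp_uS",
                               "scr_tris_s", "spret_pct"))
}

# generator config with all subject-level and residual variation off
noise_free_config <- function(...) {
  generator_config(random_sd_intercept = zero_sd_vec(),
                   random_sd_slope = zero_sd_vec(),
                   residual_sd = zero_sd_vec(), ...)
}

# a single-subject truth row with hand-set geometry, for trace tests
manual_truth <- function(scr_amp = 3, tris = 2.5, spr_amp = -1.4,
                         ssr_amp = -0.5, spret = 20, shape = "monophasic_neg",
                         onset = 61.5) {
  data.frame(subject_id = 1L, event_index = 1L, level_db = 70,
             scr_amp_uS = scr_amp, spr_amp_mV = spr_amp,
             ssr_amp_uS = ssr_amp, scr_tris_s = tris, spret_pct = spret,
             spr_shape = shape,
             scr_onset_s = onset, scr_peak_s = onset + tris,
             spr_onset_s = onset + spret * tris / 100,
             spr_peak_s = onset + tris + spret * tris / 100,
             spr_first_peak_s = if (shape == "biphasic")
               onset + spret * tris / 100 + 0.35 * tris else NA_real_,
             ss_onset_s = onset, ss_peak_s = onset + 0.8 * tris,
             stringsAsFactors = FALSE)
}

# manual eda_response constructor for formula-level tests
mk_response <- function(channel, onset_t, onset_v, peak_t, peak_v,
                        shape = "monophasic_pos", second_t = NA_real_,
                        second_v = NA_real_) {
  amp <- if (shape == "biphasic") second_v - peak_v else peak_v - onset_v
  structure(list(channel = channel, event_index = 1L,
                 onset_t_s = onset_t, onset_value = onset_v,
                 peak_t_s = peak_t, peak_value = peak_v,
                 second_peak_t_s = second_t, second_peak_value = second_v,
                 shape = shape, amplitude = amp),
            class = "eda_response")
}

cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(cohort_cache[[key]]))
    cohort_cache[[key]] <- generate_feature_table(config)
  cohort_cache[[key]]
}
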