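FEATURES <- c("scr_amp_uS", "spr_amp_mV", "ssr_amp_uS", "scr_tris_s",
              "spret_pct")

named_feature_vec <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) != length(FEATURES))
      stop(sprintf("`%s` must be named or of length %d", what,
                   length(FEATURES)))
    names(x) <- FEATURES
  }
  miss <- setdiff(FEATURES, names(x))
  if (length(miss)) stop(sprintf("`%s` missing feature(s): %s", what,
                                 paste(miss, collapse = ", ")))
  x[FEATURES]
}

#' Configuration for the synthetic EDA cohort generator
#'
#' The defaults are the calibrated preset used throughout the package:
#' 40 subjects exposed to five 5 s noise stimuli at 70-90 dB SPL, with the
#' per-5-dB fixed-effect slopes set to +1.2 uS (SCR amplitude), -0.7 mV
#' (SPR amplitude), -0.2 uS (SSR amplitude), +0.4 s (SCR rise time) and
#' +7.3% (SPRET). Noise level is coded as `x = (dB - 70)/5`, so slopes are
#' directly "per 5 dB step". Each feature follows
#' `y = (b0 + u0_i) + (b1 + u1_i) x + e` with subject-level
#' `(u0, u1)` bivariate normal and independent residuals.
#'
#' @param n_subjects Number of simulated subjects.
#' @param levels_db Strictly increasing stimulus levels (dB SPL).
#' @param fixed_intercepts Named per-feature fixed intercepts (value at
#'   70 dB), in feature units.
#' @param fixed_slopes_per5db Named per-feature fixed slopes per 5 dB step.
#' @param random_sd_intercept,random_sd_slope Named per-feature SDs of the
#'   subject-level random intercepts and slopes (`>= 0`).
#' @param random_corr Correlation between random intercept and slope,
#'   in `[-1, 1]`.
#' @param residual_sd Named per-feature residual SDs (`>= 0`).
#' @param tonic_sc_uS,tonic_ss_uS,tonic_sp_mV Tonic channel baselines.
#' @param drift_sd SD of an optional slow baseline drift added to rendered
#'   traces (channel units); 0 disables drift.
#' @param spr_biphasic_prob Probability that a simulated skin potential
#'   response is biphasic, in `[0, 1]`.
#' @param kernel_tau_rise_s,kernel_tau_decay_s Bateman kernel time constants
#'   before per-response time scaling (s).
#' @param onset_latency_s Length-2 range (s) of the uniform post-stimulus
#'   response-onset latency.
#' @param sample_rate_hz Sampling rate for rendered component traces (Hz).
#' @param seed Integer RNG seed; identical configs give identical cohorts.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 40,
    levels_db = c(70, 75, 80, 85, 90),
    fixed_intercepts = c(scr_amp_uS = 3.0, spr_amp_mV = -2.0,
                         ssr_amp_uS = -0.6, scr_tris_s = 2.5,
                         spret_pct = 12),
    fixed_slopes_per5db = c(scr_amp_uS = 1.2, spr_amp_mV = -0.7,
                            ssr_amp_uS = -0.2, scr_tris_s = 0.4,
                            spret_pct = 7.3),
    random_sd_intercept = c(scr_amp_uS = 0.6, spr_amp_mV = 0.5,
                            ssr_amp_uS = 0.12, scr_tris_s = 0.35,
                            spret_pct = 5),
    random_sd_slope = c(scr_amp_uS = 0.3, spr_amp_mV = 0.2,
                        ssr_amp_uS = 0.06, scr_tris_s = 0.1,
                        spret_pct = 2.5),
    random_corr = 0.2,
    residual_sd = c(scr_amp_uS = 0.4, spr_amp_mV = 0.3,
                    ssr_amp_uS = 0.08, scr_tris_s = 0.25,
                    spret_pct = 4),
    tonic_sc_uS = 10, tonic_ss_uS = 5, tonic_sp_mV = -20,
    drift_sd = 0,
    spr_biphasic_prob = 0.3,
    kernel_tau_rise_s = 0.75, kernel_tau_decay_s = 3,
    onset_latency_s = c(1.2, 1.8),
    sample_rate_hz = 20,
    seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), levels_db = as.numeric(levels_db),
    fixed_intercepts = named_feature_vec(fixed_intercepts, "fixed_intercepts"),
    fixed_slopes_per5db = named_feature_vec(fixed_slopes_per5db,
                                            "fixed_slopes_per5db"),
    random_sd_intercept = named_feature_vec(random_sd_intercept,
                                            "random_sd_intercept"),
    random_sd_slope = named_feature_vec(random_sd_slope, "random_sd_slope"),
    random_corr = random_corr,
    residual_sd = named_feature_vec(residual_sd, "residual_sd"),
    tonic_sc_uS = tonic_sc_uS, tonic_ss_uS = tonic_ss_uS,
    tonic_sp_mV = tonic_sp_mV, drift_sd = drift_sd,
    spr_biphasic_prob = spr_biphasic_prob,
    kernel_tau_rise_s = kernel_tau_rise_s,
    kernel_tau_decay_s = kernel_tau_decay_s,
    onset_latency_s = as.numeric(onset_latency_s),
    sample_rate_hz = sample_rate_hz, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (any(diff(cfg$levels_db) <= 0))
    stop("`levels_db` must be strictly increasing")
  sds <- c(cfg$random_sd_intercept, cfg$random_sd_slope, cfg$residual_sd,
           cfg$drift_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (abs(cfg$random_corr) > 1) stop("`random_corr` must be in [-1, 1]")
  if (cfg$spr_biphasic_prob < 0 || cfg$spr_biphasic_prob > 1)
    stop("`spr_biphasic_prob` must be in [0, 1]")
  check_taus(cfg$kernel_tau_rise_s, cfg$kernel_tau_decay_s)
  if (length(cfg$onset_latency_s) != 2 ||
      cfg$onset_latency_s[1] > cfg$onset_latency_s[2] ||
      cfg$onset_latency_s[1] < 0)
    stop("`onset_latency_s` must be an increasing nonnegative range")
  if (cfg$sample_rate_hz <= 0) stop("`sample_rate_hz` must be > 0")
  if (cfg$tonic_sc_uS <= 0) stop("`tonic_sc_uS` must be > 0")
  invisible(cfg)
}

#' AC-carrier measurement configuration
#'
#' Models an ideal current source delivering a sinusoidal excitation
#' current to the skin; defaults follow a 20 uA, 20 Hz source driven from a
#' 200 mV excitation voltage.
#'
#' @param freq_hz Carrier frequency (Hz), `> 0`.
#' @param current_uA Excitation current amplitude (uA), `> 0`.
#' @param excitation_mV Source voltage before voltage-to-current conversion
#'   (mV); informational.
#' @param phase_ref_rad Reference phase of the current (rad).
#' @return A list of class `carrier_config`.
#' @export
carrier_config <- function(freq_hz = 20, current_uA = 20,
                           excitation_mV = 200, phase_ref_rad = 0) {
  if (freq_hz <= 0) stop("`freq_hz` must be > 0")
  if (current_uA <= 0) stop("`current_uA` must be > 0")
  structure(list(freq_hz = freq_hz, current_uA = current_uA,
                 excitation_mV = excitation_mV,
                 phase_ref_rad = phase_ref_rad),
            class = "carrier_config")
}

#' Digital lock-in configuration
#'
#' @param lp_cutoff_hz Low-pass cutoff applied to the demodulated products
#'   (Hz); must be below the carrier frequency.
#' @param filter_order Butterworth order of the zero-phase low-pass.
#' @param settle_s Initial transient marked invalid in the output (s).
#' @param out_rate_hz Decimated output rate (Hz).
#' @return A list of class `demod_config`.
#' @export
demod_config <- function(lp_cutoff_hz = 1, filter_order = 4, settle_s = 5,
                         out_rate_hz = 20) {
  if (lp_cutoff_hz <= 0) stop("`lp_cutoff_hz` must be > 0")
  if (settle_s < 0) stop("`settle_s` must be >= 0")
  if (filter_order < 1) stop("`filter_order` must be >= 1")
  if (out_rate_hz <= 0) stop("`out_rate_hz` must be > 0")
  structure(list(lp_cutoff_hz = lp_cutoff_hz, filter_order = filter_order,
                 settle_s = settle_s, out_rate_hz = out_rate_hz),
            class = "demod_config")
}

#' Stimulus-locked response detector configuration
#'
#' @param latency_window_s Length-2 post-stimulus window (s) in which a
#'   response onset must fall.
#' @param min_scr_amp_uS,min_spr_amp_mV,min_ssr_amp_uS Minimum absolute
#'   response amplitudes per channel; smaller deflections are treated as
#'   non-responses.
#' @param smooth_halfwidth_s Moving-average halfwidth applied before the
#'   derivative-based onset search (s).
#' @param biphasic_second_lobe_frac Minimum size of an opposite-direction
#'   second lobe, relative to the first deflection, for a skin potential
#'   response to be called biphasic; in `(0, 1]`.
#' @param max_rise_s Farthest point after onset searched for the peak (s).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(latency_window_s = c(0.5, 6),
                             min_scr_amp_uS = 0.02,
                             min_spr_amp_mV = 0.05,
                             min_ssr_amp_uS = 0.01,
                             smooth_halfwidth_s = 0.1,
                             biphasic_second_lobe_frac = 0.25,
                             max_rise_s = 15) {
  if (length(latency_window_s) != 2 || latency_window_s[1] < 0 ||
      latency_window_s[1] >= latency_window_s[2])
    stop("`latency_window_s` must satisfy 0 <= min < max")
  if (min(min_scr_amp_uS, min_spr_amp_mV, min_ssr_amp_uS) < 0)
    stop("amplitude thresholds must be >= 0")
  if (biphasic_second_lobe_frac <= 0 || biphasic_second_lobe_frac > 1)
    stop("`biphasic_second_lobe_frac` must be in (0, 1]")
  structure(list(latency_window_s = as.numeric(latency_window_s),
                 min_scr_amp_uS = min_scr_amp_uS,
                 min_spr_amp_mV = min_spr_amp_mV,
                 min_ssr_amp_uS = min_ssr_amp_uS,
                 smooth_halfwidth_s = smooth_halfwidth_s,
                 biphasic_second_lobe_frac = biphasic_second_lobe_frac,
                 max_rise_s = max_rise_s),
            class = "detection_config")
}
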