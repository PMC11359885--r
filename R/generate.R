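#' Generate a synthetic cohort of per-stimulus EDA features
#'
#' Draws, for every subject and noise level, the five response features
#' (SCR amplitude, SPR amplitude, SSR amplitude, SCR rise time, SPRET)
#' from the random-intercept/random-slope model
#' `y = (b0 + u0_i) + (b1 + u1_i) x + e`, where `x = (dB - 70)/5` counts
#' 5 dB steps, `(u0, u1)` is zero-mean bivariate normal with the configured
#' SDs and correlation, and `e` is zero-mean normal residual noise. Response
#' timing (onset latency, peak times, SPR shape) is drawn alongside so the
#' same table can drive trace rendering and round-trip testing.
#'
#' @param config A [generator_config()].
#' @return A list of class `eda_cohort` with elements
#'   \describe{
#'     \item{features}{long `data.frame`: `subject_id`, `event_index`,
#'       `level_db`, the five feature columns, `spr_shape`.}
#'     \item{truth}{the same rows plus ground-truth onset/peak times per
#'       channel (`scr_onset_s`, `scr_peak_s`, `spr_onset_s`,
#'       `spr_first_peak_s`, `spr_peak_s`, `ss_onset_s`, `ss_peak_s`).}
#'     \item{protocol}{the [build_protocol()] timeline used.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_feature_table <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  protocol <- build_protocol(levels_db = config$levels_db)
  n <- config$n_subjects
  k <- length(config$levels_db)
  x <- (config$levels_db - config$levels_db[1]) / 5
  rho <- config$random_corr

  subj <- rep(seq_len(n), each = k)
  feat <- data.frame(
    subject_id = subj,
    event_index = rep(seq_len(k), n),
    level_db = rep(config$levels_db, n))

  for (f in FEATURES) {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    u0 <- config$random_sd_intercept[[f]] * z1
    u1 <- config$random_sd_slope[[f]] * (rho * z1 + sqrt(1 - rho^2) * z2)
    eps <- stats::rnorm(n * k, sd = config$residual_sd[[f]])
    y <- (config$fixed_intercepts[[f]] + u0[subj]) +
      (config$fixed_slopes_per5db[[f]] + u1[subj]) * rep(x, n) + eps
    feat[[f]] <- y
  }
  # keep features physical; with the default preset these floors bind with
  # probability < 1e-4 and do not bias slope estimates measurably
  feat$scr_amp_uS <- pmax(feat$scr_amp_uS, 0.05)
  feat$scr_tris_s <- pmax(feat$scr_tris_s, 0.4)

  biph <- stats::runif(n * k) < config$spr_biphasic_prob
  feat$spr_shape <- ifelse(biph, "biphasic",
                           ifelse(feat$spr_amp_mV < 0, "monophasic_neg",
                                  "monophasic_pos"))

  lat <- stats::runif(n * k, config$onset_latency_s[1],
                      config$onset_latency_s[2])
  ev_onset <- protocol$events$onset_s[feat$event_index]
  truth <- feat
  truth$scr_onset_s <- ev_onset + lat
  truth$scr_peak_s <- truth$scr_onset_s + truth$scr_tris_s
  spret_offset <- truth$spret_pct * truth$scr_tris_s / 100
  truth$spr_onset_s <- truth$scr_onset_s + spret_offset
  truth$spr_peak_s <- truth$scr_peak_s + spret_offset
  truth$spr_first_peak_s <- ifelse(
    truth$spr_shape == "biphasic",
    truth$spr_onset_s + 0.35 * truth$scr_tris_s, NA_real_)
  truth$ss_onset_s <- truth$scr_onset_s
  truth$ss_peak_s <- truth$ss_onset_s + 0.8 * truth$scr_tris_s

  structure(list(features = feat, truth = truth, protocol = protocol,
                 config = config),
            class = "eda_cohort")
}

#' @export
print.eda_cohort <- function(x, ...) {
  cat(sprintf("Synthetic EDA cohort: %d subjects x %d levels (%s dB)\n",
              x$config$n_subjects, length(x$config$levels_db),
              paste(x$config$levels_db, collapse = "/")))
  invisible(x)
}

component_traces <- function(time_s, sc_uS, ss_uS, sp_mV, sample_rate_hz,
                             annotations = NULL) {
  n <- length(time_s)
  stopifnot(length(sc_uS) == n, length(ss_uS) == n, length(sp_mV) == n)
  if (any(!is.finite(c(sc_uS, ss_uS, sp_mV))))
    stop("component traces must be finite")
  if (any(sc_uS <= 0)) stop("skin conductance must be positive everywhere")
  structure(
    data.frame(time_s = time_s, sc_uS = sc_uS, ss_uS = ss_uS, sp_mV = sp_mV),
    sample_rate_hz = sample_rate_hz, annotations = annotations,
    class = c("component_traces", "data.frame"))
}

# time-scale the base kernel so onset-to-peak equals `rise_s`
scaled_kernel <- function(t_rel, amp, rise_s, tau_rise, tau_decay) {
  s <- rise_s / bateman_peak_time(tau_rise, tau_decay)
  scr_kernel(t_rel / s, amp = amp, tau_rise = tau_rise, tau_decay = tau_decay)
}

# Biphasic SPR waveform: two opposite Bateman lobes calibrated so the first
# extremum sits at (t1, v1) and the second at (t2, v2), values relative to
# the tonic baseline. Times in seconds on the same clock as `time_s`.
biphasic_waveform <- function(time_s, onset_s, t1, v1, t2, v2,
                              tau_rise, tau_decay) {
  r1 <- t1 - onset_s
  r2 <- 0.5 * (t2 - onset_s)
  o1 <- onset_s
  o2 <- t2 - r2
  unit1 <- function(t, o) scaled_kernel(t - o, 1, r1, tau_rise, tau_decay)
  unit2 <- function(t, o) scaled_kernel(t - o, 1, r2, tau_rise, tau_decay)
  a <- c(v1, v2)
  for (it in 1:6) {
    M <- rbind(c(unit1(t1, o1), unit2(t1, o2)),
               c(unit1(t2, o1), unit2(t2, o2)))
    a <- tryCatch(solve(M, c(v1, v2)), error = function(e) a)
    # locate actual extrema on a fine grid and nudge the lobe onsets so the
    # composite extrema land on the target times
    tg <- seq(onset_s, t2 + 2 * r2, by = min(0.01, r1 / 10))
    w <- a[1] * unit1(tg, o1) + a[2] * unit2(tg, o2)
    dir1 <- sign(v1)
    i1 <- which.max(dir1 * w[tg <= o2])
    i2 <- which.max(-dir1 * w)
    o1 <- o1 + (t1 - tg[i1])
    o2 <- o2 + (t2 - tg[i2])
  }
  a[1] * unit1(time_s, o1) + a[2] * unit2(time_s, o2)
}

slow_drift <- function(n, fs, sd, seed) {
  if (sd <= 0) return(numeric(n))
  set.seed(seed)
  w <- stats::rnorm(n)
  bf <- signal::butter(2, min(0.05 / (fs / 2), 0.99), type = "low")
  d <- signal::filtfilt(bf, w)
  d <- d - mean(d)
  s <- stats::sd(d)
  if (s > 0) d <- d * sd / s
  d
}

#' Render component traces for one subject
#'
#' Turns ground-truth per-event features into continuous SC/SS/SP channels:
#' each channel is its tonic baseline plus one Bateman-kernel response per
#' stimulus, time-scaled so the SC onset-to-peak interval equals the true
#' SCR rise time and amplitudes match the true feature values. The SPR peak
#' (the second, dominant peak for biphasic shapes) is placed at
#' `SCR peak time + SPRET * SCR_Tris / 100`, so SPRET is recoverable from
#' the rendered geometry.
#'
#' @param protocol A [build_protocol()] timeline.
#' @param truth Ground-truth rows for one subject (from
#'   [generate_feature_table()]'s `truth` element).
#' @param config The [generator_config()] used to generate `truth`.
#' @param subject Optional subject id to filter `truth` by.
#' @return A `component_traces` data frame (`time_s`, `sc_uS`, `ss_uS`,
#'   `sp_mV`) with attributes `sample_rate_hz` and `annotations` (per-event
#'   truncation flags).
#' @export
synthesize_traces <- function(protocol, truth, config, subject = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!is.null(subject)) truth <- truth[truth$subject_id == subject, ]
  if (length(unique(truth$subject_id)) > 1)
    stop("`truth` must contain a single subject; use `subject=`")
  if (any(truth$scr_amp_uS < 0) || any(truth$scr_tris_s <= 0))
    stop("true SCR amplitude must be >= 0 and rise time > 0")
  fs <- config$sample_rate_hz
  time_s <- seq(0, protocol$total_s, by = 1 / fs)
  tr <- config$kernel_tau_rise_s
  td <- config$kernel_tau_decay_s

  sc <- rep(0, length(time_s))
  ss <- rep(0, length(time_s))
  sp <- rep(0, length(time_s))
  truncated <- logical(nrow(truth))

  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    tris <- row$scr_tris_s
    sc <- sc + scaled_kernel(time_s - row$scr_onset_s, row$scr_amp_uS,
                             tris, tr, td)
    ss <- ss + scaled_kernel(time_s - row$ss_onset_s, row$ssr_amp_uS,
                             row$ss_peak_s - row$ss_onset_s, tr, td)
    if (identical(row$spr_shape, "biphasic") && row$spr_amp_mV != 0) {
      sp <- sp + biphasic_waveform(
        time_s, row$spr_onset_s,
        t1 = row$spr_first_peak_s, v1 = -row$spr_amp_mV / 3,
        t2 = row$spr_peak_s, v2 = 2 * row$spr_amp_mV / 3,
        tau_rise = tr, tau_decay = td)
    } else {
      sp <- sp + scaled_kernel(time_s - row$spr_onset_s, row$spr_amp_mV,
                               row$spr_peak_s - row$spr_onset_s, tr, td)
    }
    truncated[i] <- max(row$scr_peak_s, row$spr_peak_s, row$ss_peak_s) >
      protocol$total_s
  }

  sid <- if (nrow(truth)) truth$subject_id[1] else 0L
  n <- length(time_s)
  sc <- sc + config$tonic_sc_uS +
    slow_drift(n, fs, config$drift_sd, config$seed + 7919L * sid + 1L)
  ss <- ss + config$tonic_ss_uS +
    slow_drift(n, fs, config$drift_sd, config$seed + 7919L * sid + 2L)
  sp <- sp + config$tonic_sp_mV +
    slow_drift(n, fs, config$drift_sd, config$seed + 7919L * sid + 3L)

  ann <- data.frame(event_index = truth$event_index, truncated = truncated)
  component_traces(time_s, sc, ss, sp, fs, annotations = ann)
}
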