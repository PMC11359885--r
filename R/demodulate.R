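#' Digital lock-in demodulation of a raw carrier signal
#'
#' Phase-sensitive detection: the raw voltage is multiplied by reference
#' `sin`/`cos` waves at the carrier frequency and reference phase, the
#' products (doubled) and the raw signal itself are passed through a
#' zero-phase Butterworth low-pass, and the result is decimated to the
#' output rate. This splits the measurement into a DC component (skin
#' potential) and the in-phase/quadrature amplitudes of the AC component.
#'
#' @param raw A `raw_signal` data frame (see [synthesize_raw_carrier()]) or
#'   any data frame with `time_s`, `v_mV` and a `sample_rate_hz` attribute.
#' @param carrier A [carrier_config()].
#' @param cfg A [demod_config()]. `lp_cutoff_hz` must be below the carrier
#'   frequency or the DC and AC components are inseparable.
#' @return A data frame with columns `time_s`, `dc_mV`, `v_inphase_mV`,
#'   `v_quad_mV` and `valid` (FALSE during the initial `settle_s`
#'   transient), decimated to `cfg$out_rate_hz`, with attribute
#'   `sample_rate_hz` set to the output rate.
#' @export
lockin_demodulate <- function(raw, carrier = carrier_config(),
                              cfg = demod_config()) {
  fs <- attr(raw, "sample_rate_hz")
  if (is.null(fs)) fs <- 1 / stats::median(diff(raw$time_s))
  if (fs <= 2 * carrier$freq_hz)
    stop("sample rate must exceed twice the carrier frequency")
  if (cfg$lp_cutoff_hz >= carrier$freq_hz)
    stop("low-pass cutoff must be below the carrier frequency")
  v <- raw$v_mV
  wt <- 2 * pi * carrier$freq_hz * raw$time_s + carrier$phase_ref_rad
  bf <- signal::butter(cfg$filter_order, cfg$lp_cutoff_hz / (fs / 2),
                       type = "low")
  dc <- signal::filtfilt(bf, v)
  vi <- 2 * signal::filtfilt(bf, v * sin(wt))
  vq <- 2 * signal::filtfilt(bf, v * cos(wt))
  decim <- max(1L, round(fs / cfg$out_rate_hz))
  idx <- seq(1L, length(v), by = decim)
  # zero-phase (forward-backward) filtering has transients at both edges,
  # so the settle margin is applied at the start and the end
  t_idx <- raw$time_s[idx]
  out <- data.frame(time_s = t_idx, dc_mV = dc[idx],
                    v_inphase_mV = vi[idx], v_quad_mV = vq[idx],
                    valid = t_idx >= raw$time_s[1] + cfg$settle_s &
                      t_idx <= raw$time_s[length(raw$time_s)] - cfg$settle_s)
  attr(out, "sample_rate_hz") <- fs / decim
  out
}

#' Convert demodulated voltage phasors to skin admittance
#'
#' The AC voltage phasor is `V = v_inphase + j v_quad` (mV, relative to the
#' current reference phase); with excitation current `I` (uA) the skin
#' admittance is `Y = I / V`, returned as conductance (real part) and
#' susceptance (imaginary part) in uS. Capacitive susceptance is positive.
#'
#' @param v_inphase,v_quad In-phase and quadrature voltage amplitudes (mV);
#'   vectorized.
#' @param carrier A [carrier_config()] supplying `current_uA`.
#' @return A data frame with columns `g_uS` (conductance) and `b_uS`
#'   (susceptance).
#' @export
phasor_to_admittance <- function(v_inphase, v_quad,
                                 carrier = carrier_config()) {
  mag2 <- v_inphase^2 + v_quad^2
  if (any(mag2 == 0)) stop("zero voltage phasor: admittance undefined")
  V <- complex(real = v_inphase, imaginary = v_quad)
  Y_uS <- 1000 * carrier$current_uA / V   # uA/mV = mS -> uS
  data.frame(g_uS = Re(Y_uS), b_uS = Im(Y_uS))
}

#' Demodulate a raw signal into component traces
#'
#' Convenience wrapper: [lockin_demodulate()] followed by
#' [phasor_to_admittance()], returning the same `component_traces` layout
#' that [synthesize_traces()] produces (SP from the DC path, SC/SS from the
#' AC path).
#'
#' @inheritParams lockin_demodulate
#' @param drop_invalid Drop samples inside the settle transient
#'   (default FALSE: they are kept so the timeline matches the protocol).
#' @return A `component_traces` data frame.
#' @export
demodulate_to_traces <- function(raw, carrier = carrier_config(),
                                 cfg = demod_config(),
                                 drop_invalid = FALSE) {
  d <- lockin_demodulate(raw, carrier, cfg)
  if (drop_invalid) d <- d[d$valid, ]
  adm <- phasor_to_admittance(d$v_inphase_mV, d$v_quad_mV, carrier)
  component_traces(d$time_s, pmax(adm$g_uS, .Machine$double.eps),
                   adm$b_uS, d$dc_mV,
                   sample_rate_hz = attr(d, "sample_rate_hz"))
}

#' Estimate the lock-in reference phase from a calibration segment
#'
#' With an unknown reference phase, demodulating a stationary carrier
#' segment at phase 0 yields in-phase/quadrature means whose angle is the
#' phase that maximizes in-phase power.
#'
#' @inheritParams lockin_demodulate
#' @param segment_s Length-2 time window (s) of a stationary segment.
#' @return Estimated `phase_ref_rad`.
#' @export
estimate_phase_ref <- function(raw, carrier = carrier_config(),
                               cfg = demod_config(),
                               segment_s = NULL) {
  c0 <- carrier
  c0$phase_ref_rad <- 0
  d <- lockin_demodulate(raw, c0, cfg)
  d <- d[d$valid, ]
  if (!is.null(segment_s))
    d <- d[d$time_s >= segment_s[1] & d$time_s <= segment_s[2], ]
  atan2(mean(d$v_quad_mV), mean(d$v_inphase_mV))
}
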