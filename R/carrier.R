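#' Synthesize the raw AC-carrier voltage from component traces
#'
#' Models an ideal sinusoidal current source `i(t) = I sin(2 pi f t + phi)`
#' driving the skin admittance `Y(t) = G(t) + jB(t)` built from the SC and
#' SS channels, superposed on the DC skin potential:
#' `v(t) = SP(t) + |I / Y(t)| sin(2 pi f t + phi - arg Y(t))`, emitted in
#' mV (uA / uS = V). The admittance is treated quasi-statically, valid
#' because sudomotor dynamics are far slower than the carrier.
#'
#' @param traces A `component_traces` data frame (see
#'   [synthesize_traces()]).
#' @param carrier A [carrier_config()]. The trace sampling rate must exceed
#'   twice the carrier frequency (>= 20x recommended).
#' @return A `raw_signal` data frame with columns `time_s`, `v_mV` and
#'   attributes `sample_rate_hz` and `carrier`.
#' @export
synthesize_raw_carrier <- function(traces, carrier = carrier_config()) {
  fs <- attr(traces, "sample_rate_hz")
  if (is.null(fs)) stop("`traces` lacks a sample_rate_hz attribute")
  if (fs <= 2 * carrier$freq_hz)
    stop("trace sample rate must exceed twice the carrier frequency")
  Y <- complex(real = traces$sc_uS, imaginary = traces$ss_uS)
  if (any(Mod(Y) == 0))
    stop("zero admittance is non-physical: |Y| must be > 0 everywhere")
  amp_mV <- 1000 * carrier$current_uA / Mod(Y)
  ph <- 2 * pi * carrier$freq_hz * traces$time_s + carrier$phase_ref_rad -
    Arg(Y)
  v <- traces$sp_mV + amp_mV * sin(ph)
  raw_signal(traces$time_s, v, fs, carrier)
}

raw_signal <- function(time_s, v_mV, sample_rate_hz, carrier = NULL) {
  stopifnot(length(time_s) == length(v_mV))
  if (any(!is.finite(v_mV))) stop("raw signal must be finite")
  structure(data.frame(time_s = time_s, v_mV = v_mV),
            sample_rate_hz = sample_rate_hz, carrier = carrier,
            class = c("raw_signal", "data.frame"))
}
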