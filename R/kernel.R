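#' Peak time of the Bateman (biexponential) response kernel
#'
#' @param tau_rise Rise time constant (s), `0 < tau_rise < tau_decay`.
#' @param tau_decay Decay time constant (s).
#' @return Time from kernel onset to its maximum (s).
#' @export
bateman_peak_time <- function(tau_rise, tau_decay) {
  check_taus(tau_rise, tau_decay)
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

check_taus <- function(tau_rise, tau_decay) {
  if (!(tau_rise > 0 && tau_decay > tau_rise))
    stop("require 0 < tau_rise < tau_decay")
  invisible(TRUE)
}

#' Normalized Bateman response kernel
#'
#' The standard difference-of-exponentials model of a sudomotor response
#' waveform, normalized so its maximum equals `amp`:
#' `amp * (exp(-t/tau_decay) - exp(-t/tau_rise)) / c`, where `c` is the
#' unnormalized kernel value at the peak time
#' `t_p = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#' Zero for `t_rel < 0`.
#'
#' @param t_rel Time since kernel onset (s); vectorized.
#' @param amp Peak amplitude (channel units).
#' @param tau_rise,tau_decay Time constants (s), `0 < tau_rise < tau_decay`.
#' @return Kernel values, same length as `t_rel`.
#' @export
scr_kernel <- function(t_rel, amp = 1, tau_rise = 0.75, tau_decay = 3) {
  check_taus(tau_rise, tau_decay)
  tp <- bateman_peak_time(tau_rise, tau_decay)
  cnorm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- amp * (exp(-t_rel / tau_decay) - exp(-t_rel / tau_rise)) / cnorm
  out[t_rel < 0] <- 0
  out
}
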