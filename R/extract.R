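CHANNEL_COLS <- c(sc = "sc_uS", sp = "sp_mV", ss = "ss_uS")

channel_min_amp <- function(channel, cfg) {
  switch(channel,
         sc = cfg$min_scr_amp_uS,
         sp = cfg$min_spr_amp_mV,
         ss = cfg$min_ssr_amp_uS,
         stop("unknown channel: ", channel))
}

moving_average <- function(y, halfwidth) {
  h <- as.integer(halfwidth)
  if (h < 1) return(y)
  k <- rep(1 / (2 * h + 1), 2 * h + 1)
  ys <- stats::filter(y, k, sides = 2)
  ys <- as.numeric(ys)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

#' Detect a stimulus-locked response on one channel
#'
#' Onset search: the channel is lightly smoothed, and the first point inside
#' the post-stimulus latency window where the smoothed derivative exceeds a
#' direction-appropriate threshold is taken as the rise; the onset is then
#' refined by backtracking on the raw derivative to the foot of the
#' deflection. The peak is the first subsequent local extremum in the
#' deflection direction. For skin potential, the response is biphasic when,
#' after the first peak, the signal crosses beyond the onset level in the
#' opposite direction by at least `biphasic_second_lobe_frac` of the first
#' deflection; the opposite extremum is then the second peak. SC responses
#' are constrained to positive deflections; SP and SS deflection direction
#' is determined per event from the first threshold crossing, so both
#' polarities are supported.
#'
#' @param traces A `component_traces` data frame (or any data frame with
#'   `time_s` and the channel column).
#' @param channel One of `"sc"`, `"sp"`, `"ss"`.
#' @param event A one-row event (see [noise_event()]).
#' @param cfg A [detection_config()].
#' @return An `eda_response` list (`channel`, `event_index`, `onset_t_s`,
#'   `onset_value`, `peak_t_s`, `peak_value`, `second_peak_t_s`,
#'   `second_peak_value`, `shape`, `amplitude`), or `NULL` when no
#'   response clears the channel's amplitude threshold.
#' @export
detect_response <- function(traces, channel, event,
                            cfg = detection_config()) {
  channel <- match.arg(channel, names(CHANNEL_COLS))
  col <- CHANNEL_COLS[[channel]]
  if (!col %in% names(traces))
    stop("traces missing channel column: ", col)
  t <- traces$time_s
  y <- traces[[col]]
  fs <- attr(traces, "sample_rate_hz")
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  dt <- 1 / fs

  w_lo <- event$onset_s + cfg$latency_window_s[1]
  w_hi <- event$onset_s + cfg$latency_window_s[2]
  if (w_lo > t[length(t)]) {
    warning("latency window extends past trace end; no detection attempted")
    return(NULL)
  }
  if (w_hi > t[length(t)]) {
    warning("latency window truncated at trace end")
    w_hi <- t[length(t)]
  }

  ys <- moving_average(y, round(cfg$smooth_halfwidth_s * fs))
  d_s <- c(0, diff(ys)) / dt
  d_r <- c(0, diff(y)) / dt

  win <- which(t >= w_lo & t <= w_hi)
  if (!length(win)) return(NULL)

  # derivative threshold: absolute floor tied to the channel's minimum
  # amplitude, raised to 10% of the strongest in-window slope so that slow
  # ripple (e.g. zero-phase filter precursors) cannot anchor the onset
  floor_thr <- 0.5 * channel_min_amp(channel, cfg)  # units per second
  if (channel == "sc") {
    thr <- max(floor_thr, 0.1 * max(d_s[win]))
    hit <- win[d_s[win] >= thr]
    if (!length(hit)) return(NULL)
    i0 <- hit[1]
    dir <- 1
  } else {
    thr <- max(floor_thr, 0.1 * max(abs(d_s[win])))
    hit <- win[abs(d_s[win]) >= thr]
    if (!length(hit)) return(NULL)
    i0 <- hit[1]
    dir <- sign(d_s[i0])
  }

  # walk to the foot of the deflection on the raw derivative: back over the
  # rise the smoothing may have spread, then forward over flat baseline
  lo_i <- which(t >= event$onset_s)[1]
  tol <- 0.25 * thr
  while (i0 > lo_i && d_r[i0] * dir > tol) i0 <- i0 - 1
  while (i0 + 1L < length(y) && d_r[i0 + 1L] * dir <= tol) i0 <- i0 + 1L
  onset_i <- i0

  # first local extremum in the deflection direction
  hi_i <- min(length(y), onset_i + round(cfg$max_rise_s * fs))
  if (onset_i + 1L > hi_i) return(NULL)
  peak_i <- NA_integer_
  for (i in seq(onset_i + 1L, hi_i)) {
    if (i == length(y) || d_r[i + 1L] * dir <= 0) {
      if ((y[i] - y[onset_i]) * dir > 0) { peak_i <- i; break }
    }
  }
  if (is.na(peak_i)) return(NULL)
  # refine to the raw local extremum in a small neighbourhood
  nb <- max(1L, round(cfg$smooth_halfwidth_s * fs))
  rng <- max(onset_i + 1L, peak_i - nb):min(length(y), peak_i + nb)
  peak_i <- rng[which.max(dir * y[rng])]

  onset_value <- y[onset_i]
  peak_value <- y[peak_i]
  amp1 <- peak_value - onset_value
  shape <- if (dir > 0) "monophasic_pos" else "monophasic_neg"
  second_peak_t <- NA_real_
  second_peak_v <- NA_real_
  amplitude <- amp1

  if (channel == "sp") {
    # biphasic: after the first peak the signal must cross beyond the onset
    # level in the opposite direction by >= frac of the first deflection
    hi2 <- min(length(y), peak_i + round(2 * cfg$max_rise_s * fs))
    seg <- seq(peak_i + 1L, hi2)
    if (length(seg) > 1) {
      j <- seg[which.max(-dir * y[seg])]
      e2 <- -dir * (y[j] - onset_value)
      if (is.finite(e2) && e2 >= cfg$biphasic_second_lobe_frac * abs(amp1)) {
        shape <- "biphasic"
        second_peak_t <- t[j]
        second_peak_v <- y[j]
        amplitude <- second_peak_v - peak_value
      }
    }
  }

  if (abs(amplitude) < channel_min_amp(channel, cfg)) return(NULL)

  structure(list(channel = toupper(channel),
                 event_index = if (!is.null(event$event_index))
                   event$event_index else NA_integer_,
                 onset_t_s = t[onset_i], onset_value = onset_value,
                 peak_t_s = t[peak_i], peak_value = peak_value,
                 second_peak_t_s = second_peak_t,
                 second_peak_value = second_peak_v,
                 shape = shape, amplitude = amplitude),
            class = "eda_response")
}

#' @export
print.eda_response <- function(x, ...) {
  cat(sprintf("%s response (%s): onset %.2f s, peak %.2f s, amplitude %.3f\n",
              x$channel, x$shape, x$onset_t_s, x$peak_t_s, x$amplitude))
  invisible(x)
}

#' Signed response amplitude
#'
#' Monophasic responses: peak value minus onset value (positive for SCRs by
#' construction). Biphasic skin potential responses: second peak value minus
#' first peak value (peak-to-peak).
#'
#' @param resp An `eda_response`.
#' @return Signed amplitude in channel units.
#' @export
response_amplitude <- function(resp) {
  stopifnot(inherits(resp, "eda_response"))
  if (identical(resp$shape, "biphasic"))
    resp$second_peak_value - resp$peak_value
  else
    resp$peak_value - resp$onset_value
}

#' SCR rise time (onset to peak)
#'
#' @param resp An SC `eda_response`.
#' @return Onset-to-peak interval (s).
#' @export
scr_tris <- function(resp) {
  stopifnot(inherits(resp, "eda_response"), resp$channel == "SC")
  resp$peak_t_s - resp$onset_t_s
}

#' SPRET: skin potential relative early turn
#'
#' `100 * (SPR peak time - SCR peak time) / (SCR peak time - SCR onset
#' time)`. For biphasic skin potential responses the second (terminal)
#' peak anchors the SPR peak time, since the biphasic amplitude is defined
#' peak-to-peak and the second peak is the response's extremum.
#'
#' @param scr The SC `eda_response` of the event.
#' @param spr The SP `eda_response` of the same event.
#' @return SPRET in percent.
#' @export
spret <- function(scr, spr) {
  stopifnot(inherits(scr, "eda_response"), scr$channel == "SC",
            inherits(spr, "eda_response"), spr$channel == "SP")
  tris <- scr$peak_t_s - scr$onset_t_s
  if (tris <= 0) stop("SCR rise time must be positive")
  spr_peak_t <- if (identical(spr$shape, "biphasic"))
    spr$second_peak_t_s else spr$peak_t_s
  100 * (spr_peak_t - scr$peak_t_s) / tris
}

#' Extract the five per-stimulus features from component traces
#'
#' Runs [detect_response()] on each channel for every protocol event and
#' assembles the feature table: SCR amplitude (uS), SPR amplitude (mV), SSR
#' amplitude (uS), SCR rise time (s) and SPRET (%). Events with no
#' detection on a channel get `NA` for the features that depend on it;
#' non-responses are never zero-filled.
#'
#' @param traces A `component_traces` data frame with all three channels.
#' @param protocol A [build_protocol()] timeline.
#' @param cfg A [detection_config()].
#' @param subject_id Identifier copied into the output rows.
#' @return A `data.frame` with one row per event: `subject_id`,
#'   `event_index`, `level_db`, `scr_amp_uS`, `spr_amp_mV`, `ssr_amp_uS`,
#'   `scr_tris_s`, `spret_pct`, `spr_shape`. Attribute `responses` holds
#'   the underlying `eda_response` objects.
#' @export
build_feature_table <- function(traces, protocol, cfg = detection_config(),
                                subject_id = 1L) {
  miss <- setdiff(unname(CHANNEL_COLS), names(traces))
  if (length(miss))
    stop("traces missing channel column(s): ", paste(miss, collapse = ", "))
  events <- protocol$events
  n_ev <- nrow(events)
  rows <- vector("list", n_ev)
  responses <- vector("list", n_ev)
  for (e in seq_len(n_ev)) {
    ev <- events[e, ]
    ev$event_index <- e
    r_sc <- detect_response(traces, "sc", ev, cfg)
    r_sp <- detect_response(traces, "sp", ev, cfg)
    r_ss <- detect_response(traces, "ss", ev, cfg)
    rows[[e]] <- data.frame(
      subject_id = subject_id, event_index = e, level_db = ev$level_db,
      scr_amp_uS = if (!is.null(r_sc)) response_amplitude(r_sc) else NA_real_,
      spr_amp_mV = if (!is.null(r_sp)) response_amplitude(r_sp) else NA_real_,
      ssr_amp_uS = if (!is.null(r_ss)) response_amplitude(r_ss) else NA_real_,
      scr_tris_s = if (!is.null(r_sc)) scr_tris(r_sc) else NA_real_,
      spret_pct = if (!is.null(r_sc) && !is.null(r_sp))
        spret(r_sc, r_sp) else NA_real_,
      spr_shape = if (!is.null(r_sp)) r_sp$shape else NA_character_,
      stringsAsFactors = FALSE)
    responses[[e]] <- list(sc = r_sc, sp = r_sp, ss = r_ss)
  }
  out <- if (n_ev) do.call(rbind, rows) else
    data.frame(subject_id = integer(), event_index = integer(),
               level_db = numeric(), scr_amp_uS = numeric(),
               spr_amp_mV = numeric(), ssr_amp_uS = numeric(),
               scr_tris_s = numeric(), spret_pct = numeric(),
               spr_shape = character(), stringsAsFactors = FALSE)
  attr(out, "responses") <- responses
  out
}
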