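#' Construct a single noise event
#'
#' A noise event is one acoustic stimulus on the recording timeline, labelled
#' with its sound pressure level in dB SPL.
#'
#' @param onset_s Time of stimulus onset from recording start (s), `>= 0`.
#' @param duration_s Stimulus duration (s), `> 0`.
#' @param level_db Sound pressure level (dB SPL), in `[0, 140]`.
#' @param label Free-text description of the sound (e.g. "ambulance siren").
#' @return A one-row `data.frame` with columns `onset_s`, `duration_s`,
#'   `level_db`, `label`.
#' @export
noise_event <- function(onset_s, duration_s, level_db, label = "") {
  stopifnot(is.numeric(onset_s), is.numeric(duration_s), is.numeric(level_db))
  if (onset_s < 0) stop("`onset_s` must be >= 0")
  if (duration_s <= 0) stop("`duration_s` must be > 0")
  if (level_db < 0 || level_db > 140) stop("`level_db` must be in [0, 140]")
  data.frame(onset_s = onset_s, duration_s = duration_s,
             level_db = level_db, label = as.character(label),
             stringsAsFactors = FALSE)
}

#' Build a graded noise-stimulus protocol
#'
#' Lays out one stimulus per sound level on a single timeline: an initial
#' rest (`pre_baseline_s`), then each stimulus of `stim_s` seconds followed
#' by `rest_s` seconds of relaxation. With the default arguments (five levels
#' 70-90 dB in 5 dB steps, 5 s stimuli, 60 s rests, 60 s baseline) the
#' timeline is 385 s long.
#'
#' @param levels_db Ordered vector of stimulus levels (dB SPL).
#' @param stim_s Stimulus duration (s), `> 0`.
#' @param rest_s Post-stimulus relaxation (s), `>= 0`.
#' @param pre_baseline_s Initial rest before the first stimulus (s), `>= 0`.
#' @param labels Optional character vector of stimulus labels, recycled.
#' @return An object of class `stimulus_protocol`: a list with `events`
#'   (a `data.frame` of [noise_event()] rows), `pre_baseline_s`,
#'   `post_event_rest_s` and `total_s`.
#' @examples
#' p <- build_protocol()
#' p$total_s  # 385
#' @export
build_protocol <- function(levels_db = c(70, 75, 80, 85, 90),
                           stim_s = 5, rest_s = 60, pre_baseline_s = 60,
                           labels = NULL) {
  if (length(levels_db) == 0) stop("`levels_db` must be nonempty")
  if (stim_s <= 0) stop("`stim_s` must be > 0")
  if (rest_s < 0 || pre_baseline_s < 0)
    stop("rest and baseline durations must be >= 0")
  k <- length(levels_db)
  if (is.null(labels)) labels <- paste0("stimulus_", seq_len(k))
  labels <- rep_len(as.character(labels), k)
  onsets <- pre_baseline_s + (seq_len(k) - 1) * (stim_s + rest_s)
  events <- do.call(rbind, lapply(seq_len(k), function(i) {
    noise_event(onsets[i], stim_s, levels_db[i], labels[i])
  }))
  total_s <- pre_baseline_s + k * (stim_s + rest_s)
  structure(
    list(events = events, pre_baseline_s = pre_baseline_s,
         post_event_rest_s = rest_s, total_s = total_s),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d events, %.0f s pre-baseline, %.0f s total\n",
              nrow(x$events), x$pre_baseline_s, x$total_s))
  print(x$events)
  invisible(x)
}

validate_events <- function(events) {
  req <- c("onset_s", "duration_s", "level_db")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("event table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(events) > 1) {
    o <- order(events$onset_s)
    events <- events[o, , drop = FALSE]
    ends <- events$onset_s + events$duration_s
    if (any(events$onset_s[-1] < ends[-nrow(events)]))
      stop("events overlap")
  }
  events
}
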