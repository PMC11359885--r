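#' Fit the response-amplitude vs noise-level model function
#'
#' Least-squares fit of the mean response amplitude per level against the
#' level step `x = (dB - ref_db)/5`: linear `a + b x`, or exponential
#' `a exp(b x)` fitted by nonlinear least squares initialized from the
#' log-linear fit. When amplitudes are non-positive on the log scale the
#' exponential form falls back to linear with a warning status.
#'
#' @param features Feature table with `level_db` and the amplitude column.
#' @param form `"linear"` or `"exponential"`.
#' @param dv Amplitude column used for the fit (default SCR amplitude).
#' @param ref_db Reference level for the step coding (dB).
#' @return An `amplitude_level_model` list: `form`, `params` (`a`, `b`),
#'   `fit_rss`, `n_points`, `level_range_db`, `status`.
#' @export
fit_amplitude_vs_level <- function(features,
                                   form = c("linear", "exponential"),
                                   dv = "scr_amp_uS", ref_db = 70) {
  form <- match.arg(form)
  if (!dv %in% names(features)) stop("unknown amplitude column: ", dv)
  ok <- !is.na(features[[dv]])
  means <- tapply(features[[dv]][ok], features$level_db[ok], mean)
  levels_db <- as.numeric(names(means))
  if (length(means) < 3)
    stop("need >= 3 distinct noise levels with data to fit the model")
  x <- (levels_db - ref_db) / 5
  y <- as.numeric(means)
  status <- "ok"
  if (form == "exponential" && any(y <= 0)) {
    warning("non-positive mean amplitudes; falling back to linear form")
    form <- "linear"
    status <- "fallback_linear"
  }
  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    a <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
    rss <- sum(stats::resid(fit)^2)
  } else {
    init <- unname(stats::coef(stats::lm(log(y) ~ x)))
    fit <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                             start = list(a = exp(init[1]), b = init[2]))
    a <- unname(stats::coef(fit)["a"])
    b <- unname(stats::coef(fit)["b"])
    rss <- sum(stats::resid(fit)^2)
  }
  structure(list(form = form, params = c(a = a, b = b), fit_rss = rss,
                 n_points = length(y), ref_db = ref_db,
                 level_range_db = range(levels_db), status = status),
            class = "amplitude_level_model")
}

#' Predict response amplitude at a noise level
#'
#' @param object An `amplitude_level_model`.
#' @param level_db Noise levels (dB); vectorized.
#' @param ... Unused.
#' @return Predicted amplitudes. Levels outside the fitted range are
#'   extrapolated with a warning.
#' @export
predict.amplitude_level_model <- function(object, level_db, ...) {
  x <- (level_db - object$ref_db) / 5
  outside <- level_db < object$level_range_db[1] |
    level_db > object$level_range_db[2]
  if (any(outside))
    warning("predicting outside the fitted level range (extrapolation)")
  a <- object$params[["a"]]
  b <- object$params[["b"]]
  if (object$form == "linear") a + b * x else a * exp(b * x)
}

#' Attribute detected responses to logged noise events
#'
#' A response is noise-attributed iff its onset lies within the latency
#' window after some event onset; when several events qualify the nearest
#' preceding event wins, ties going to the earlier event.
#'
#' @param responses `data.frame` with at least `onset_t_s` (and typically
#'   an amplitude column).
#' @param events Event log `data.frame` with `onset_s` and `level_db`.
#' @param window Length-2 latency bounds (s) after event onset.
#' @return `responses` with added columns `attributed_event` (row index
#'   into `events`, `NA` if unattributed) and `attributed_level_db`.
#' @export
attribute_responses <- function(responses, events, window = c(0.5, 6)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  ev_idx <- rep(NA_integer_, nrow(responses))
  if (nrow(responses) && !is.null(events) && nrow(events)) {
    ord <- order(events$onset_s, seq_len(nrow(events)))
    for (i in seq_len(nrow(responses))) {
      lag <- responses$onset_t_s[i] - events$onset_s
      cand <- which(lag >= window[1] & lag <= window[2])
      if (length(cand)) {
        best <- cand[lag[cand] == min(lag[cand])]
        ev_idx[i] <- best[1]  # tie -> earlier event
      }
    }
  }
  responses$attributed_event <- ev_idx
  responses$attributed_level_db <- ifelse(is.na(ev_idx), NA_real_,
                                          events$level_db[ev_idx])
  responses
}

#' Binned noise-elicited EDA correction
#'
#' Treats measured EDA as the sum of intrinsic and noise-elicited activity.
#' Within consecutive time bins (default 5 min), the raw score is the sum
#' of SCR amplitudes with onset in the bin; the noise-elicited score is the
#' sum of model-predicted amplitudes at the attributed events' levels; the
#' corrected score is their difference. Negative corrected bins are not
#' clipped: they signal model overcorrection.
#'
#' @param responses `data.frame` with `onset_t_s` and `amplitude` (SCR
#'   amplitudes, uS).
#' @param events Event log with `onset_s`, `level_db`.
#' @param model An [fit_amplitude_vs_level()] model.
#' @param bin_s Bin width (s), default 300 (5 min).
#' @param window Attribution latency window (s), see
#'   [attribute_responses()].
#' @param total_s Optional recording length; defaults to the last response
#'   or event time.
#' @return A `correction_result` data frame: `bin_start_s`, `bin_end_s`,
#'   `raw_score`, `noise_elicited_score`, `corrected_score`,
#'   `n_responses`, `n_attributed`.
#' @export
correct_bins <- function(responses, events, model, bin_s = 300,
                         window = c(0.5, 6), total_s = NULL) {
  if (bin_s <= 0) stop("`bin_s` must be > 0")
  stopifnot(inherits(model, "amplitude_level_model"))
  if (is.null(total_s))
    total_s <- max(c(responses$onset_t_s, events$onset_s, bin_s), na.rm = TRUE)
  edges <- seq(0, ceiling(total_s / bin_s) * bin_s, by = bin_s)
  att <- attribute_responses(responses, events, window)
  nb <- length(edges) - 1
  out <- data.frame(bin_start_s = edges[-length(edges)],
                    bin_end_s = edges[-1])
  out$raw_score <- 0
  out$noise_elicited_score <- 0
  out$n_responses <- 0L
  out$n_attributed <- 0L
  if (nrow(att)) {
    bin_of <- pmin(pmax(findInterval(att$onset_t_s, edges,
                                     rightmost.closed = TRUE), 1L), nb)
    pred <- rep(0, nrow(att))
    has_ev <- !is.na(att$attributed_event)
    if (any(has_ev))
      pred[has_ev] <- predict(model, att$attributed_level_db[has_ev])
    for (b in seq_len(nb)) {
      in_b <- bin_of == b
      out$raw_score[b] <- sum(att$amplitude[in_b], na.rm = TRUE)
      out$noise_elicited_score[b] <- sum(pred[in_b & has_ev])
      out$n_responses[b] <- sum(in_b)
      out$n_attributed[b] <- sum(in_b & has_ev)
    }
  }
  out$corrected_score <- out$raw_score - out$noise_elicited_score
  structure(out, class = c("correction_result", "data.frame"),
            bin_s = bin_s, model_form = model$form)
}
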