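read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  d <- as.data.frame(data.table::fread(path))
  if (nrow(d) == 0) stop("empty input file (no rows): ", path)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  d
}

#' Read/write component traces as CSV
#'
#' CSV schema: `time_s, sc_uS, ss_uS, sp_mV`. Round trips are lossless to
#' at least 9 significant digits; time must be strictly increasing.
#'
#' @param path CSV file path.
#' @return `read_traces()`: a `component_traces` data frame.
#' @export
read_traces <- function(path) {
  d <- read_csv_checked(path, c("time_s", "sc_uS", "ss_uS", "sp_mV"))
  if (any(diff(d$time_s) <= 0)) stop("non-monotonic time_s in ", path)
  fs <- 1 / stats::median(diff(d$time_s))
  component_traces(d$time_s, d$sc_uS, d$ss_uS, d$sp_mV, fs)
}

#' @rdname read_traces
#' @param traces A `component_traces` data frame.
#' @export
write_traces <- function(traces, path) {
  data.table::fwrite(as.data.frame(traces)[c("time_s", "sc_uS", "ss_uS",
                                             "sp_mV")], path)
  invisible(path)
}

#' Read/write a raw carrier signal as CSV
#'
#' CSV schema: `time_s, v_mV`.
#'
#' @param path CSV file path.
#' @export
read_raw_signal <- function(path) {
  d <- read_csv_checked(path, c("time_s", "v_mV"))
  if (any(diff(d$time_s) <= 0)) stop("non-monotonic time_s in ", path)
  raw_signal(d$time_s, d$v_mV, 1 / stats::median(diff(d$time_s)))
}

#' @rdname read_raw_signal
#' @param raw A `raw_signal` data frame.
#' @export
write_raw_signal <- function(raw, path) {
  data.table::fwrite(as.data.frame(raw)[c("time_s", "v_mV")], path)
  invisible(path)
}

#' Read/write feature tables and event logs as CSV
#'
#' Feature schema: `subject_id, event_index, level_db, scr_amp_uS,
#' spr_amp_mV, ssr_amp_uS, scr_tris_s, spret_pct, spr_shape`. Event-log
#' schema: `onset_s, duration_s, level_db, label`.
#'
#' @param path CSV file path.
#' @export
read_features <- function(path) {
  read_csv_checked(path, c("subject_id", "event_index", "level_db",
                           FEATURES))
}

#' @rdname read_features
#' @param features Feature table.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname read_features
#' @export
read_events <- function(path) {
  validate_events(read_csv_checked(path, c("onset_s", "duration_s",
                                           "level_db")))
}

#' @rdname read_features
#' @param events Event table.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' One flat configuration driving the end-to-end pipeline. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param generator A [generator_config()].
#' @param carrier A [carrier_config()].
#' @param demod A [demod_config()].
#' @param detection A [detection_config()].
#' @param render `"features"` (analyze generated features directly),
#'   `"traces"` (render component traces and re-extract features) or
#'   `"carrier"` (additionally synthesize the raw carrier and demodulate).
#' @param correction_form Amplitude-level model form for the correction
#'   stage (`"linear"` or `"exponential"`).
#' @param correction_bin_s Correction bin width (s).
#' @param seed Overall run seed; overrides the generator seed.
#' @param out_dir Optional directory to write artifacts into.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       carrier = carrier_config(),
                       demod = demod_config(),
                       detection = detection_config(),
                       render = c("features", "traces", "carrier"),
                       correction_form = "exponential",
                       correction_bin_s = 300,
                       seed = NULL, out_dir = NULL) {
  render <- match.arg(render)
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  if (render == "carrier" &&
      generator$sample_rate_hz <= 2 * carrier$freq_hz)
    stop("carrier rendering needs sample_rate_hz > 2 * freq_hz")
  structure(list(generator = generator, carrier = carrier, demod = demod,
                 detection = detection, render = render,
                 correction_form = correction_form,
                 correction_bin_s = correction_bin_s,
                 seed = generator$seed, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(x) {
  # stable content hash without extra dependencies: serialize to a
  # canonical text form and crc via sum of char codes + length mixing
  s <- paste(deparse(x), collapse = "\n")
  raw <- utf8ToInt(s)
  h <- 5381
  for (ch in raw) h <- (h * 33 + ch) %% 2147483647
  sprintf("%x-%d", h, nchar(s))
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, optionally render traces (and the raw carrier,
#' demodulating it back), extract the five features, run the
#' repeated-measures ANOVA and the mixed model on every feature, and apply
#' the noise-elicited correction. Deterministic given the configured seed.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report`: `config_hash`, `seed`,
#'   `render`, `features`, `analyses` (per-feature ANOVA + LMM),
#'   `lmm_table` (tidy per-feature slope summary), `correction`
#'   (per-subject [correct_bins()] results pooled), and `artifacts`
#'   (paths written, if `out_dir` was set).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_feature_table(config$generator)
  protocol <- cohort$protocol
  artifacts <- character()

  if (config$render == "features") {
    features <- cohort$features
    resp <- data.frame(subject_id = cohort$truth$subject_id,
                       onset_t_s = cohort$truth$scr_onset_s,
                       amplitude = cohort$truth$scr_amp_uS)
  } else {
    feats <- list()
    resp <- list()
    for (s in seq_len(config$generator$n_subjects)) {
      tr <- synthesize_traces(protocol, cohort$truth, config$generator,
                              subject = s)
      if (config$render == "carrier") {
        raw <- synthesize_raw_carrier(tr, config$carrier)
        tr <- demodulate_to_traces(raw, config$carrier, config$demod)
      }
      ft <- build_feature_table(tr, protocol, config$detection,
                                subject_id = s)
      feats[[s]] <- ft
      rs <- attr(ft, "responses")
      on <- vapply(rs, function(r) if (is.null(r$sc)) NA_real_ else
        r$sc$onset_t_s, numeric(1))
      am <- vapply(rs, function(r) if (is.null(r$sc)) NA_real_ else
        r$sc$amplitude, numeric(1))
      resp[[s]] <- data.frame(subject_id = s, onset_t_s = on,
                              amplitude = am)
    }
    features <- do.call(rbind, feats)
    resp <- do.call(rbind, resp)
    resp <- resp[!is.na(resp$onset_t_s), ]
  }

  analyses <- analyze_features(features)
  lmm_table <- do.call(rbind, lapply(names(analyses), function(f) {
    l <- analyses[[f]]$lmm
    if (inherits(l, "error"))
      return(data.frame(feature = f, beta1_per5db = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_,
                        p_value = NA_real_))
    data.frame(feature = f, beta1_per5db = l$beta1_per_step,
               ci95_low = l$ci95_low, ci95_high = l$ci95_high,
               p_value = l$p_value)
  }))

  model <- fit_amplitude_vs_level(features, config$correction_form)
  corrections <- lapply(split(resp, resp$subject_id), function(r) {
    correct_bins(r, protocol$events, model,
                 bin_s = config$correction_bin_s,
                 total_s = protocol$total_s)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- file.path(config$out_dir, "features.csv")
    write_features(features, fp)
    ep <- file.path(config$out_dir, "events.csv")
    write_events(protocol$events, ep)
    artifacts <- c(fp, ep)
  }

  structure(list(config_hash = config_hash(config), seed = config$seed,
                 render = config$render,
                 package_version =
                   as.character(utils::packageVersion("edanoise")),
                 features = features, analyses = analyses,
                 lmm_table = lmm_table,
                 amplitude_model = model, correction = corrections,
                 artifacts = artifacts),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("EDA pipeline report (render = %s, seed = %d, config %s)\n",
              x$render, x$seed, x$config_hash))
  print(x$lmm_table, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serializes the analysis summary (seed, config hash, package version,
#' per-feature slope table with intervals and p values, ANOVA F/p per
#' feature, amplitude-level model, per-bin correction scores) for
#' provenance and downstream consumption.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  anova_tab <- lapply(report$analyses, function(a) {
    if (inherits(a$anova, "error")) list(error = conditionMessage(a$anova))
    else list(f_stat = a$anova$f_stat, df_treatment = a$anova$df_treatment,
              df_error = a$anova$df_error, p_value = a$anova$p_value)
  })
  out <- list(
    seed = report$seed, config_hash = report$config_hash,
    package_version = report$package_version, render = report$render,
    lmm = report$lmm_table, anova = anova_tab,
    amplitude_model = report$amplitude_model[c("form", "params", "fit_rss",
                                               "n_points")],
    correction = lapply(report$correction, as.data.frame))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
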