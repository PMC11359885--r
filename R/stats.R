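#' Reshape a long feature table to a subjects-by-levels matrix
#'
#' @param features A feature table (see [build_feature_table()] or
#'   [generate_feature_table()]).
#' @param dv Feature column name (e.g. `"scr_amp_uS"`).
#' @return Numeric matrix, one row per subject, one column per noise level
#'   in ascending dB order; missing cells are `NA`.
#' @export
feature_wide <- function(features, dv) {
  if (!dv %in% names(features)) stop("unknown feature column: ", dv)
  levels_db <- sort(unique(features$level_db))
  subjects <- unique(features$subject_id)
  mat <- matrix(NA_real_, nrow = length(subjects), ncol = length(levels_db),
                dimnames = list(as.character(subjects),
                                as.character(levels_db)))
  mat[cbind(match(features$subject_id, subjects),
            match(features$level_db, levels_db))] <- features[[dv]]
  mat
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition on the complete-case submatrix:
#' `SS_total = SS_subjects + SS_treatment + SS_error`, with
#' `F = (SS_treatment / (k-1)) / (SS_error / ((n-1)(k-1)))` tested against
#' the F distribution with `(k-1, (n-1)(k-1))` degrees of freedom. No
#' sphericity correction is applied. Sidak-adjusted pairwise comparisons
#' from [pairwise_sidak()] are attached.
#'
#' @param mat Subjects-by-levels matrix (see [feature_wide()]).
#' @return An `rm_anova` list: `f_stat`, `df_treatment`, `df_error`,
#'   `p_value`, sums of squares, `n_subjects`, `n_levels` and a
#'   `pairwise` table.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  cc <- stats::complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2)
    stop("repeated-measures ANOVA needs >= 2 complete subjects and >= 2 levels")
  grand <- mean(mat)
  ss_total <- sum((mat - grand)^2)
  ss_subjects <- k * sum((rowMeans(mat) - grand)^2)
  ss_treatment <- n * sum((colMeans(mat) - grand)^2)
  ss_error <- max(ss_total - ss_subjects - ss_treatment, 0)
  df_t <- k - 1
  df_e <- (n - 1) * (k - 1)
  if (ss_treatment == 0) {
    f <- 0
    p <- 1
  } else if (ss_error <= .Machine$double.eps * ss_total) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_treatment / df_t) / (ss_error / df_e)
    p <- stats::pf(f, df_t, df_e, lower.tail = FALSE)
  }
  structure(list(f_stat = f, df_treatment = df_t, df_error = df_e,
                 p_value = p, ss_treatment = ss_treatment,
                 ss_subjects = ss_subjects, ss_error = ss_error,
                 n_subjects = n, n_levels = k,
                 pairwise = pairwise_sidak(mat)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_treatment, x$df_error, x$f_stat, x$p_value))
  invisible(x)
}

#' Sidak-corrected pairwise comparisons between noise levels
#'
#' Paired t tests on every pair of levels, adjusted with the Sidak
#' correction `p_adj = 1 - (1 - p)^m` over the `m = k(k-1)/2` comparisons.
#' When the paired differences have zero variance, `p` is 0 if the means
#' differ and 1 otherwise.
#'
#' @param mat Subjects-by-levels matrix (see [feature_wide()]).
#' @return `data.frame` with `level_a`, `level_b`, `mean_diff`, `raw_p`,
#'   `sidak_p`.
#' @export
pairwise_sidak <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2) stop("need >= 2 levels")
  lv <- colnames(mat)
  if (is.null(lv)) lv <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- mat[, b] - mat[, a]
    if (stats::sd(d) == 0) {
      raw_p <- if (mean(d) == 0) 1 else 0
    } else {
      raw_p <- stats::t.test(d)$p.value
    }
    data.frame(level_a = lv[a], level_b = lv[b], mean_diff = mean(d),
               raw_p = raw_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$sidak_p <- pmin(1, 1 - (1 - out$raw_p)^m)
  out
}

#' Fit the dose-response linear mixed model for one feature
#'
#' REML fit of `y_ij = (b0 + u0_i) + (b1 + u1_i) x_ij + e_ij`, where `x`
#' counts noise-level steps above the reference (`x = (dB - ref_db) /
#' per_db`, default 5 dB steps above 70 dB), `(u0, u1)` are correlated
#' subject-level random intercept and slope, and `e` is residual noise.
#' Fitted with [lme4::lmer()]; the reported 95% interval for the slope is
#' Wald (`beta1 +/- 1.96 SE`) and the p value a Wald z test. Observations
#' with missing `dv` are dropped (all available observations are used; no
#' complete-case restriction).
#'
#' @param features Long feature table with `subject_id`, `level_db` and the
#'   feature columns.
#' @param dv Dependent feature column name.
#' @param ref_db Reference level subtracted before coding (dB).
#' @param per_db Step size of the level coding (dB); `per_db = 5` makes the
#'   slope "per 5 dB", `per_db = 1` makes it per dB (exactly 1/5 of the
#'   former).
#' @return An `eda_lmm` list: `beta0`, `beta1_per_step`, `ci95_low`,
#'   `ci95_high`, `p_value`, `var_b0`, `var_b1`, `corr_b0b1`, `sigma2`,
#'   `n_subjects`, `n_obs`, `converged`, `messages`.
#' @export
fit_lmm <- function(features, dv, ref_db = 70, per_db = 5) {
  if (!dv %in% names(features)) stop("unknown feature column: ", dv)
  d <- data.frame(y = features[[dv]],
                  x = (features$level_db - ref_db) / per_db,
                  subject = factor(features$subject_id))
  d <- d[stats::complete.cases(d), ]
  tab <- table(d$subject)
  tab <- tab[tab >= 2]
  if (length(tab) < 2)
    stop("mixed model needs >= 2 subjects with >= 2 observations each")
  d <- d[d$subject %in% names(tab), , drop = FALSE]
  d$subject <- droplevels(d$subject)

  # exactly collinear (noise-free) data: per-subject OLS is exact and the
  # REML optimizer has nothing to estimate
  per_ols <- lapply(split(d, d$subject), function(s) stats::lm(y ~ x, data = s))
  max_resid <- max(vapply(per_ols, function(m) max(abs(stats::resid(m))),
                          numeric(1)))
  scale_y <- max(abs(d$y), 1)
  degenerate <- max_resid < 1e-9 * scale_y

  msgs <- character()
  fit <- if (degenerate) simpleError("degenerate: zero residual variance")
  else withCallingHandlers(
    tryCatch(
      lme4::lmer(y ~ x + (1 + x | subject), data = d, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore")),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  if (inherits(fit, "error")) {
    # exactly collinear (noise-free) data defeat the REML optimizer; fall
    # back to per-subject OLS, which is exact in that degenerate case
    per <- do.call(rbind, lapply(split(d, d$subject), function(s) {
      co <- stats::coef(stats::lm(y ~ x, data = s))
      data.frame(b0 = co[1], b1 = co[2])
    }))
    beta0 <- mean(per$b0); beta1 <- mean(per$b1)
    se1 <- stats::sd(per$b1) / sqrt(nrow(per))
    res <- list(beta0 = beta0, beta1_per_step = beta1,
                ci95_low = beta1 - 1.96 * se1,
                ci95_high = beta1 + 1.96 * se1,
                p_value = if (se1 == 0) 0 else
                  2 * stats::pnorm(-abs(beta1 / se1)),
                var_b0 = stats::var(per$b0), var_b1 = stats::var(per$b1),
                corr_b0b1 = suppressWarnings(stats::cor(per$b0, per$b1)),
                sigma2 = 0, n_subjects = nrow(per), n_obs = nrow(d),
                converged = TRUE,
                messages = c(msgs, "degenerate fit: per-subject OLS path"))
    return(structure(res, class = "eda_lmm"))
  }

  conv_fail <- any(grepl("failed to converge", msgs, ignore.case = TRUE))
  fe <- lme4::fixef(fit)
  se1 <- sqrt(stats::vcov(fit)["x", "x"])
  vc <- lme4::VarCorr(fit)$subject
  z <- fe[["x"]] / se1
  res <- list(
    beta0 = fe[["(Intercept)"]], beta1_per_step = fe[["x"]],
    ci95_low = fe[["x"]] - stats::qnorm(0.975) * se1,
    ci95_high = fe[["x"]] + stats::qnorm(0.975) * se1,
    p_value = 2 * stats::pnorm(-abs(z)),
    var_b0 = vc["(Intercept)", "(Intercept)"],
    var_b1 = vc["x", "x"],
    corr_b0b1 = attr(vc, "correlation")["(Intercept)", "x"],
    sigma2 = stats::sigma(fit)^2,
    n_subjects = nlevels(d$subject), n_obs = nrow(d),
    converged = !conv_fail, messages = msgs)
  if (conv_fail)
    warning("mixed-model fit did not converge: ",
            paste(msgs, collapse = "; "))
  structure(res, class = "eda_lmm")
}

#' @export
print.eda_lmm <- function(x, ...) {
  cat(sprintf(
    "LMM slope per step: %.4f (95%% CI %.4f to %.4f), p = %.3g\n",
    x$beta1_per_step, x$ci95_low, x$ci95_high, x$p_value))
  cat(sprintf("  random effects: var(b0) = %.4g, var(b1) = %.4g, corr = %.3f, sigma2 = %.4g\n",
              x$var_b0, x$var_b1, x$corr_b0b1, x$sigma2))
  invisible(x)
}

#' Run both dose-response analyses on every feature
#'
#' @param features Long feature table.
#' @param dvs Feature columns to analyze (default: all five).
#' @inheritParams fit_lmm
#' @return Named list per feature, each with elements `anova`
#'   ([rm_anova()]) and `lmm` ([fit_lmm()]).
#' @export
analyze_features <- function(features, dvs = FEATURES, ref_db = 70,
                             per_db = 5) {
  out <- lapply(dvs, function(dv) {
    an <- tryCatch(rm_anova(feature_wide(features, dv)),
                   error = function(e) e)
    lm_ <- tryCatch(fit_lmm(features, dv, ref_db, per_db),
                    error = function(e) e)
    list(anova = an, lmm = lm_)
  })
  names(out) <- dvs
  out
}
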