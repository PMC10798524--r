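## ---------------------------------------------------------------------------
## The numbered model suite. Step 1 (model 1) estimates current-trial value
## sensitivity with correlated subject slopes; its linear predictions (before
## the link) become a fixed offset in every later behavioral model, so
## context regressors can only claim variance the current-trial model left
## unexplained. SCR models are linear mixed models on the normalized
## amplitudes of responder subjects.
## ---------------------------------------------------------------------------

## display names used when rendering specs back to analysis pseudo-code
suite_term_names <- c(
  choice = "choice(t)",
  choice_signed = "choice(t)",
  riskygain_n = "risky gain amount(t)",
  safe_n = "safe amount(t)",
  magnitude_n = "magnitude(t)",
  prev_outcome_n = "outcome(t-1)",
  pos_shift_n = "positive shift amount(t)",
  neg_shift_n = "negative shift amount(t)",
  pos_shift_prev_n = "positive shift amount(t-1)",
  earnings_n = "cumulative earnings(t)",
  expectation_n = "linear expectation(t)",
  outcome_n = "outcome(t)",
  earn_x_prevout = "cumulative earnings(t)*outcome(t-1)",
  earn_x_out = "cumulative earnings(t)*outcome(t)",
  prevout_x_posshift = "positive shift amount(t)*outcome(t-1)",
  scr_out_n = "SCR following outcome(t)",
  scr_prev_n = "SCR following outcome(t-1)",
  scr_prev_x_prevout = "SCR following outcome(t-1)*outcome(t-1)",
  scr_dec_n = "SCR during decision phase(t)",
  offset1 = "predicted values from model 1",
  offset3a = "predicted values from model 3a")

#' Render a model specification as analysis pseudo-code
#' @param spec a `model_spec` from the suite.
#' @return a single string.
#' @export
render_model <- function(spec) format(spec, term_names = suite_term_names)

#' Behavioral model specifications
#'
#' The numbered behavioral models: model 1 regresses choice on current-trial
#' values with correlated risky-gain and safe random slopes; models 2-4b add
#' context regressors over a fixed model-1 offset with a subject random
#' intercept. Two reduced variants of model 4a (earnings only, expectation
#' only) are included for the AIC comparison.
#'
#' @param offset_3c which predictions feed model 3c's offset: `"model1"`
#'   (default, consistent with every other behavioral model) or `"model3a"`.
#' @return named list of `model_spec` objects.
#' @export
behavior_model_specs <- function(offset_3c = c("model1", "model3a")) {
  offset_3c <- match.arg(offset_3c)
  off3 <- if (offset_3c == "model1") "offset1" else "offset3a"
  list(
    m1 = model_spec("choice", c("riskygain_n", "safe_n", "magnitude_n"),
                    random = c("riskygain_n", "safe_n")),
    m2 = model_spec("choice", "prev_outcome_n", offset = "offset1"),
    m3a = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "neg_shift_n"),
                     offset = "offset1"),
    m3b = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "pos_shift_prev_n"),
                     offset = "offset1"),
    m3c = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "prevout_x_posshift"),
                     offset = off3),
    m4a = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "earnings_n",
                                 "expectation_n"), offset = "offset1"),
    m4a_earnings = model_spec("choice", c("prev_outcome_n", "pos_shift_n",
                                          "earnings_n"), offset = "offset1"),
    m4a_expectation = model_spec("choice", c("prev_outcome_n", "pos_shift_n",
                                             "expectation_n"), offset = "offset1"),
    m4b = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "earnings_n",
                                 "earn_x_prevout", "expectation_n"),
                     offset = "offset1"))
}

#' SCR model specifications
#'
#' Outcome-locked SCR models (5a-d), SCR-to-behavior models carrying the
#' model-1 offset (6a-b, 8c), and decision-phase models (7, 8a-b). Model 7
#' uses choice coded 1 = risky / -1 = safe.
#'
#' @return named list of `model_spec` objects.
#' @export
scr_model_specs <- function() {
  list(
    m5a = model_spec("scr_out_n", "outcome_n", family = "gaussian", intercept = TRUE),
    m5b = model_spec("scr_out_n", "pos_shift_n", family = "gaussian", intercept = TRUE),
    m5c = model_spec("scr_out_n", c("earnings_n", "expectation_n"),
                     family = "gaussian", intercept = TRUE),
    m5d = model_spec("scr_out_n", c("earnings_n", "outcome_n", "earn_x_out"),
                     family = "gaussian", intercept = TRUE),
    m6a = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "earnings_n",
                                 "earn_x_prevout", "scr_prev_n"),
                     offset = "offset1"),
    m6b = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "scr_prev_n",
                                 "scr_prev_x_prevout"), offset = "offset1"),
    m7 = model_spec("scr_dec_n", "choice_signed", family = "gaussian",
                    intercept = TRUE),
    m8a = model_spec("scr_dec_n", c("prev_outcome_n", "pos_shift_n", "earnings_n",
                                    "expectation_n"), family = "gaussian",
                     intercept = TRUE),
    m8b = model_spec("scr_dec_n", c("pos_shift_n", "pos_shift_prev_n"),
                     family = "gaussian", intercept = TRUE),
    m8c = model_spec("choice", c("prev_outcome_n", "pos_shift_n", "earnings_n",
                                 "earn_x_prevout", "scr_dec_n"),
                     offset = "offset1"))
}

#' Run the behavioral model suite (two-step offset procedure)
#'
#' Fits model 1 first, computes its linear predictions (optionally including
#' the subject random-effect modes), stores them as the `offset1` column, and
#' fits every later behavioral model over that fixed offset.
#'
#' @param features a cohort `feature_table` with a `subject` column.
#' @param nAGQ integration setting for the context models.
#' @param nAGQ_step1 integration setting for model 1 (set to 0 inside large
#'   simulation studies to use only the penalized-least-squares step).
#' @param include_random_offset include subject random-effect modes in the
#'   offset (default `TRUE`).
#' @param offset_3c see [behavior_model_specs()].
#' @param models optional character subset of model ids to fit (model 1 is
#'   always fitted).
#' @return a `suite_report`: list with `fits` (named `fit_result` list),
#'   `features` (with the offset columns attached), and the settings.
#' @export
run_behavior_suite <- function(features, nAGQ = 1L, nAGQ_step1 = nAGQ,
                               include_random_offset = TRUE,
                               offset_3c = "model1", models = NULL) {
  specs <- behavior_model_specs(offset_3c)
  wanted <- if (is.null(models)) names(specs) else union("m1", models)
  fits <- list()
  fits$m1 <- fit_binomial_glmm(features, specs$m1, nAGQ = nAGQ_step1,
                               model_id = "1")
  features$offset1 <- linear_predictions(fits$m1,
                                         include_random = include_random_offset)
  for (id in setdiff(wanted, "m1")) {
    spec <- specs[[id]]
    if (identical(spec$offset, "offset3a")) {
      if (is.null(fits$m3a))
        fits$m3a <- fit_binomial_glmm(features, specs$m3a, nAGQ = nAGQ,
                                      model_id = "3a")
      features$offset3a <- features$offset1 +
        linear_predictions(fits$m3a, include_random = include_random_offset)
    }
    if (is.null(fits[[id]]))
      fits[[id]] <- fit_binomial_glmm(features, spec, nAGQ = nAGQ,
                                      model_id = sub("^m", "", id))
  }
  structure(list(fits = fits, features = features,
                 include_random_offset = include_random_offset,
                 offset_3c = offset_3c),
            class = "suite_report")
}

#' Run the SCR model suite
#'
#' Linear mixed models for outcome- and decision-phase SCR amplitudes and
#' the behavioral models carrying SCR regressors over the model-1 offset.
#' The feature table must already be restricted to responder subjects for
#' the respective phase and carry `scr_out_n` / `scr_prev_n` / `scr_dec_n`
#' columns (see [attach_scr()]); each model uses the rows complete for its
#' own columns.
#'
#' @param features a `feature_table` with SCR columns and an `offset1`
#'   column (from a behavioral `suite_report`'s `features`).
#' @param nAGQ integration setting for the binomial models.
#' @param models optional character subset of model ids.
#' @return a `suite_report` with the SCR fits.
#' @export
run_scr_suite <- function(features, nAGQ = 1L, models = NULL) {
  specs <- scr_model_specs()
  if (is.null(features$offset1))
    config_stop("features carry no offset1 column; run the behavioral suite first")
  wanted <- if (is.null(models)) names(specs) else models
  fits <- list()
  for (id in wanted) {
    spec <- specs[[id]]
    cols <- c(spec$response, spec$fixed, spec$offset, spec$id)
    d <- features[stats::complete.cases(features[, cols]), , drop = FALSE]
    if (length(unique(d[[spec$id]])) < 2L)
      config_stop("model %s: fewer than 2 responder subjects with complete data", id)
    fits[[id]] <- if (spec$family == "binomial")
      fit_binomial_glmm(d, spec, nAGQ = nAGQ, model_id = sub("^m", "", id))
    else fit_linear_mixed(d, spec, model_id = sub("^m", "", id))
  }
  structure(list(fits = fits), class = "suite_report")
}

#' Attach scored SCR columns to a feature table
#'
#' Joins per-trial normalized SCR amplitudes into the feature table:
#' `scr_out_n` (outcome-locked SCR on trial t), `scr_prev_n` (outcome-locked
#' SCR on trial t-1), `scr_dec_n` (decision-phase SCR on trial t), the
#' product `scr_prev_x_prevout`, and the signed choice code
#' `choice_signed = 2 * choice - 1`. Amplitudes are joined only for the
#' subjects present in `outcome_scored` / `decision_scored`, so restricting
#' those tables to responders implements the exclusion rule.
#'
#' @param features a cohort `feature_table`.
#' @param outcome_scored data.frame `subject`, `trial`, `normalized` for the
#'   outcome phase (responders only).
#' @param decision_scored same for the decision phase.
#' @return the augmented `feature_table`.
#' @export
attach_scr <- function(features, outcome_scored = NULL, decision_scored = NULL) {
  key <- function(s, t) paste(s, t, sep = ":")
  if (!is.null(outcome_scored)) {
    lut <- stats::setNames(outcome_scored$normalized,
                           key(outcome_scored$subject, outcome_scored$trial))
    features$scr_out_n <- unname(lut[key(features$subject, features$trial)])
    features$scr_prev_n <- unname(lut[key(features$subject, features$trial - 1L)])
    features$scr_prev_x_prevout <- features$scr_prev_n * features$prev_outcome_n
  }
  if (!is.null(decision_scored)) {
    lut <- stats::setNames(decision_scored$normalized,
                           key(decision_scored$subject, decision_scored$trial))
    features$scr_dec_n <- unname(lut[key(features$subject, features$trial)])
  }
  features$choice_signed <- 2 * features$choice - 1
  features
}

#' Results table of a suite report
#' @param report a `suite_report`.
#' @return data.frame with one row per model term.
#' @export
suite_table <- function(report) {
  rows <- lapply(report$fits, function(f)
    cbind(model = f$model_id, f$coefficients,
          aic = f$aic, loglik = f$log_likelihood, n = f$n_obs))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.suite_report <- function(x, ...) {
  for (f in x$fits) { print(f); cat("\n") }
  invisible(x)
}

#' Paired per-subject comparisons of mean SCR by event category
#'
#' Computes each subject's mean amplitude per category, then paired t tests
#' on the per-subject differences for every category pair (and optionally a
#' paired Wilcoxon signed-rank test, exact for 25 or fewer subjects).
#' Subjects lacking either category of a pair are dropped from that pair
#' with a warning. Zero-variance, zero-mean differences give t = 0, p = 1.
#'
#' @param events data.frame with columns `subject`, `category`, `value`.
#' @param wilcoxon also run the signed-rank test per pair.
#' @return list with `means` (subject-by-category matrix) and `tests`
#'   (data.frame of pair, n, t, df, p, and optionally V, p_wilcoxon).
#' @export
paired_category_tests <- function(events, wilcoxon = FALSE) {
  means <- tapply(events$value, list(events$subject, events$category), mean)
  cats <- colnames(means)
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  tests <- lapply(pairs, function(pr) {
    m <- means[, pr, drop = FALSE]
    ok <- stats::complete.cases(m)
    if (any(!ok))
      warning(sprintf("%d subject(s) lack a '%s' or '%s' mean and were dropped",
                      sum(!ok), pr[1], pr[2]), call. = FALSE)
    m <- m[ok, , drop = FALSE]
    if (nrow(m) < 2L)
      config_stop("fewer than 2 subjects with events in both '%s' and '%s'",
                  pr[1], pr[2])
    d <- m[, 1] - m[, 2]
    if (sd(d) == 0) {
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- t.test(m[, 1], m[, 2], paired = TRUE)
    }
    row <- data.frame(pair = paste(pr, collapse = " vs "), n = nrow(m),
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value)
    if (wilcoxon) {
      wt <- suppressWarnings(wilcox.test(m[, 1], m[, 2], paired = TRUE,
                                         exact = nrow(m) <= 25))
      row$V <- unname(wt$statistic)
      row$p_wilcoxon <- wt$p.value
    }
    row
  })
  list(means = means, tests = do.call(rbind, tests))
}

#' Translate a logistic coefficient into a probability change
#'
#' Returns the percentage-point change in the probability of gambling when a
#' normalized regressor moves from 0 to `x`, starting from `baseline`
#' (indifference, 0.5, by default):
#' `100 * (plogis(qlogis(baseline) + beta * x) - baseline)`.
#'
#' @param beta logistic-scale coefficient.
#' @param x normalized regressor value (e.g. `68/68` for the maximum
#'   previous outcome, `15/68` for a +$15 shift under a $68 money scale).
#' @param baseline baseline probability in (0, 1).
#' @return signed percentage-point change (not rounded).
#' @export
effect_to_probability <- function(beta, x, baseline = 0.5) {
  if (baseline <= 0 || baseline >= 1)
    config_stop("baseline must lie strictly inside (0, 1)")
  100 * (logistic(logit(baseline) + beta * x) - baseline)
}

#' Rank fitted models by AIC
#'
#' @param fits list of `fit_result` objects fitted to identical observations
#'   (compared by row count; differing counts are an error since AIC is not
#'   comparable across datasets).
#' @return data.frame `model`, `aic`, `delta_aic` in ascending AIC order;
#'   ties share a `delta_aic` of 0.
#' @export
compare_aic <- function(fits) {
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1L)
    config_stop("fits use differing observation counts (%s); AIC is not comparable",
                paste(unique(n), collapse = ", "))
  ids <- vapply(seq_along(fits), function(i)
    fits[[i]]$model_id %||% names(fits)[i] %||% as.character(i), character(1))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aic)
  data.frame(model = ids[ord], aic = aic[ord],
             delta_aic = aic[ord] - min(aic), row.names = NULL)
}
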