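## ---------------------------------------------------------------------------
## Normalized per-trial context regressors. A single money scale divides all
## dollar-valued regressors and a single earnings scale divides cumulative
## earnings and the linear expectation, so printed-magnitude coefficients are
## comparable across terms. Cumulative earnings at trial t are the sum of
## outcomes on trials 1..t-1 (the pre-decision information set).
## ---------------------------------------------------------------------------

#' Construct a normalization scheme
#'
#' @param money_scale dollars; divides every dollar-valued regressor
#'   (amounts, outcomes, shifts). The conventional choice is the maximum
#'   outcome amount in the dataset (about $68-$70 for the standard design),
#'   which reproduces the usual probability-change translations.
#' @param earnings_scale dollars; divides cumulative earnings and the linear
#'   expectation. The conventional choice is the expected total earnings at
#'   the final trial, so both regressors are O(1).
#' @return an object of class `normalization_scheme`.
#' @export
normalization_scheme <- function(money_scale, earnings_scale) {
  if (money_scale <= 0 || earnings_scale <= 0)
    config_stop("normalization scales must be > 0")
  structure(list(money_scale = money_scale, earnings_scale = earnings_scale),
            class = "normalization_scheme")
}

#' Default normalization for one or more choice sets
#'
#' Money scale: the maximum risky gain across the sets (the largest amount an
#' outcome can take). Earnings scale: the average over sets of
#' `mean(EV level) * n_trials`, i.e. the expected total earnings at the final
#' trial, so the normalized linear expectation ends at 1.
#'
#' @param sets a `choice_set` or list of them.
#' @return a `normalization_scheme`.
#' @export
default_normalization <- function(sets) {
  if (inherits(sets, "choice_set")) sets <- list(sets)
  money <- max(vapply(sets, function(s) max(s$risky_gain), numeric(1)))
  earn <- mean(vapply(sets, function(s) mean(s$ev_level) * nrow(s), numeric(1)))
  normalization_scheme(money, earn)
}

#' Linear expectation of earnings at each trial
#'
#' A straight line in the trial index: `expectation_t = t * mean(EV level)`
#' over the whole choice set, capturing the steady increase in expected
#' earnings across the task. The slope depends only on the task-level mean,
#' not on run ordering.
#'
#' @param set a `choice_set`.
#' @return numeric vector of expected earnings in dollars, one per trial.
#' @export
linear_expectation <- function(set) {
  seq_len(nrow(set)) * mean(set$ev_level)
}

#' Build the normalized per-trial regressor table
#'
#' Computes current-trial amounts, the previous outcome, signed shifts (the
#' positive and negative parts carried separately, each nonzero only on a
#' run's first trial), the previous trial's positive shift, cumulative
#' earnings before the trial, the linear expectation, the current outcome,
#' and the interaction products used by the model suite; divides each by the
#' applicable scale; and applies the exclusions: trial 1, missed trials, and
#' any trial whose predecessor was missed (its previous outcome is
#' undefined).
#'
#' @param set a `choice_set`.
#' @param records matching trial records from [simulate_choices()] (or read
#'   from a trial-table CSV).
#' @param norm a `normalization_scheme`.
#' @return a `feature_table` data.frame with one row per retained trial.
#' @export
build_features <- function(set, records, norm) {
  stopifnot(inherits(norm, "normalization_scheme"))
  n <- nrow(set)
  if (nrow(records) != n)
    config_stop("records (%d rows) are not aligned with the choice set (%d trials)",
                nrow(records), n)
  if (any(!records$missed & is.na(records$outcome)))
    config_stop("missing outcome on a non-missed trial")
  ms <- norm$money_scale; es <- norm$earnings_scale

  outcome_filled <- ifelse(records$missed, 0, records$outcome)
  earnings <- c(0, cumsum(outcome_filled))[seq_len(n)]
  expectation <- linear_expectation(set)
  pos_shift <- pmax(set$shift, 0)
  neg_shift <- pmin(set$shift, 0)

  tab <- data.frame(
    trial = set$trial,
    choice = records$choice,
    riskygain_n = set$risky_gain / ms,
    safe_n = set$safe / ms,
    magnitude_n = set$ev_level / ms,
    prev_outcome_n = c(NA, records$outcome[-n]) / ms,
    pos_shift_n = pos_shift / ms,
    neg_shift_n = neg_shift / ms,
    pos_shift_prev_n = c(NA, pos_shift[-n]) / ms,
    earnings_n = earnings / es,
    expectation_n = expectation / es,
    outcome_n = records$outcome / ms)
  tab$earn_x_prevout <- tab$earnings_n * tab$prev_outcome_n
  tab$earn_x_out <- tab$earnings_n * tab$outcome_n
  tab$prevout_x_posshift <- tab$prev_outcome_n * tab$pos_shift_n

  prev_missed <- c(TRUE, records$missed[-n])  # trial 1 treated like "no predecessor"
  keep <- !records$missed & !prev_missed
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature table for a whole cohort
#'
#' Applies [build_features()] per subject with the cohort's shared
#' normalization scheme and binds the rows with a `subject` factor.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @return a `feature_table` with a `subject` column.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(seq_along(cohort$subjects), function(s) {
    f <- build_features(cohort$subjects[[s]]$set, cohort$subjects[[s]]$records,
                        cohort$norm)
    f$subject <- s
    f
  })
  out <- do.call(rbind, rows)
  out$subject <- factor(out$subject)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
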