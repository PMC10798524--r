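## ---------------------------------------------------------------------------
## Synthetic cohorts: context-sensitive choosers simulated from a hierarchical
## logistic model whose fixed-effect pattern follows the fitted behavioral
## models (current-trial value sensitivity plus previous-outcome, shift,
## earnings-vs-expectation and earnings-by-outcome terms), with stochastic
## 50/50 gamble outcomes accumulating into earnings.
## ---------------------------------------------------------------------------

#' Default population parameters for the synthetic cohort
#'
#' Coefficient means follow the fitted estimates of the current-trial model
#' (risky gain 30.88, safe -13.18, magnitude -49.51) and the full context
#' model (previous outcome -0.7, positive shift 5.3, negative shift -0.37,
#' cumulative earnings 0.37, linear expectation -0.26, earnings-by-outcome
#' interaction 1.3), all on the normalized-regressor scale. Between-subject
#' SDs for the risky-gain and safe slopes use an SE-times-sqrt(N) heuristic
#' from the printed standard errors (N = 62); context coefficients are
#' population-homogeneous because the context models posit them as pure fixed
#' effects alongside a subject random intercept (SD 0.3 by default).
#'
#' SCR parameters are stated on the square-root/maximum normalized amplitude
#' scale and converted to microsiemens via `max_amp` (the subject-level
#' maximum response, default 0.4 uS): baseline outcome-response level
#' `alpha0`, earnings gain `alpha_earnings` (0.12 per unit normalized
#' earnings), baseline decision-response level `delta0`, and positive-shift
#' gain `delta_shift` (0.41 per unit normalized positive shift).
#'
#' @return a named list with `mean`, `sd` (coefficient vectors) and `scr`
#'   (SCR synthesis parameters).
#' @export
default_population <- function() {
  means <- c(b_riskygain = 30.88, b_safe = -13.18, b_magnitude = -49.51,
             b_prev_outcome = -0.7, b_pos_shift = 5.3, b_neg_shift = -0.37,
             b_earnings = 0.37, b_expectation = -0.26, b_interaction = 1.3)
  sds <- c(b_riskygain = 2.9 * sqrt(62), b_safe = 5.19 * sqrt(62),
           b_magnitude = 0, b_prev_outcome = 0, b_pos_shift = 0,
           b_neg_shift = 0, b_earnings = 0, b_expectation = 0,
           b_interaction = 0)
  list(mean = means, sd = sds, sd_intercept = 0.3,
       scr = list(alpha0 = 0.5, alpha_earnings = 0.12,
                  delta0 = 0.4, delta_shift = 0.41,
                  nonresponse_prob = 0.5, amp_noise_sd = 0.1,
                  trace_noise_sd = 0.003, max_amp = 0.4,
                  tonic_level = 2, drift_amplitude = 0.02,
                  drift_period = 120))
}

#' Draw one subject's parameters from a population configuration
#'
#' Coefficients are drawn normally around the configured means; with all SDs
#' zero every subject equals the population mean. The subject's random
#' intercept is drawn from `N(0, sd_intercept^2)` and SCR parameters are
#' copied from the population block.
#'
#' @param population a list as returned by [default_population()].
#' @param seed integer seed.
#' @return an object of class `subject_params`.
#' @export
sample_subject_params <- function(population = default_population(), seed = 1L) {
  if (any(population$sd < 0) || population$sd_intercept < 0)
    config_stop("population SDs must be >= 0")
  scr <- population$scr
  if (scr$nonresponse_prob < 0 || scr$nonresponse_prob > 1)
    config_stop("nonresponse_prob must lie in [0, 1]")
  set.seed(seed)
  b <- population$mean + rnorm(length(population$mean), 0, population$sd)
  names(b) <- names(population$mean)
  structure(list(beta = b,
                 intercept = rnorm(1, 0, population$sd_intercept),
                 scr = scr),
            class = "subject_params")
}

## linear predictor for one trial given realized history (internal)
trial_linear_predictor <- function(params, set, t, prev_outcome, earnings,
                                   expectation, norm) {
  b <- params$beta
  ms <- norm$money_scale; es <- norm$earnings_scale
  pos <- max(set$shift[t], 0) / ms
  neg <- min(set$shift[t], 0) / ms
  po <- if (is.na(prev_outcome)) 0 else prev_outcome / ms
  en <- earnings / es
  eta <- b[["b_riskygain"]] * set$risky_gain[t] / ms +
    b[["b_safe"]] * set$safe[t] / ms +
    b[["b_magnitude"]] * set$ev_level[t] / ms +
    b[["b_prev_outcome"]] * po +
    b[["b_pos_shift"]] * pos + b[["b_neg_shift"]] * neg +
    b[["b_earnings"]] * en +
    b[["b_expectation"]] * expectation[t] / es +
    b[["b_interaction"]] * en * po +
    params$intercept
  unname(eta)
}

#' Simulate one subject's choices on a structured choice set
#'
#' Proceeds trial by trial: the normalized linear predictor is assembled from
#' current-trial amounts and the realized history (previous outcome, shift,
#' cumulative earnings and linear expectation), the gamble is taken with
#' probability `plogis(eta)`, and a taken gamble pays its risky gain with
#' probability 0.5 (else $0) while a rejected gamble pays the safe amount.
#' Earnings accumulate forward. Previous-outcome terms are zero wherever the
#' predecessor outcome is undefined (trial 1 or after a missed trial).
#' Missed trials are injected uniformly at random at `miss_rate` and carry no
#' choice or outcome.
#'
#' @param set a `choice_set` from [make_choice_set()].
#' @param params a `subject_params` from [sample_subject_params()].
#' @param norm a `normalization_scheme`; see [normalization_scheme()].
#' @param seed integer seed.
#' @param miss_rate probability a trial is missed (default 0.005).
#' @param rt_range uniform reaction-time range in seconds (used only for
#'   event timing in SCR synthesis).
#' @return a data.frame of trial records: `trial`, `choice` (1 = gamble),
#'   `outcome` (dollars), `p_gamble` (the model probability behind the
#'   choice draw, useful for verification), `rt` (seconds), `missed`.
#' @export
simulate_choices <- function(set, params, norm, seed = 1L, miss_rate = 0.005,
                             rt_range = c(0.3, 2)) {
  stopifnot(inherits(set, "choice_set"), inherits(params, "subject_params"))
  n <- nrow(set)
  expectation <- linear_expectation(set)
  set.seed(seed)
  missed <- runif(n) < miss_rate
  rt <- runif(n, rt_range[1], rt_range[2])
  rt[missed] <- NA_real_
  choice <- rep(NA_integer_, n)
  outcome <- rep(NA_real_, n)
  p_gamble <- rep(NA_real_, n)
  earnings <- 0
  prev_outcome <- NA_real_
  for (t in seq_len(n)) {
    if (!missed[t]) {
      eta <- trial_linear_predictor(params, set, t, prev_outcome, earnings,
                                    expectation, norm)
      p_gamble[t] <- logistic(eta)
      choice[t] <- rbinom(1, 1, p_gamble[t])
      outcome[t] <- if (choice[t] == 1L) {
        if (runif(1) < set$p_win[t]) set$risky_gain[t] else 0
      } else set$safe[t]
      earnings <- earnings + outcome[t]
      prev_outcome <- outcome[t]
    } else {
      prev_outcome <- NA_real_  # predecessor undefined for the next trial
    }
  }
  data.frame(trial = set$trial, choice = choice, outcome = outcome,
             p_gamble = p_gamble, rt = rt, missed = missed)
}

#' Attach event timing to trial records
#'
#' Trial timing follows the task structure: options are displayed for 2 s,
#' then a response window of up to 2 s (the response lands at
#' `decision onset + 2 + rt`), a 0.5 s interstimulus interval, a 1 s outcome
#' display, and a uniform 1.5-4.5 s intertrial interval to which the unused
#' response time (2 - rt) is added. Missed trials consume the full timeline
#' with no response event.
#'
#' @param records trial records from [simulate_choices()].
#' @param seed integer seed for the ITI draws.
#' @param iti_range intertrial-interval range in seconds.
#' @param display_s,response_s,isi_s,outcome_s phase durations in seconds.
#' @return `records` with columns `t_decision`, `t_response`, `t_outcome`
#'   (absolute onset times in seconds; `NA` response for missed trials).
#' @export
trial_event_times <- function(records, seed = 1L, iti_range = c(1.5, 4.5),
                              display_s = 2, response_s = 2, isi_s = 0.5,
                              outcome_s = 1) {
  n <- nrow(records)
  set.seed(seed)
  iti <- runif(n, iti_range[1], iti_range[2])
  t_decision <- t_response <- t_outcome <- numeric(n)
  now <- 10  # lead-in so the first scoring window is fully recorded
  for (t in seq_len(n)) {
    t_decision[t] <- now
    rt <- if (is.na(records$rt[t])) response_s else records$rt[t]
    t_response[t] <- now + display_s + rt
    t_outcome[t] <- t_response[t] + isi_s
    now <- t_outcome[t] + outcome_s + iti[t] + (response_s - rt)
  }
  t_response[records$missed] <- NA_real_
  records$t_decision <- t_decision
  records$t_response <- t_response
  records$t_outcome <- t_outcome
  records
}

#' Simulate a cohort of subjects on freshly generated choice sets
#'
#' Each subject receives an independently sampled structured choice set and
#' parameter draw (seeds derived from `seed`, the stage name and the subject
#' id). A single normalization scheme is fixed for the whole cohort before
#' any choice is simulated: the money scale is the maximum risky gain across
#' the generated sets and the earnings scale is the cohort-average expected
#' total earnings, unless `norm` is supplied.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject.
#' @param population population configuration ([default_population()]).
#' @param norm optional `normalization_scheme` fixed in advance.
#' @param seed integer master seed.
#' @param miss_rate per-trial miss probability.
#' @param timing if `TRUE`, attach event timing to each subject's records.
#' @param ... further arguments to [make_choice_set()].
#' @return an object of class `cohort`: list with `subjects` (per-subject
#'   lists of `set`, `params`, `records`), the shared `norm`, and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 60L, n_trials = 240L,
                            population = default_population(), norm = NULL,
                            seed = 1L, miss_rate = 0.005, timing = FALSE, ...) {
  sets <- lapply(seq_len(n_subjects), function(s)
    make_choice_set(n_trials = n_trials, seed = derive_seed(seed, "task", s), ...))
  if (is.null(norm)) norm <- default_normalization(sets)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    params <- sample_subject_params(population, seed = derive_seed(seed, "params", s))
    records <- simulate_choices(sets[[s]], params, norm,
                                seed = derive_seed(seed, "choices", s),
                                miss_rate = miss_rate)
    if (timing)
      records <- trial_event_times(records, seed = derive_seed(seed, "timing", s))
    list(set = sets[[s]], params = params, records = records)
  })
  structure(list(subjects = subjects, norm = norm, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d trials each\n",
              length(x$subjects), nrow(x$subjects[[1]]$set)))
  cat(sprintf("  money scale $%.2f, earnings scale $%.2f\n",
              x$norm$money_scale, x$norm$earnings_scale))
  invisible(x)
}
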