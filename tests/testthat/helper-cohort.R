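# shared fixtures built in code: small feasible designs and quiet fitting

# a compact structured design: 60-120 trials in 4-5 runs of 9-30 trials
small_choice_set <- function(seed = 1, n_trials = 60) {
  make_choice_set(n_trials = n_trials, n_runs_range = c(4, 5),
                  length_range = c(9, 30), seed = seed)
}

small_cohort <- function(n_subjects = 6, n_trials = 60, seed = 1,
                         population = default_population(), ...) {
  simulate_cohort(n_subjects = n_subjects, n_trials = n_trials,
                  population = population, seed = seed,
                  n_runs_range = c(4, 5), length_range = c(9, 30), ...)
}

# population with every context coefficient switched off
null_population <- function() {
  pop <- default_population()
  pop$mean[c("b_prev_outcome", "b_pos_shift", "b_neg_shift", "b_earnings",
             "b_expectation", "b_interaction")] <- 0
  pop
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
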