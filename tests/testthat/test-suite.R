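test_that("model specifications render to the documented pseudo-code", {
  sp <- behavior_model_specs()
  expect_identical(render_model(sp$m1),
    'glmer(choice(t) ~ 0 + risky gain amount(t) + safe amount(t) + magnitude(t) + (0 + risky gain amount(t) + safe amount(t) | Subject ID), family = "binomial")')
  expect_identical(render_model(sp$m2),
    'glmer(choice(t) ~ 0 + outcome(t-1) + (1 | Subject ID), family = "binomial", offset = predicted values from model 1)')
  expect_identical(render_model(sp$m3a),
    'glmer(choice(t) ~ 0 + outcome(t-1) + positive shift amount(t) + negative shift amount(t) + (1 | Subject ID), family = "binomial", offset = predicted values from model 1)')
  expect_identical(render_model(sp$m3b),
    'glmer(choice(t) ~ 0 + outcome(t-1) + positive shift amount(t) + positive shift amount(t-1) + (1 | Subject ID), family = "binomial", offset = predicted values from model 1)')
  expect_identical(render_model(sp$m4a),
    'glmer(choice(t) ~ 0 + outcome(t-1) + positive shift amount(t) + cumulative earnings(t) + linear expectation(t) + (1 | Subject ID), family = "binomial", offset = predicted values from model 1)')
  expect_identical(render_model(sp$m4b),
    'glmer(choice(t) ~ 0 + outcome(t-1) + positive shift amount(t) + cumulative earnings(t) + cumulative earnings(t)*outcome(t-1) + linear expectation(t) + (1 | Subject ID), family = "binomial", offset = predicted values from model 1)')
  ssp <- scr_model_specs()
  expect_identical(render_model(ssp$m5c),
    'lmer(SCR following outcome(t) ~ 1 + cumulative earnings(t) + linear expectation(t) + (1 | Subject ID))')
  expect_identical(render_model(ssp$m7),
    'lmer(SCR during decision phase(t) ~ 1 + choice(t) + (1 | Subject ID))')
  expect_identical(render_model(ssp$m8c),
    'glmer(choice(t) ~ 0 + outcome(t-1) + positive shift amount(t) + cumulative earnings(t) + cumulative earnings(t)*outcome(t-1) + SCR during decision phase(t) + (1 | Subject ID), family = "binomial", offset = predicted values from model 1)')
  # model 3c's offset source is configurable
  expect_match(render_model(behavior_model_specs("model3a")$m3c),
               "predicted values from model 3a")
})

test_that("the two-step suite recovers strong context effects with the right signs", {
  # previous-outcome effect, assessed on a single-run design where the EV
  # level never moves: previous outcomes are then nearly orthogonal to
  # current-trial amounts, so the two-step procedure attenuates little
  # modest heterogeneity so no subject is a deterministic chooser
  pop <- default_population()
  pop$mean["b_prev_outcome"] <- -4
  pop$sd["b_riskygain"] <- 4
  pop$sd["b_safe"] <- 4
  co <- simulate_cohort(n_subjects = 10, n_trials = 100, population = pop,
                        seed = 31, miss_rate = 0, n_runs_range = c(1, 1),
                        length_range = c(100, 100))
  f <- cohort_features(co)
  rep <- quiet(run_behavior_suite(f, nAGQ_step1 = 0, models = "m2"))
  co2 <- rep$fits$m2$coefficients
  expect_lt(co2$estimate[co2$term == "prev_outcome_n"], 0)
  expect_lt(co2$p[co2$term == "prev_outcome_n"], 0.05)
  # the offset column is exactly model 1's linear predictions
  expect_equal(rep$features$offset1, linear_predictions(rep$fits$m1))

  # positive-shift effect, assessed on a shift-rich design (many short runs)
  pop2 <- default_population()
  pop2$mean["b_pos_shift"] <- 8
  pop2$sd["b_riskygain"] <- 4
  pop2$sd["b_safe"] <- 4
  co2b <- simulate_cohort(n_subjects = 10, n_trials = 120, population = pop2,
                          seed = 32, miss_rate = 0, n_runs_range = c(10, 13),
                          length_range = c(9, 12))
  f2 <- cohort_features(co2b)
  rep2 <- quiet(run_behavior_suite(f2, nAGQ_step1 = 0, models = "m3a"))
  co3 <- rep2$fits$m3a$coefficients
  expect_gt(co3$estimate[co3$term == "pos_shift_n"], 0)
  # model ids propagate
  expect_identical(rep2$fits$m3a$model_id, "3a")
})

test_that("two-step context estimates match the joint fit on orthogonal designs", {
  # with context regressors independent of current-trial regressors, freezing
  # step 1 loses nothing: the two routes agree within 2 standard errors
  set.seed(21)
  n_sub <- 12; n_per <- 150
  id <- factor(rep(seq_len(n_sub), each = n_per))
  n <- n_sub * n_per
  # centered regressors, so omitting the context terms in step 1 does not
  # displace the intercept or the current-trial coefficients
  d <- data.frame(subject = id,
                  riskygain_n = runif(n, -0.5, 0.5), safe_n = runif(n, -0.5, 0.5),
                  prev_outcome_n = runif(n, -0.5, 0.5),
                  pos_shift_n = rbinom(n, 1, 0.1) * runif(n, -0.5, 0.5))
  b0 <- rnorm(n_sub, 0, 0.3)
  eta <- 2 * d$riskygain_n - 1.5 * d$safe_n - 0.8 * d$prev_outcome_n +
    2 * d$pos_shift_n + b0[as.integer(id)]
  d$choice <- rbinom(n, 1, plogis(eta))
  step1 <- quiet(fit_binomial_glmm(d, model_spec("choice", c("riskygain_n", "safe_n"),
                                                 random = "intercept",
                                                 intercept = TRUE)))
  d$offset1 <- linear_predictions(step1)
  step2 <- quiet(fit_binomial_glmm(d, model_spec("choice",
                                                 c("prev_outcome_n", "pos_shift_n"),
                                                 offset = "offset1")))
  joint <- quiet(fit_binomial_glmm(d, model_spec("choice",
                                                 c("riskygain_n", "safe_n",
                                                   "prev_outcome_n", "pos_shift_n"),
                                                 random = "intercept",
                                                 intercept = TRUE)))
  for (term in c("prev_outcome_n", "pos_shift_n")) {
    e2 <- step2$coefficients[step2$coefficients$term == term, ]
    ej <- joint$coefficients[joint$coefficients$term == term, ]
    expect_lt(abs(e2$estimate - ej$estimate), 2 * ej$se, label = term)
  }
})

test_that("the SCR suite ties amplitudes to their generative drivers", {
  pop <- default_population()
  pop$scr$alpha_earnings <- 0.6    # strong earnings drive, small cohort
  pop$scr$delta_shift <- 1.2
  pop$scr$nonresponse_prob <- 0.1
  pop$scr$amp_noise_sd <- 0.05
  co <- small_cohort(n_subjects = 6, n_trials = 60, seed = 41,
                     population = pop, miss_rate = 0, timing = TRUE)
  scored <- do.call(rbind, lapply(seq_along(co$subjects), function(s) {
    subj <- co$subjects[[s]]
    tr <- synthesize_scr_trace(subj$records, subj$set, subj$params, co$norm,
                               seed = derive_seed(41, "scr", s))
    sc <- score_subject(tr)
    do.call(rbind, lapply(c("outcome", "decision"), function(ph)
      data.frame(subject = s, phase = ph, sc[[ph]]$events,
                 responder = sc[[ph]]$responder)))
  }))
  keep <- function(ph) {
    d <- scored[scored$phase == ph & scored$responder, ]
    data.frame(subject = d$subject, trial = d$trial, normalized = d$normalized)
  }
  f <- cohort_features(co)
  beh <- quiet(run_behavior_suite(f, nAGQ_step1 = 0, models = "m2"))
  fs <- attach_scr(beh$features, keep("outcome"), keep("decision"))
  scr_rep <- quiet(run_scr_suite(fs, models = c("m5c", "m7", "m8a", "m6a")))
  co5c <- scr_rep$fits$m5c$coefficients
  expect_gt(co5c$estimate[co5c$term == "earnings_n"], 0)
  co8a <- scr_rep$fits$m8a$coefficients
  expect_gt(co8a$estimate[co8a$term == "pos_shift_n"], 0)
  expect_identical(scr_rep$fits$m7$spec$family, "gaussian")
  # behavioral SCR model carries the offset and an SCR term
  expect_true("scr_prev_n" %in% scr_rep$fits$m6a$coefficients$term)
  # earnings monotonicity: a stronger generative drive yields a larger
  # fitted earnings coefficient in the outcome-SCR model
  slope_at <- function(alpha, seed) {
    pop2 <- pop
    pop2$scr$alpha_earnings <- alpha
    co2 <- small_cohort(n_subjects = 6, n_trials = 60, seed = seed,
                        population = pop2, miss_rate = 0, timing = TRUE)
    scored2 <- do.call(rbind, lapply(seq_along(co2$subjects), function(s) {
      subj <- co2$subjects[[s]]
      tr <- synthesize_scr_trace(subj$records, subj$set, subj$params, co2$norm,
                                 seed = derive_seed(seed, "scr", s))
      ev <- score_subject(tr)$outcome$events
      data.frame(subject = s, trial = ev$trial, normalized = ev$normalized)
    }))
    f2 <- cohort_features(co2)
    f2$offset1 <- 0
    fs2 <- attach_scr(f2, scored2, NULL)
    fit <- quiet(run_scr_suite(fs2, models = "m5c"))$fits$m5c$coefficients
    fit$estimate[fit$term == "earnings_n"]
  }
  slopes <- vapply(c(0, 0.3, 0.6), slope_at, numeric(1), seed = 43)
  expect_true(all(diff(slopes) > 0))
})

test_that("paired category comparisons handle degenerate and exact cases", {
  ev <- data.frame(subject = rep(1:5, each = 2),
                   category = rep(c("win", "safe"), 5),
                   value = rep(c(0.2, 0.2), 5))
  out <- paired_category_tests(ev)
  expect_equal(out$tests$t, 0)
  expect_equal(out$tests$p, 1)
  # mirrored differences across two subjects: t = 0
  ev2 <- data.frame(subject = rep(1:2, each = 2),
                    category = rep(c("a", "b"), 2),
                    value = c(0.3, 0.2, 0.2, 0.3))
  expect_equal(paired_category_tests(ev2)$tests$t, 0)
  # subjects lacking a category are dropped with a warning
  ev3 <- rbind(ev, data.frame(subject = 6, category = "win", value = 0.4))
  expect_warning(paired_category_tests(ev3), "dropped")
  # exact Wilcoxon on n = 6 equals brute-force enumeration of sign flips
  d <- c(0.11, -0.23, 0.05, 0.17, -0.02, 0.08)
  ev4 <- data.frame(subject = rep(1:6, each = 2),
                    category = rep(c("a", "b"), 6),
                    value = as.vector(rbind(d, 0)))
  got <- paired_category_tests(ev4, wilcoxon = TRUE)$tests
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  v_null <- as.matrix(signs) %*% r
  p_exact <- mean(abs(v_null - sum(r) / 2) >= abs(v_obs - sum(r) / 2) - 1e-9)
  expect_equal(got$V, v_obs)
  expect_equal(got$p_wilcoxon, p_exact, tolerance = 1e-9)
})

test_that("logistic effect translations reproduce the printed percentages", {
  expect_equal(round(effect_to_probability(-0.15, 68 / 68), 1), -3.7)
  expect_equal(round(effect_to_probability(4.8, 15 / 68), 1), 24.2)
  expect_identical(effect_to_probability(0, 0.73), 0)
  expect_equal(effect_to_probability(0, 1, baseline = 0.3), 0)
  # symmetric around the baseline on the logit scale
  expect_equal(effect_to_probability(1.2, 0.5),
               -effect_to_probability(-1.2, 0.5))
  expect_error(effect_to_probability(1, 1, baseline = 1), "baseline")
})

test_that("AIC ranking orders models and refuses mismatched data", {
  d <- data.frame(subject = factor(rep(1:8, each = 60)))
  set.seed(33)
  d$x <- runif(480)
  b <- rnorm(8, 0, 0.3)
  d$y <- rbinom(480, 1, plogis(1.5 * d$x + b[as.integer(d$subject)]))
  d$z <- runif(480)  # irrelevant regressor
  true_fit <- quiet(fit_binomial_glmm(d, model_spec("y", "x", intercept = TRUE),
                                      model_id = "true"))
  null_fit <- quiet(fit_binomial_glmm(d, model_spec("y", "z", intercept = TRUE),
                                      model_id = "null"))
  rk <- compare_aic(list(true_fit, null_fit))
  expect_identical(rk$model[1], "true")
  expect_equal(rk$delta_aic[1], 0)
  expect_gt(rk$delta_aic[2], 0)
  # identical fits tie at delta 0
  tie <- compare_aic(list(true_fit, true_fit))
  expect_equal(tie$delta_aic, c(0, 0))
  # AIC recomputed from (loglik, k) matches the stored value exactly
  expect_equal(rk$aic[1], -2 * true_fit$log_likelihood + 2 * true_fit$df)
  short <- quiet(fit_binomial_glmm(d[1:240, ], model_spec("y", "x", intercept = TRUE)))
  expect_error(compare_aic(list(true_fit, short)), "differing")
})
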