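make_trace <- function(x, fs = 200) {
  structure(list(time = (seq_along(x) - 1) / fs, conductance = x,
                 events = data.frame(onset = numeric(0), kind = character(0),
                                     trial = integer(0)),
                 fs = fs), class = "scr_trace")
}

test_that("the low-pass filter has unit DC gain and the designed frequency response", {
  x <- rep(3.5, 2000)
  expect_equal(lowpass_fir(make_trace(x))$conductance, x, tolerance = 1e-9)

  # oracle: evaluate the designed filter's transfer function |H(f)| directly
  b <- signal::fir1(15, 25 / 100)
  b <- b / sum(b)
  H <- function(f_hz, fs = 200) {
    w <- 2 * pi * f_hz / fs
    Mod(sum(b * exp(-1i * w * (seq_along(b) - 1))))
  }
  fs <- 200
  tt <- (0:7999) / fs
  for (f_hz in c(5, 80)) {
    y <- lowpass_fir(make_trace(sin(2 * pi * f_hz * tt)))$conductance
    core <- 500:7500  # steady-state region
    gain <- sqrt(mean(y[core]^2) / mean(sin(2 * pi * f_hz * tt[core])^2))
    expect_equal(gain, H(f_hz), tolerance = 0.01)
  }
  expect_gt(H(5), 0.95)   # passband preserved
  expect_lt(H(80), 0.15)  # stopband attenuated
})

test_that("group delay is compensated so features stay aligned", {
  tt <- (0:1999) / 200
  x <- exp(-(tt - 5)^2 / 0.1)  # smooth bump centered at 5 s
  y <- lowpass_fir(make_trace(x))$conductance
  expect_lt(abs(which.max(y) - which.max(x)), 2)  # within 1 sample
  expect_error(lowpass_fir(make_trace(rep(1, 8))), "shorter")
})

test_that("Blackman weights match the hand-computed window", {
  # w_k = 0.42 - 0.5 cos(2 pi k/(N-1)) + 0.08 cos(4 pi k/(N-1)), sum-normalized;
  # for N = 3 the endpoints are exactly zero, so the window is the identity
  expect_equal(blackman_weights(3), c(0, 1, 0))
  k <- 0:4
  w5 <- 0.42 - 0.5 * cos(2 * pi * k / 4) + 0.08 * cos(4 * pi * k / 4)
  expect_equal(blackman_weights(5), w5 / sum(w5))
  expect_identical(blackman_weights(1), 1)

  x <- rnorm(500)
  expect_equal(smooth_blackman(make_trace(x), 1)$conductance, x)
  # constant input unchanged (edges included, via renormalized partial windows)
  expect_equal(smooth_blackman(make_trace(rep(2, 100)), 5)$conductance, rep(2, 100))
  # impulse spreads to the normalized window profile
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smooth_blackman(make_trace(imp), 5)$conductance
  expect_equal(sm[9:13], w5 / sum(w5), tolerance = 1e-12)
  expect_error(smooth_blackman(make_trace(x), 4), "odd")
})

test_that("trough-to-peak scoring uses the running minimum and the floor", {
  fs <- 200
  # monotone decline: no rise, score 0
  dec <- make_trace(2 + seq(1, 0, length.out = 6 * fs))
  expect_identical(score_event(dec, onset = 0.5), 0)
  # early peak then decline cannot inflate the score beyond the largest rise
  tt <- (0:(6 * fs)) / fs
  x <- 2 + 0.5 * exp(-(tt - 1)^2 / 0.05) + 0.1 * exp(-(tt - 4)^2 / 0.05)
  tr <- make_trace(x)
  amp <- score_event(tr, onset = 0.5, window = c(2, 5.5))
  expect_lt(amp, 0.2)  # only the late 0.1 bump rises within the window
  expect_gt(amp, 0.08)
  # baseline invariance
  tr_shift <- make_trace(x + 11.3)
  expect_equal(score_event(tr_shift, onset = 0.5, window = c(2, 5.5)), amp)
  # window past the end of the trace is a truncated-trial error
  expect_error(score_event(tr, onset = 5), "truncated")
})

test_that("noise-free synthesized amplitudes are recovered through the full chain", {
  amps <- c(0.30, 0.10, 0.05, 0.015, 0)
  ev <- data.frame(onset = seq(20, by = 40, length.out = 5), amplitude = amps,
                   kind = "outcome", trial = 1:5)
  tr <- synthesize_trace(ev, duration = 220, noise_sd = 0, tonic_level = 2,
                         drift_amplitude = 0)
  scored <- score_events(preprocess_scr(tr), "outcome")
  above <- amps >= 0.02
  expect_equal(scored$raw[above], amps[above], tolerance = 0.05)
  expect_identical(scored$raw[!above], c(0, 0))
  # kernel is unit-peak: a single event's trough-to-peak equals its amplitude
  one <- synthesize_trace(data.frame(onset = 10, amplitude = 0.25),
                          duration = 40, noise_sd = 0)
  expect_equal(score_event(one, 10), 0.25, tolerance = 0.01 * 0.25)
  # all-nonresponse trace is flat at the baseline
  flat <- synthesize_trace(data.frame(onset = c(5, 15), amplitude = c(0, 0)),
                           duration = 30, noise_sd = 0, tonic_level = 2)
  expect_equal(unique(flat$conductance), 2)
})

test_that("sqrt-max normalization and the responder rule behave per contract", {
  sc <- normalize_subject(c(0.04, 0.16))
  expect_equal(sc$events$normalized, c(0.5, 1.0))
  expect_equal(sc$max_sqrt_amplitude, 0.4)
  expect_equal(sc$response_fraction, 1)
  expect_identical(normalize_subject(0.07)$events$normalized, 1)
  z <- normalize_subject(rep(0, 5))
  expect_true(all(z$events$normalized == 0))
  expect_identical(z$response_fraction, 0)
  expect_false(classify_responder(z))
  # 130 nonzero of 240 events: responder
  sc130 <- normalize_subject(c(runif(130, 0.05, 0.3), rep(0, 110)))
  expect_true(classify_responder(sc130))
  # strict inequality at the 25% boundary
  sc60 <- normalize_subject(c(runif(60, 0.05, 0.3), rep(0, 180)))
  expect_equal(sc60$response_fraction, 0.25)
  expect_false(classify_responder(sc60))
  # renormalization fixed points: zeros stay zero, the maximum stays 1,
  # ordering is preserved (sqrt is monotone)
  v <- sc130$events$normalized
  re <- normalize_subject(v)$events$normalized
  expect_identical(re[v == 0], v[v == 0])
  expect_equal(max(re), 1)
  expect_identical(order(re), order(v))
  expect_error(normalize_subject(c(0.1, -0.2)), ">= 0")
})

test_that("subject-level scoring separates decision and outcome phases", {
  set <- small_choice_set(seed = 13, n_trials = 40)
  # use 40 trials in 3-4 runs for a quick trace
  set <- make_choice_set(n_trials = 40, n_runs_range = c(3, 4),
                         length_range = c(9, 15), seed = 13)
  norm <- default_normalization(set)
  params <- sample_subject_params(default_population(), seed = 4)
  rec <- trial_event_times(simulate_choices(set, params, norm, seed = 5,
                                            miss_rate = 0), seed = 6)
  tr <- synthesize_scr_trace(rec, set, params, norm, seed = 7)
  sc <- score_subject(tr)
  expect_identical(nrow(sc$outcome$events), 40L)
  expect_identical(nrow(sc$decision$events), 40L)
  for (ph in c("outcome", "decision")) {
    ev <- sc[[ph]]$events
    expect_true(all(ev$raw >= 0))
    expect_true(all(ev$normalized >= 0 & ev$normalized <= 1))
    if (any(ev$raw > 0)) expect_equal(max(ev$normalized), 1)
  }
})
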