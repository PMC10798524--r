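## ---------------------------------------------------------------------------
## Electrodermal scoring: FIR low-pass filtering with group-delay
## compensation, Blackman-window smoothing, windowed trough-to-peak amplitude
## with a 0.02 uS floor, square-root/maximum normalization per subject, and
## the 25% responder rule.
## ---------------------------------------------------------------------------

## apply f to the conductance series of a trace (or a bare numeric vector)
apply_to_trace <- function(trace, f) {
  if (inherits(trace, "scr_trace")) {
    trace$conductance <- f(trace$conductance, trace$fs)
    trace
  } else {
    f(trace, NA_real_)
  }
}

#' Low-pass FIR filter with group-delay compensation
#'
#' Designs a linear-phase windowed-sinc filter (via [signal::fir1()]) with
#' `n_coefficients` taps and the given cutoff, renormalizes the taps to unit
#' DC gain, and applies it forward with the group delay
#' `(n_coefficients - 1) / 2` samples compensated by index shifting, so event
#' alignment is preserved (to within half a sample for an even tap count).
#' Edges are padded by replicating the boundary samples.
#'
#' @param trace an `scr_trace` (or bare numeric vector plus `fs`).
#' @param cutoff_hz cutoff frequency in Hz (default 25).
#' @param n_coefficients number of filter taps (default 16).
#' @param fs sampling rate, required only when `trace` is a bare vector.
#' @return the filtered trace (same class as the input).
#' @export
lowpass_fir <- function(trace, cutoff_hz = 25, n_coefficients = 16, fs = NULL) {
  apply_to_trace(trace, function(x, fs_trace) {
    fs_use <- if (!is.na(fs_trace)) fs_trace else fs
    if (is.null(fs_use)) config_stop("fs must be given for a bare numeric trace")
    if (fs_use <= 2 * cutoff_hz)
      config_stop("sampling rate %g must exceed twice the cutoff %g Hz",
                  fs_use, cutoff_hz)
    if (length(x) < n_coefficients)
      config_stop("trace of length %d is shorter than the %d-tap filter",
                  length(x), n_coefficients)
    b <- signal::fir1(n_coefficients - 1L, cutoff_hz / (fs_use / 2))
    b <- b / sum(b)  # unit DC gain
    d <- floor((n_coefficients - 1L) / 2)
    P <- n_coefficients
    xp <- c(rep(x[1], P), x, rep(x[length(x)], P))
    y <- stats::filter(xp, b, method = "convolution", sides = 1L)
    ## y[P + j] is the delayed output aligned with x[j - d]; shift forward by d
    as.numeric(y[(P + 1L + d):(P + length(x) + d)])
  })
}

#' Blackman-window weights
#'
#' Standard symmetric Blackman taper
#' `w_k = 0.42 - 0.5 cos(2 pi k / (N-1)) + 0.08 cos(4 pi k / (N-1))`,
#' normalized to sum 1. Note the conventional 3-sample window has zero
#' endpoints, so 3-sample Blackman smoothing is numerically (almost) the
#' identity; it is retained for procedural fidelity.
#'
#' @param n window length (odd).
#' @return numeric weights summing to 1.
#' @export
blackman_weights <- function(n) {
  stopifnot(n >= 1, n %% 2 == 1)
  if (n == 1) return(1)
  k <- 0:(n - 1)
  w <- 0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
  w / sum(w)
}

#' Smooth a trace with a Blackman window
#'
#' Weighted moving average with [blackman_weights()]; edges use renormalized
#' partial windows so a constant input is reproduced exactly everywhere.
#'
#' @param trace an `scr_trace` or numeric vector.
#' @param window_samples odd window length (default 3).
#' @return the smoothed trace (same class as the input).
#' @export
smooth_blackman <- function(trace, window_samples = 3L) {
  if (window_samples %% 2 == 0)
    config_stop("window_samples must be odd (got %d)", window_samples)
  apply_to_trace(trace, function(x, fs_trace) {
    if (window_samples == 1L) return(x)
    w <- blackman_weights(window_samples)
    h <- (window_samples - 1L) %/% 2L
    num <- stats::filter(c(rep(0, h), x, rep(0, h)), w, sides = 1L)
    den <- stats::filter(c(rep(0, h), rep(1, length(x)), rep(0, h)), w, sides = 1L)
    as.numeric((num / den)[(2L * h + 1L):(2L * h + length(x))])
  })
}

#' Preprocess a skin-conductance trace
#'
#' Applies the standard chain: low-pass FIR filter then Blackman smoothing.
#'
#' @inheritParams lowpass_fir
#' @inheritParams smooth_blackman
#' @return the preprocessed `scr_trace`.
#' @export
preprocess_scr <- function(trace, cutoff_hz = 25, n_coefficients = 16,
                           window_samples = 3L) {
  smooth_blackman(lowpass_fir(trace, cutoff_hz, n_coefficients),
                  window_samples)
}

#' Score one event by windowed trough-to-peak amplitude
#'
#' Within the window `onset + window[1]` to `onset + window[2]`, the score is
#' the largest rise from a running minimum,
#' `max_t (x_t - min_{s <= t} x_s)`, so a decline after an early peak cannot
#' inflate the score. Scores below `floor` return 0. The score is invariant
#' to adding any constant to the whole trace.
#'
#' @param trace a (preprocessed) `scr_trace`.
#' @param onset event onset in seconds.
#' @param window two-element window in seconds relative to onset
#'   (default `c(0.5, 4.5)`).
#' @param floor amplitude floor in uS (default 0.02).
#' @return the raw amplitude in uS (0 if below the floor).
#' @export
score_event <- function(trace, onset, window = c(0.5, 4.5), floor = 0.02) {
  stopifnot(inherits(trace, "scr_trace"), window[2] > window[1])
  t0 <- onset + window[1]
  t1 <- onset + window[2]
  if (t0 < trace$time[1] || t1 > trace$time[length(trace$time)])
    config_stop("scoring window [%.2f, %.2f] s extends past the recorded trace (truncated trial at onset %.2f s)",
                t0, t1, onset)
  i0 <- round((t0 - trace$time[1]) * trace$fs) + 1L
  i1 <- round((t1 - trace$time[1]) * trace$fs) + 1L
  x <- trace$conductance[i0:i1]
  amp <- max(x - cummin(x))
  if (amp < floor) 0 else amp
}

#' Score all events of one phase on a trace
#'
#' Outcome-phase events use the fixed post-onset window; decision-phase
#' events use a per-trial window from `onset + window[1]` up to the response
#' time plus `window[1]` (mirroring the onset latency), following the
#' definition of the decision phase as presentation up to the entered
#' response. Decision windows are clipped to a minimum length of 1 s.
#'
#' @param trace a preprocessed `scr_trace` whose `events` table has `onset`,
#'   `kind` and `trial` columns.
#' @param phase `"outcome"` or `"decision"`.
#' @param window scoring window (seconds after onset) for the outcome phase;
#'   its first element is also the latency used for the decision phase.
#' @param floor amplitude floor in uS.
#' @return data.frame with `trial`, `onset` and `raw` (uS, 0 if floored).
#' @export
score_events <- function(trace, phase = c("outcome", "decision"),
                         window = c(0.5, 4.5), floor = 0.02) {
  phase <- match.arg(phase)
  ev <- trace$events
  if (phase == "outcome") {
    sel <- ev[ev$kind == "outcome", , drop = FALSE]
    raw <- vapply(sel$onset, function(o)
      score_event(trace, o, window, floor), numeric(1))
  } else {
    dec <- ev[ev$kind == "decision", , drop = FALSE]
    resp <- ev[ev$kind == "response", , drop = FALSE]
    sel <- dec[dec$trial %in% resp$trial, , drop = FALSE]
    resp_t <- resp$onset[match(sel$trial, resp$trial)]
    raw <- mapply(function(o, r) {
      w_end <- max(r - o, 1) + window[1]
      score_event(trace, o, c(window[1], w_end), floor)
    }, sel$onset, resp_t)
  }
  data.frame(trial = sel$trial, onset = sel$onset, raw = as.numeric(raw))
}

#' Square-root/maximum normalization of a subject's amplitudes
#'
#' Each raw amplitude is square-rooted (to reduce skewness) and divided by
#' the subject's maximum square-rooted amplitude, so the largest response
#' maps to exactly 1 and an all-zero subject maps to all zeros.
#'
#' @param amplitudes nonnegative raw amplitudes in uS (one per event).
#' @param trial optional trial indices carried into the result.
#' @return an object of class `scored_scr`: list with `events` (data.frame
#'   of `trial`, `raw`, `normalized`), `max_sqrt_amplitude`, and
#'   `response_fraction` (proportion of events with raw > 0).
#' @export
normalize_subject <- function(amplitudes, trial = seq_along(amplitudes)) {
  if (any(amplitudes < 0)) config_stop("amplitudes must be >= 0")
  s <- sqrt(amplitudes)
  mx <- max(s)
  normalized <- if (mx > 0) s / mx else rep(0, length(s))
  structure(list(events = data.frame(trial = trial, raw = amplitudes,
                                     normalized = normalized),
                 max_sqrt_amplitude = mx,
                 response_fraction = mean(amplitudes > 0)),
            class = "scored_scr")
}

#' Classify a subject as an SCR responder
#'
#' A subject is a responder iff their fraction of events with a nonzero
#' scored response strictly exceeds `min_fraction` (default 0.25); subjects
#' at or below the threshold are excluded from SCR analyses.
#'
#' @param scored a `scored_scr` from [normalize_subject()].
#' @param min_fraction responder threshold (default 0.25, strict inequality).
#' @return logical flag.
#' @export
classify_responder <- function(scored, min_fraction = 0.25) {
  stopifnot(inherits(scored, "scored_scr"))
  if (nrow(scored$events) < 1L) config_stop("no scored events")
  scored$response_fraction > min_fraction
}

#' End-to-end SCR scoring for one subject
#'
#' Preprocesses the trace, scores outcome- and decision-phase events, applies
#' square-root/maximum normalization per phase, and attaches responder flags.
#'
#' @param trace a raw `scr_trace`.
#' @param cutoff_hz,n_coefficients,window_samples preprocessing settings.
#' @param window,floor scoring settings (see [score_event()]).
#' @param min_fraction responder threshold.
#' @return list with `outcome` and `decision`, each a `scored_scr` with an
#'   added `responder` flag.
#' @export
score_subject <- function(trace, cutoff_hz = 25, n_coefficients = 16,
                          window_samples = 3L, window = c(0.5, 4.5),
                          floor = 0.02, min_fraction = 0.25) {
  pp <- preprocess_scr(trace, cutoff_hz, n_coefficients, window_samples)
  out <- list()
  for (phase in c("outcome", "decision")) {
    sc <- score_events(pp, phase, window, floor)
    scored <- normalize_subject(sc$raw, trial = sc$trial)
    scored$responder <- classify_responder(scored, min_fraction)
    out[[phase]] <- scored
  }
  out
}
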