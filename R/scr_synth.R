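## ---------------------------------------------------------------------------
## Event-locked skin-conductance synthesis: each phasic response is a
## difference-of-exponentials kernel scaled to unit peak, placed at the event
## onset plus a fixed latency, superposed on a slow tonic baseline with
## optional white measurement noise.
## ---------------------------------------------------------------------------

#' Canonical skin-conductance response kernel
#'
#' `h(t) = c * (exp(-t / tau_decay) - exp(-t / tau_rise))` for `t >= 0`,
#' scaled so its peak equals 1. With the defaults (rise 0.75 s, decay 2 s,
#' latency 1 s) the peak lands about 2.2 s after the event onset, inside the
#' standard 0.5-4.5 s scoring window.
#'
#' @param tau_rise,tau_decay time constants in seconds.
#' @param latency onset-to-rise latency in seconds.
#' @param fs sampling rate (samples/s).
#' @param duration kernel support in seconds.
#' @return a list with `values` (unit-peak samples, starting at the event
#'   onset), `fs`, and `latency`.
#' @export
scr_kernel <- function(tau_rise = 0.75, tau_decay = 2, latency = 1,
                       fs = 200, duration = 15) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0, latency >= 0)
  tt <- seq(0, duration, by = 1 / fs)
  h <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  h <- h / max(h)
  lat_pad <- rep(0, round(latency * fs))
  list(values = c(lat_pad, h), fs = fs, latency = latency)
}

#' Synthesize a conductance trace from explicit event amplitudes
#'
#' The workhorse behind [synthesize_scr_trace()], also used directly as a
#' scoring oracle: `trace = tonic baseline + slow sinusoidal drift +
#' sum(amplitude_i * kernel(t - onset_i)) + white noise`. Overlapping
#' responses are summed (superposition).
#'
#' @param events data.frame with columns `onset` (s), `amplitude` (uS), and
#'   optionally `kind` and `trial` (carried through as markers).
#' @param duration trace length in seconds (default: last onset + 15 s).
#' @param kernel kernel from [scr_kernel()].
#' @param fs sampling rate; must match the kernel's.
#' @param noise_sd white-noise SD in uS.
#' @param tonic_level constant baseline in uS.
#' @param drift_amplitude,drift_period slow sinusoidal drift (uS, s).
#' @param seed integer seed for the noise.
#' @return an object of class `scr_trace`: list with `time`, `conductance`,
#'   `events` (onset/kind/trial), and `fs`.
#' @export
synthesize_trace <- function(events, duration = NULL, kernel = scr_kernel(),
                             fs = 200, noise_sd = 0, tonic_level = 2,
                             drift_amplitude = 0, drift_period = 120,
                             seed = 1L) {
  stopifnot(is.data.frame(events), all(c("onset", "amplitude") %in% names(events)))
  if (abs(fs - kernel$fs) > 1e-9)
    config_stop("kernel sampling rate (%g) does not match fs (%g)", kernel$fs, fs)
  if (is.null(duration)) duration <- max(events$onset) + 15
  n <- ceiling(duration * fs) + 1L
  x <- rep(tonic_level, n)
  tt <- (seq_len(n) - 1L) / fs
  if (drift_amplitude > 0)
    x <- x + drift_amplitude * sin(2 * pi * tt / drift_period)
  kv <- kernel$values
  for (i in seq_len(nrow(events))) {
    a <- events$amplitude[i]
    if (is.na(a) || a <= 0) next
    i0 <- round(events$onset[i] * fs) + 1L
    idx <- i0:min(n, i0 + length(kv) - 1L)
    x[idx] <- x[idx] + a * kv[seq_along(idx)]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  ev <- events
  ev$amplitude <- NULL
  if (is.null(ev$kind)) ev$kind <- "event"
  if (is.null(ev$trial)) ev$trial <- seq_len(nrow(ev))
  ev <- ev[order(ev$onset), , drop = FALSE]
  structure(list(time = tt, conductance = x, events = ev, fs = fs),
            class = "scr_trace")
}

#' Synthesize a subject's skin-conductance trace from their trial history
#'
#' Decision- and outcome-locked responses are generated from the subject's
#' SCR parameters on the normalized amplitude scale and converted to uS by
#' inverting the square-root/maximum normalization: a normalized target `s`
#' becomes `max_amp * s^2` uS. Outcome-event targets are
#' `alpha0 + alpha_earnings * normalized earnings + noise`; decision-event
#' targets are `delta0 + delta_shift * normalized positive shift + noise`;
#' both are floored at 0 and each event is independently zeroed with
#' probability `nonresponse_prob`. Missed trials contribute a decision event
#' but no response or outcome event.
#'
#' @param records trial records with timing columns (see
#'   [trial_event_times()]).
#' @param set the subject's `choice_set`.
#' @param params the subject's `subject_params`.
#' @param norm the cohort `normalization_scheme`.
#' @param kernel response kernel from [scr_kernel()].
#' @param seed integer seed.
#' @param fs sampling rate (samples/s).
#' @return an `scr_trace` whose `events` table marks decision, response and
#'   outcome onsets per trial.
#' @export
synthesize_scr_trace <- function(records, set, params, norm,
                                 kernel = scr_kernel(), seed = 1L, fs = 200) {
  if (!all(c("t_decision", "t_response", "t_outcome") %in% names(records)))
    config_stop("records carry no event timing; call trial_event_times() first")
  scr <- params$scr
  n <- nrow(records)
  ms <- norm$money_scale; es <- norm$earnings_scale
  outcome_filled <- ifelse(records$missed | is.na(records$outcome), 0, records$outcome)
  earnings_n <- c(0, cumsum(outcome_filled))[seq_len(n)] / es
  pos_shift_n <- pmax(set$shift, 0) / ms

  set.seed(seed)
  amp_out_n <- pmax(0, scr$alpha0 + scr$alpha_earnings * earnings_n +
                      rnorm(n, 0, scr$amp_noise_sd))
  amp_dec_n <- pmax(0, scr$delta0 + scr$delta_shift * pos_shift_n +
                      rnorm(n, 0, scr$amp_noise_sd))
  amp_out_n[runif(n) < scr$nonresponse_prob] <- 0
  amp_dec_n[runif(n) < scr$nonresponse_prob] <- 0
  ## invert sqrt/max normalization: normalized s -> max_amp * s^2 uS
  amp_out <- scr$max_amp * amp_out_n^2
  amp_dec <- scr$max_amp * amp_dec_n^2
  amp_out[records$missed] <- 0

  keep_resp <- !records$missed
  events <- rbind(
    data.frame(onset = records$t_decision, amplitude = amp_dec,
               kind = "decision", trial = records$trial),
    data.frame(onset = records$t_response[keep_resp], amplitude = 0,
               kind = "response", trial = records$trial[keep_resp]),
    data.frame(onset = records$t_outcome, amplitude = amp_out,
               kind = "outcome", trial = records$trial))
  synthesize_trace(events,
                   duration = max(records$t_outcome) + 15,
                   kernel = kernel, fs = fs,
                   noise_sd = scr$trace_noise_sd,
                   tonic_level = scr$tonic_level,
                   drift_amplitude = scr$drift_amplitude,
                   drift_period = scr$drift_period,
                   seed = derive_seed(seed, "noise"))
}

#' @export
print.scr_trace <- function(x, ...) {
  cat(sprintf("SCR trace: %.1f s at %g samples/s, %d events\n",
              max(x$time), x$fs, nrow(x$events)))
  invisible(x)
}
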