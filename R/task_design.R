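## ---------------------------------------------------------------------------
## Structured gain-only choice sets: runs of shared expected value (EV level)
## separated by signed shifts on a $1.25 grid. Amounts are derived from the
## run's EV level with independent +/- noise per option, so the risky gain is
## roughly double the guaranteed alternative on every trial.
## ---------------------------------------------------------------------------

#' Expected value of the two options on a trial
#'
#' The risky option pays `risky_gain` with probability `p_win` and `risky_loss`
#' otherwise; the safe option pays `safe` with certainty.
#'
#' @param risky_gain,risky_loss,safe dollar amounts (vectorized).
#' @param p_win win probability of the gamble (default 0.5).
#' @return a data.frame with columns `ev_risky` and `ev_safe`.
#' @examples
#' option_ev(30, 0, 16)  # ev_risky 15, ev_safe 16
#' @export
option_ev <- function(risky_gain, risky_loss = 0, safe, p_win = 0.5) {
  data.frame(ev_risky = p_win * risky_gain + (1 - p_win) * risky_loss,
             ev_safe  = safe)
}

## count bounded integer compositions: N[m+1, j] = #ways to write m as an
## ordered sum of j parts each in [lo, hi]; memoized, since cohorts reuse
## the same (n, k, lo, hi) configuration for every subject
.composition_cache <- new.env(parent = emptyenv())

count_compositions <- function(n, k, lo, hi) {
  key <- paste(n, k, lo, hi, sep = "/")
  hit <- .composition_cache[[key]]
  if (!is.null(hit)) return(hit)
  counts <- matrix(0, nrow = n + 1L, ncol = k + 1L)
  counts[1L, 1L] <- 1
  for (j in seq_len(k)) {
    for (m in 0:n) {
      tot <- 0
      if (m >= lo)
        for (v in lo:min(hi, m)) tot <- tot + counts[m - v + 1L, j]
      counts[m + 1L, j + 1L] <- tot
    }
  }
  .composition_cache[[key]] <- counts
  counts
}

## draw one composition uniformly at random using the count table
sample_composition <- function(n, k, lo, hi, counts) {
  parts <- integer(k)
  m <- n
  for (j in k:1) {
    vals <- lo:min(hi, m)
    w <- counts[m - vals + 1L, j]
    v <- if (length(vals) == 1L) vals else vals[sample.int(length(vals), 1L, prob = w)]
    parts[k - j + 1L] <- v
    m <- m - v
  }
  parts
}

#' Sample the run-length structure of a choice set
#'
#' Draws the number of runs and their lengths uniformly over all ordered
#' integer compositions of `n_trials` whose part count lies in `n_runs_range`
#' and whose parts lie in `length_range`. Sampling is exact (a
#' dynamic-programming count table drives the draw), so every admissible
#' composition is equally likely and the result is deterministic given `seed`.
#'
#' @param n_trials total number of trials (default 240; a 171-trial variant is
#'   supported through this argument).
#' @param n_runs_range integer vector `c(min, max)` of admissible run counts.
#' @param length_range integer vector `c(min, max)` of admissible run lengths.
#' @param seed integer seed.
#' @return an object of class `run_plan`: a list with `run_lengths`,
#'   `n_trials`, and empty `ev_levels`/`shifts` slots to be filled by
#'   [assign_ev_levels()].
#' @export
make_run_structure <- function(n_trials = 240L,
                               n_runs_range = c(9L, 10L),
                               length_range = c(9L, 36L),
                               seed = 1L) {
  n_trials <- as.integer(n_trials)
  lo <- as.integer(length_range[1]); hi <- as.integer(length_range[2])
  kmin <- as.integer(n_runs_range[1]); kmax <- as.integer(n_runs_range[2])
  if (kmin < 1L || kmax < kmin)
    config_stop("n_runs_range must satisfy 1 <= min <= max (got [%d, %d])", kmin, kmax)
  if (lo < 1L || hi < lo)
    config_stop("length_range must satisfy 1 <= min <= max (got [%d, %d])", lo, hi)
  if (n_trials < kmin * lo)
    config_stop("infeasible: n_trials = %d < n_runs_min * length_min = %d",
                n_trials, kmin * lo)
  if (n_trials > kmax * hi)
    config_stop("infeasible: n_trials = %d > n_runs_max * length_max = %d",
                n_trials, kmax * hi)

  counts <- count_compositions(n_trials, kmax, lo, hi)
  ks <- kmin:kmax
  n_by_k <- vapply(ks, function(k) counts[n_trials + 1L, k + 1L], numeric(1))
  if (sum(n_by_k) == 0)
    config_stop("infeasible: no composition of %d trials into [%d, %d] runs of length [%d, %d]",
                n_trials, kmin, kmax, lo, hi)

  set.seed(seed)
  k <- if (length(ks) == 1L) ks else ks[sample.int(length(ks), 1L, prob = n_by_k)]
  lengths <- sample_composition(n_trials, k, lo, hi, counts)
  structure(list(run_lengths = lengths, ev_levels = NULL, shifts = NULL,
                 n_trials = n_trials),
            class = "run_plan")
}

#' Default grid of admissible shift magnitudes between runs
#'
#' Shift magnitudes run from $5 to $15 in $1.25 increments (9 magnitudes per
#' sign).
#' @return numeric vector of dollar magnitudes.
#' @export
default_shift_grid <- function() seq(5, 15, by = 1.25)

#' Assign EV levels and between-run shifts to a run plan
#'
#' The first run's EV level is drawn uniformly from the quarter-dollar grid
#' inside `level_bounds`; each later level equals the previous level plus a
#' signed shift drawn uniformly from the admissible elements of
#' `+/- shift_grid` (those keeping the level inside `level_bounds`). Keeping
#' levels on a quarter-dollar grid means $1.25-increment shifts never leave
#' the grid.
#'
#' @param plan a `run_plan` from [make_run_structure()].
#' @param shift_grid positive shift magnitudes (default [default_shift_grid()]).
#' @param level_bounds EV-level bounds, default `c(2.25, 33)` so realized safe
#'   amounts stay in `[$0.25, $35]` under +/- $2 noise.
#' @param seed integer seed.
#' @param max_redraw bounded re-draw budget if a trajectory dead-ends.
#' @return the `run_plan` with `ev_levels` (one per run) and `shifts`
#'   (one per run boundary) filled in.
#' @export
assign_ev_levels <- function(plan, shift_grid = default_shift_grid(),
                             level_bounds = c(2.25, 33), seed = 1L,
                             max_redraw = 25L) {
  stopifnot(inherits(plan, "run_plan"))
  if (length(shift_grid) == 0L || any(shift_grid <= 0))
    config_stop("shift_grid must be a nonempty set of positive magnitudes")
  k <- length(plan$run_lengths)
  level_grid <- seq(ceiling(level_bounds[1] * 4) / 4, floor(level_bounds[2] * 4) / 4,
                    by = 0.25)
  set.seed(seed)
  for (attempt in seq_len(max_redraw)) {
    levels <- numeric(k)
    levels[1] <- sample(level_grid, 1L)
    ok <- TRUE
    if (k > 1L) {
      for (j in 2:k) {
        cand <- c(levels[j - 1] + shift_grid, levels[j - 1] - shift_grid)
        cand <- cand[cand >= level_bounds[1] & cand <= level_bounds[2]]
        if (length(cand) == 0L) { ok <- FALSE; break }
        levels[j] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
    }
    if (ok) {
      plan$ev_levels <- levels
      plan$shifts <- if (k > 1L) diff(levels) else numeric(0)
      return(plan)
    }
  }
  config_stop("no admissible shift from some reachable level after %d re-draws; widen level_bounds or shrink shift_grid",
              max_redraw)
}

#' Realize per-trial option amounts from a run plan
#'
#' For each trial in run with EV level `L`, the safe amount is
#' `round(L + u1)` and the risky gain `round(2 * (L + u2))` with `u1`, `u2`
#' independent uniform draws on `[-noise_half_width, +noise_half_width]`,
#' rounded to whole cents. The risky loss is always $0 and the win probability
#' 0.5. Amounts falling outside `[$0.25, $35]` (safe) or `[$0.50, $70]`
#' (risky gain) are re-drawn; persistent violation indicates level bounds
#' incompatible with the noise width.
#'
#' @param plan a `run_plan` with EV levels assigned.
#' @param noise_half_width half-width of the option noise in dollars
#'   (default 2).
#' @param seed integer seed.
#' @return a `choice_set` data.frame with one row per trial and columns
#'   `trial`, `run_id`, `ev_level`, `safe`, `risky_gain`, `risky_loss`,
#'   `p_win`, `shift` (nonzero only on the first trial of runs 2..K).
#' @export
realize_trials <- function(plan, noise_half_width = 2, seed = 1L) {
  stopifnot(inherits(plan, "run_plan"))
  if (is.null(plan$ev_levels))
    config_stop("run plan has no EV levels; call assign_ev_levels() first")
  if (noise_half_width < 0)
    config_stop("noise_half_width must be >= 0 (got %g)", noise_half_width)
  k <- length(plan$run_lengths)
  run_id <- rep.int(seq_len(k), plan$run_lengths)
  L <- plan$ev_levels[run_id]
  n <- length(L)

  set.seed(seed)
  draw_amount <- function(base, mult, lo, hi) {
    out <- round_money(mult * (base + stats::runif(n, -noise_half_width, noise_half_width)))
    for (i in seq_len(50L)) {
      bad <- out < lo | out > hi
      if (!any(bad)) return(out)
      out[bad] <- round_money(mult * (base[bad] +
        stats::runif(sum(bad), -noise_half_width, noise_half_width)))
    }
    config_stop("amounts persistently outside [%g, %g]; level bounds and noise width are inconsistent", lo, hi)
  }
  safe <- draw_amount(L, 1, 0.25, 35)
  risky_gain <- draw_amount(L, 2, 0.50, 70)

  shift <- numeric(n)
  if (k > 1L) {
    first_of_run <- match(2:k, run_id)
    shift[first_of_run] <- plan$shifts
  }
  out <- data.frame(trial = seq_len(n), run_id = run_id, ev_level = L,
                    safe = safe, risky_gain = risky_gain, risky_loss = 0,
                    p_win = 0.5, shift = shift)
  class(out) <- c("choice_set", "data.frame")
  out
}

#' Generate a complete structured choice set
#'
#' Convenience wrapper chaining [make_run_structure()], [assign_ev_levels()]
#' and [realize_trials()], with per-stage seeds derived from `seed` via
#' [derive_seed()].
#'
#' @inheritParams make_run_structure
#' @inheritParams assign_ev_levels
#' @inheritParams realize_trials
#' @return a `choice_set` data.frame; see [realize_trials()].
#' @export
make_choice_set <- function(n_trials = 240L, n_runs_range = c(9L, 10L),
                            length_range = c(9L, 36L),
                            shift_grid = default_shift_grid(),
                            level_bounds = c(2.25, 33),
                            noise_half_width = 2, seed = 1L) {
  plan <- make_run_structure(n_trials, n_runs_range, length_range,
                             seed = derive_seed(seed, "runs"))
  plan <- assign_ev_levels(plan, shift_grid, level_bounds,
                           seed = derive_seed(seed, "levels"))
  realize_trials(plan, noise_half_width, seed = derive_seed(seed, "amounts"))
}

#' Validate a choice set against its structural invariants
#'
#' Checks trial counts, run-length bounds, amount ranges, the shift grid, and
#' the consistency of shifts with EV-level differences. Used by tests and by
#' [run_pipeline()] as a schema check.
#'
#' @param set a `choice_set`.
#' @param n_runs_range,length_range,shift_grid,noise_half_width the
#'   constraints the set was generated under.
#' @return `TRUE` invisibly, or an error naming the violated invariant.
#' @export
validate_choice_set <- function(set, n_runs_range = c(9L, 10L),
                                length_range = c(9L, 36L),
                                shift_grid = default_shift_grid(),
                                noise_half_width = 2) {
  rl <- rle(set$run_id)$lengths
  if (length(rl) < n_runs_range[1] || length(rl) > n_runs_range[2])
    config_stop("run count %d outside [%d, %d]", length(rl),
                n_runs_range[1], n_runs_range[2])
  if (any(rl < length_range[1] | rl > length_range[2]))
    config_stop("run length outside [%d, %d]", length_range[1], length_range[2])
  if (any(set$safe < 0.25 | set$safe > 35)) config_stop("safe amount outside [$0.25, $35]")
  if (any(set$risky_gain < 0.50 | set$risky_gain > 70)) config_stop("risky gain outside [$0.50, $70]")
  if (any(set$risky_loss != 0)) config_stop("risky loss must be $0")
  if (any(set$p_win != 0.5)) config_stop("win probability must be 0.5")
  if (any(abs(set$safe - set$ev_level) > noise_half_width + 0.005))
    config_stop("safe amount deviates from EV level by more than the noise half-width")
  if (any(abs(set$risky_gain / 2 - set$ev_level) > noise_half_width + 0.005))
    config_stop("risky gain / 2 deviates from EV level by more than the noise half-width")
  nz <- set$shift[set$shift != 0]
  if (length(nz) && !all(round(abs(nz) / 1.25, 8) == round(abs(nz) / 1.25)))
    config_stop("shift off the $1.25 grid")
  if (length(nz) && (any(abs(nz) < min(shift_grid) - 1e-9) ||
                     any(abs(nz) > max(shift_grid) + 1e-9)))
    config_stop("shift magnitude outside the configured grid")
  lev_diff <- diff(set$ev_level)
  run_change <- diff(set$run_id) != 0
  if (any(abs(lev_diff[run_change] - set$shift[-1][run_change]) > 1e-9))
    config_stop("shift does not equal the EV-level difference at a run boundary")
  if (any(lev_diff[!run_change] != 0))
    config_stop("EV level changes inside a run")
  invisible(TRUE)
}
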