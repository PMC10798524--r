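## ---------------------------------------------------------------------------
## File formats and the pipeline driver. All tables are UTF-8 CSV with a
## header row; money in decimal dollars with two fraction digits; times in
## seconds; missing values as empty fields.
## ---------------------------------------------------------------------------

#' Write a cohort's trial table to CSV
#'
#' One row per trial: `subject`, `trial`, `run_id`, `ev_level`, `safe`,
#' `risky_gain`, `risky_loss`, `p_win`, `shift`, `choice`, `rt`, `outcome`,
#' `missed`.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_trials_csv <- function(cohort, file) {
  rows <- lapply(seq_along(cohort$subjects), function(s) {
    subj <- cohort$subjects[[s]]
    cbind(subject = s,
          subj$set[, c("trial", "run_id", "ev_level", "safe", "risky_gain",
                       "risky_loss", "p_win", "shift")],
          subj$records[, c("choice", "rt", "outcome", "missed")])
  })
  tab <- do.call(rbind, rows)
  for (col in c("ev_level", "safe", "risky_gain", "risky_loss", "shift", "outcome"))
    tab[[col]] <- sprintf("%.2f", tab[[col]])
  tab$outcome[tab$missed] <- ""
  write.csv(tab, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read a trial table written by [write_trials_csv()]
#'
#' @param file CSV path.
#' @return list with `sets` (per-subject `choice_set`s) and `records`
#'   (per-subject trial records), in subject order.
#' @export
read_trials_csv <- function(file) {
  tab <- read.csv(file, na.strings = "")
  needed <- c("subject", "trial", "run_id", "ev_level", "safe", "risky_gain",
              "risky_loss", "p_win", "shift", "choice", "rt", "outcome", "missed")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    config_stop("trial table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  subjects <- sort(unique(tab$subject))
  sets <- records <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    d <- tab[tab$subject == subjects[i], , drop = FALSE]
    d <- d[order(d$trial), , drop = FALSE]
    set <- d[, c("trial", "run_id", "ev_level", "safe", "risky_gain",
                 "risky_loss", "p_win", "shift")]
    rownames(set) <- NULL
    class(set) <- c("choice_set", "data.frame")
    rec <- d[, c("trial", "choice", "outcome", "rt", "missed")]
    rec$missed <- as.logical(rec$missed)
    rownames(rec) <- NULL
    sets[[i]] <- set
    records[[i]] <- rec
  }
  list(sets = sets, records = records, subjects = subjects)
}

#' Write a skin-conductance trace (and its event table) to CSV
#'
#' @param trace an `scr_trace`.
#' @param trace_file CSV path for the sampled series (`time`, `conductance`).
#' @param events_file CSV path for the event table (`onset`, `kind`, `trial`).
#' @return `trace_file`, invisibly.
#' @export
write_trace_csv <- function(trace, trace_file, events_file) {
  write.csv(data.frame(time = trace$time, conductance = trace$conductance),
            trace_file, row.names = FALSE, quote = FALSE)
  write.csv(trace$events[, c("onset", "kind", "trial")], events_file,
            row.names = FALSE, quote = FALSE)
  invisible(trace_file)
}

#' Read a trace written by [write_trace_csv()]
#' @param trace_file,events_file CSV paths.
#' @param fs sampling rate; default inferred from the time column.
#' @return an `scr_trace`.
#' @export
read_trace_csv <- function(trace_file, events_file, fs = NULL) {
  tr <- read.csv(trace_file)
  ev <- read.csv(events_file)
  if (!all(c("time", "conductance") %in% names(tr)))
    config_stop("trace CSV must have 'time' and 'conductance' columns")
  if (is.null(fs)) fs <- round(1 / stats::median(diff(tr$time)))
  structure(list(time = tr$time, conductance = tr$conductance,
                 events = ev, fs = fs),
            class = "scr_trace")
}

#' Write a feature table to CSV
#' @param features a `feature_table`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(features, file) {
  write.csv(features, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read a feature table written by [write_features_csv()]
#' @param file CSV path.
#' @return a `feature_table`.
#' @export
read_features_csv <- function(file) {
  tab <- read.csv(file, na.strings = "")
  if (!is.null(tab$subject)) tab$subject <- factor(tab$subject)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Write suite results to CSV
#' @param report a `suite_report` (or list of them, concatenated).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_fits_csv <- function(report, file) {
  if (inherits(report, "suite_report")) report <- list(report)
  tab <- do.call(rbind, lapply(report, suite_table))
  write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: `generate` (structured choice sets and simulated
#' choices), `score` (synthesized traces scored to per-trial amplitudes with
#' responder flags), `fit` (the behavioral and, when scored data exist, SCR
#' model suites), `power` (simulation-based power for the previous-outcome
#' term), and `report` (results tables on disk). Stage artifacts are written
#' as CSV under `out_dir` together with a `manifest.csv`; rerunning with the
#' same config and seed reproduces the CSVs byte-for-byte.
#'
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("generate", "score", "fit", "power", "report")`.
#' @param n_subjects,n_trials cohort dimensions.
#' @param population generative population.
#' @param seed master seed; all stage streams derive from it.
#' @param power_sims replicates for the power stage.
#' @param ... further arguments to [simulate_cohort()] (e.g. `n_runs_range`).
#' @return invisibly, a list with the in-memory artifacts of the requested
#'   stages.
#' @export
run_pipeline <- function(out_dir, stages = c("generate", "fit", "report"),
                         n_subjects = 60L, n_trials = 240L,
                         population = default_population(), seed = 1L,
                         power_sims = 100L, ...) {
  stages <- match.arg(stages, c("generate", "score", "fit", "power", "report"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  manifest <- data.frame(stage = character(0), artifact = character(0))
  note <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, artifact = basename(file)))
    file
  }

  cohort <- simulate_cohort(n_subjects, n_trials, population, seed = seed,
                            timing = "score" %in% stages, ...)
  art$cohort <- cohort
  if ("generate" %in% stages)
    write_trials_csv(cohort, note("generate", file.path(out_dir, "trials.csv")))

  if ("score" %in% stages) {
    scored_rows <- lapply(seq_along(cohort$subjects), function(s) {
      subj <- cohort$subjects[[s]]
      trace <- synthesize_scr_trace(subj$records, subj$set, subj$params,
                                    cohort$norm, seed = derive_seed(seed, "scr", s))
      sc <- score_subject(trace)
      do.call(rbind, lapply(c("outcome", "decision"), function(ph)
        data.frame(subject = s, phase = ph, sc[[ph]]$events,
                   responder = sc[[ph]]$responder)))
    })
    scored <- do.call(rbind, scored_rows)
    art$scored <- scored
    write.csv(scored, note("score", file.path(out_dir, "scored_scr.csv")),
              row.names = FALSE, quote = FALSE)
  }

  if (any(c("fit", "report", "power") %in% stages)) {
    features <- cohort_features(cohort)
    art$features <- features
    write_features_csv(features, note("fit", file.path(out_dir, "features.csv")))
  }

  if ("fit" %in% stages) {
    behavior <- run_behavior_suite(features)
    art$behavior <- behavior
    reports <- list(behavior)
    if (!is.null(art$scored)) {
      keep <- function(ph) {
        d <- art$scored[art$scored$phase == ph & art$scored$responder, ]
        data.frame(subject = d$subject, trial = d$trial, normalized = d$normalized)
      }
      feat_scr <- attach_scr(behavior$features, keep("outcome"), keep("decision"))
      art$scr_suite <- run_scr_suite(feat_scr)
      reports <- c(reports, list(art$scr_suite))
      ## mean outcome-locked SCR by outcome category (win / loss / safe)
      oc <- keep("outcome")
      cat_rows <- do.call(rbind, lapply(unique(oc$subject), function(s) {
        rec <- cohort$subjects[[s]]$records
        idx <- match(oc$trial[oc$subject == s], rec$trial)
        data.frame(subject = s,
                   category = ifelse(rec$choice[idx] == 0, "safe",
                                     ifelse(rec$outcome[idx] > 0, "win", "loss")),
                   value = oc$normalized[oc$subject == s])
      }))
      cat_rows <- cat_rows[!is.na(cat_rows$category), , drop = FALSE]
      art$paired_tests <- tryCatch(paired_category_tests(cat_rows)$tests,
                                   error = function(e) {
                                     message("paired category tests skipped: ",
                                             conditionMessage(e))
                                     NULL
                                   })
      if (!is.null(art$paired_tests))
        write.csv(art$paired_tests,
                  note("fit", file.path(out_dir, "paired_tests.csv")),
                  row.names = FALSE, quote = FALSE)
    }
    write_fits_csv(reports, note("fit", file.path(out_dir, "fits.csv")))
  }

  if ("power" %in% stages) {
    design <- lapply(cohort$subjects, `[[`, "set")
    pw <- simulate_power(population, design, n_sims = power_sims,
                         seed = derive_seed(seed, "power"))
    art$power <- pw
    write.csv(data.frame(term = pw$term, power = pw$power,
                         ci_lo = pw$ci[1], ci_hi = pw$ci[2],
                         n_sims = pw$n_sims, n_rejections = pw$n_rejections,
                         alpha = pw$alpha),
              note("power", file.path(out_dir, "power.csv")),
              row.names = FALSE, quote = FALSE)
  }

  if ("report" %in% stages && !is.null(art$behavior)) {
    txt <- file.path(out_dir, "report.txt")
    con <- file(txt, "w")
    for (f in art$behavior$fits) {
      writeLines(format(f$spec, term_names = suite_term_names), con)
      writeLines(utils::capture.output(print(f)), con)
      writeLines("", con)
    }
    close(con)
    note("report", txt)
  }

  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(art)
}
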