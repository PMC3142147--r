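#' In-silico comparison of REPT, MOBS and MOCS
#'
#' Replays the validation logic of a staircase-comparison study on a panel
#' of simulated observers: for each observer, a fixed number of REPT and
#' MOBS staircases (default 4 of each) and one MOCS session are run with
#' derived seeds, and per-observer accuracy (absolute difference of the
#' mean-of-runs threshold from the observer's analytic 60% point, with the
#' MOCS estimate also reported as proxy truth), reliability (SD over the
#' runs) and trial counts are tabulated. Durations are reported as trial
#' counts: REPT always takes its fixed 30 trials while MOBS run lengths
#' vary.
#'
#' @param panel A list of [sim_observer()]s, e.g. from [observer_panel()].
#' @param n_runs Staircase runs per procedure per observer (default 4).
#' @param config A [psi_config()] for the REPT runs.
#' @param mocs_reps,mocs_spacing MOCS presentations per level and level
#'   spacing; the MOCS design is centered on the mean REPT estimate,
#'   mirroring the practice of picking MOCS levels from pilot staircases.
#' @param seed Integer seed; every staircase and MOCS session derives its
#'   own response stream from it.
#' @return A `comparison_report`: `$observers` is a per-observer tibble,
#'   `$summary` a one-row tibble of panel means/SDs; observers whose
#'   staircases aborted are flagged in `$excluded`.
#' @examples
#' \donttest{
#' panel <- observer_panel(3, seed = 42)
#' rep <- run_comparison(panel, seed = 1)
#' rep$summary
#' }
#' @export
run_comparison <- function(panel, n_runs = 4L, config = psi_config(),
                           mocs_reps = 25L, mocs_spacing = 5, seed = 1L) {
  if (length(panel) == 0L) {
    abort("`panel` must be non-empty.", class = "phosphene_config_error")
  }
  seeds <- local_rng(seed, sample.int(.Machine$integer.max, length(panel)))
  rows <- vector("list", length(panel))
  excluded <- character(0)
  for (i in seq_along(panel)) {
    obs <- panel[[i]]
    true60 <- threshold_at_accuracy(0.60, obs$params)
    row <- tryCatch({
      run_seeds <- local_rng(seeds[i], sample.int(.Machine$integer.max, 2L * n_runs + 1L))
      fresh <- function(s) sim_observer(obs$params, seed = s, mode = obs$mode)
      rept_runs <- lapply(seq_len(n_runs), function(k) {
        run_rept(fresh(run_seeds[k]), config)
      })
      mobs_runs <- lapply(seq_len(n_runs), function(k) {
        run_mobs(fresh(run_seeds[n_runs + k]))
      })
      rept_thr <- vapply(rept_runs, `[[`, numeric(1), "threshold")
      mobs_thr <- vapply(mobs_runs, `[[`, numeric(1), "threshold")
      pilot <- min(max(mean(rept_thr), 1), 100)
      design <- design_mocs(pilot, reps_per_level = mocs_reps,
                            spacing = mocs_spacing, seed = run_seeds[2L * n_runs + 1L])
      mocs_data <- run_mocs(fresh(run_seeds[2L * n_runs + 1L]), design)
      mocs_fit <- fit_weibull_ml(mocs_data, guess = obs$params$guess,
                                 lapse = obs$params$lapse)
      tibble(
        observer = i,
        true_alpha = obs$params$alpha,
        true_beta = obs$params$beta,
        true_threshold_60 = true60,
        rept_mean = mean(rept_thr),
        mobs_mean = mean(mobs_thr),
        mocs_threshold_60 = mocs_fit$threshold_60,
        mocs_threshold_50 = mocs_fit$threshold_50,
        rept_abs_err = abs(mean(rept_thr) - true60),
        mobs_abs_err = abs(mean(mobs_thr) - true60),
        # MOCS-as-proxy-truth columns: REPT reads out at 60% accuracy, MOBS
        # converges on the 50% point, so each is matched to its own level
        rept_abs_err_mocs = abs(mean(rept_thr) - mocs_fit$threshold_60),
        mobs_abs_err_mocs = abs(mean(mobs_thr) - mocs_fit$threshold_50),
        rept_sd = sd(rept_thr),
        mobs_sd = sd(mobs_thr),
        rept_trials_mean = mean(vapply(rept_runs, `[[`, numeric(1), "n_trials")),
        mobs_trials_mean = mean(vapply(mobs_runs, `[[`, numeric(1), "n_trials")),
        mobs_trials_sd = sd(vapply(mobs_runs, `[[`, numeric(1), "n_trials"))
      )
    }, error = function(e) {
      excluded <<- c(excluded, sprintf("observer %d: %s", i, conditionMessage(e)))
      NULL
    })
    rows[[i]] <- row
  }
  observers <- dplyr::bind_rows(rows)
  if (nrow(observers) == 0L) {
    abort("Every observer was excluded.", class = "phosphene_session_error")
  }
  summary <- tibble(
    n_observers = nrow(observers),
    rept_abs_err_mean = mean(observers$rept_abs_err),
    mobs_abs_err_mean = mean(observers$mobs_abs_err),
    rept_sd_mean = mean(observers$rept_sd),
    mobs_sd_mean = mean(observers$mobs_sd),
    rept_trials_mean = mean(observers$rept_trials_mean),
    mobs_trials_mean = mean(observers$mobs_trials_mean)
  )
  structure(
    list(observers = observers, summary = summary, excluded = excluded,
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    paste0("Staircase comparison over %d observers (%d runs/procedure):\n",
           "  mean |error| vs true 60%% point: REPT %.2f, MOBS %.2f\n",
           "  mean run-to-run SD:             REPT %.2f, MOBS %.2f\n",
           "  mean trials:                    REPT %.1f, MOBS %.1f\n"),
    x$summary$n_observers, x$n_runs,
    x$summary$rept_abs_err_mean, x$summary$mobs_abs_err_mean,
    x$summary$rept_sd_mean, x$summary$mobs_sd_mean,
    x$summary$rept_trials_mean, x$summary$mobs_trials_mean
  ))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Per-observer table as CSV, panel summary as JSON.
#'
#' @param report A [run_comparison()] result.
#' @param path Base path (without extension).
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  write.csv(report$observers, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(as.list(report$summary), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
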