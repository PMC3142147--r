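#' Tidy a REPT staircase result
#'
#' @param x A `rept_result`.
#' @param ... Unused.
#' @return The trial-by-trial history: `trial`, `intensity`, `response`,
#'   `entropy` (posterior entropy in nats after the update).
#' @export
tidy.rept_result <- function(x, ...) x$history

#' @rdname tidy.rept_result
#' @return For `glance`: a one-row tibble with the threshold (at the
#'   configured accuracy), marginal posterior-mean `alpha` and `beta`, the
#'   post-hoc 50% threshold, trial count and final posterior entropy.
#' @export
glance.rept_result <- function(x, ...) {
  tibble(threshold = x$threshold,
         threshold_accuracy = x$config$threshold_accuracy,
         alpha_estimate = x$alpha_estimate,
         beta_estimate = x$beta_estimate,
         threshold_50 = x$threshold_50,
         n_trials = x$n_trials,
         final_entropy = tail(x$history$entropy, 1))
}

#' Tidy a MOBS staircase result
#'
#' @param x A `mobs_result`.
#' @param ... Unused.
#' @return The trial history: `trial`, `intensity`, `response`, `reversal`.
#' @export
tidy.mobs_result <- function(x, ...) x$history

#' @rdname tidy.mobs_result
#' @export
glance.mobs_result <- function(x, ...) {
  tibble(threshold = x$threshold, n_trials = x$n_trials,
         reversals = x$reversals)
}

#' Tidy a MOCS maximum-likelihood fit
#'
#' @param x A `mocs_fit`.
#' @param ... Unused.
#' @return A parameter table (`term`, `estimate`, `fixed`); bootstrap
#'   standard errors for the thresholds appear in [glance.mocs_fit()] once
#'   [bootstrap_threshold_se()] has been run.
#' @export
tidy.mocs_fit <- function(x, ...) {
  tibble(
    term = c("alpha", "beta", "guess", "lapse"),
    estimate = c(x$params$alpha, x$params$beta, x$params$guess, x$params$lapse),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' @rdname tidy.mocs_fit
#' @export
glance.mocs_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    threshold_60 = x$threshold_60,
    threshold_50 = x$threshold_50,
    threshold_60_se = x$bootstrap_se$threshold_60 %||% NA_real_,
    threshold_50_se = x$bootstrap_se$threshold_50 %||% NA_real_,
    n_levels = nrow(x$data),
    n_trials = sum(x$data$presented)
  )
}

#' Tidy a procedure-comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return Per-observer rows (`tidy`) or the one-row panel summary
#'   (`glance`).
#' @export
tidy.comparison_report <- function(x, ...) x$observers

#' @rdname tidy.comparison_report
#' @export
glance.comparison_report <- function(x, ...) x$summary
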