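#' Plot a REPT staircase run
#'
#' Delivered intensity by trial, colored by response, with the posterior
#' entropy trace underneath the reported threshold line.
#'
#' @param object A `rept_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rept_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$trial, y = .data$intensity)) +
    ggplot2::geom_step(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$response,
                                                     levels = c(0, 1),
                                                     labels = c("not seen", "seen")))) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Trial", y = "Intensity (% max output)",
                  colour = "Response",
                  title = sprintf("REPT staircase: threshold %.1f", object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a MOBS staircase run
#'
#' @param object A `mobs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mobs_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$trial, y = .data$intensity)) +
    ggplot2::geom_step(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$reversal,
                                     colour = factor(.data$response,
                                                     levels = c(0, 1),
                                                     labels = c("not seen", "seen")))) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Trial", y = "Intensity (% max output)",
                  colour = "Response", shape = "Reversal",
                  title = sprintf("MOBS staircase: threshold %.0f in %d trials",
                                  object$threshold, object$n_trials)) +
    ggplot2::theme_minimal()
}

#' Plot a MOCS dataset with its fitted psychometric function
#'
#' Observed per-level detection proportions (point size by presentations)
#' with the fitted lapse-corrected Weibull and the 60%/50% threshold
#' read-outs.
#'
#' @param object A `mocs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mocs_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, proportion = .data$seen / .data$presented)
  grid <- tibble(
    level = seq(min(d$level) * 0.8, max(d$level) * 1.1, length.out = 200)
  )
  grid$fitted <- detect_prob(grid$level, object$params)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$proportion)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$presented), alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$threshold_50, object$threshold_60),
                        linetype = c("dotted", "dashed")) +
    ggplot2::scale_size_continuous(range = c(1.5, 3.5)) +
    ggplot2::labs(x = "Intensity (% max output)", y = "Proportion seen",
                  size = "Trials",
                  title = sprintf("MOCS Weibull fit: 60%% threshold %.1f, 50%% threshold %.1f",
                                  object$threshold_60, object$threshold_50)) +
    ggplot2::theme_minimal()
}

#' Plot a procedure-comparison report
#'
#' Accuracy panel: per-observer |REPT - truth| against |MOBS - truth|;
#' points below the identity line favour REPT. Reliability panel: the
#' run-to-run SDs likewise.
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @export
autoplot.comparison_report <- function(object, ...) {
  obs <- object$observers
  d <- dplyr::bind_rows(
    tibble(metric = "absolute error", rept = obs$rept_abs_err, mobs = obs$mobs_abs_err),
    tibble(metric = "run-to-run SD", rept = obs$rept_sd, mobs = obs$mobs_sd)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rept, y = .data$mobs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "REPT", y = "MOBS",
                  title = "REPT vs MOBS: accuracy and reliability per observer") +
    ggplot2::theme_minimal()
}
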