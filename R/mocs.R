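#' Design a method-of-constant-stimuli (MOCS) session
#'
#' Picks a fixed set of integer intensity levels centered on a pilot
#' threshold estimate (typically a staircase result), spaced so that the
#' levels span near-0% to near-100% expected detection, each to be
#' presented a fixed number of times in seeded random order. A window that
#' overhangs the 1--100% stimulator range is slid back inside it so all
#' levels stay distinct; the design is refused only if fewer than six
#' distinct levels fit.
#'
#' @param pilot_threshold Pilot threshold estimate in `[1, 100]`.
#' @param n_levels Number of levels (default 7).
#' @param spacing Level spacing in percent of maximum output (default 5).
#' @param reps_per_level Presentations per level, conventionally 20--30
#'   (default 25).
#' @param seed Integer seed for the presentation order.
#' @return A `mocs_design` with `levels`, `reps_per_level` and the full
#'   seeded `presentation_order`.
#' @examples
#' design_mocs(60)$levels
#' @export
design_mocs <- function(pilot_threshold, n_levels = 7L, spacing = 5,
                        reps_per_level = 25L, seed = 1L) {
  if (!is.numeric(pilot_threshold) || pilot_threshold < 1 || pilot_threshold > 100) {
    abort("`pilot_threshold` must lie in [1, 100].", class = "phosphene_config_error")
  }
  if (reps_per_level < 1) {
    abort("`reps_per_level` must be positive.", class = "phosphene_config_error")
  }
  offsets <- (seq_len(n_levels) - (n_levels + 1) / 2) * spacing
  levels <- round_half_up(pilot_threshold + offsets)
  # slide a window that overhangs the stimulator range back inside it, so a
  # near-ceiling pilot keeps its full set of distinct levels
  if (max(levels) > 100) levels <- levels - (max(levels) - 100)
  if (min(levels) < 1) levels <- levels + (1 - min(levels))
  levels <- sort(unique(pmin(pmax(levels, 1), 100)))
  if (length(levels) < 6L) {
    abort("Fewer than 6 distinct levels after clipping to [1, 100].",
          class = "phosphene_design_error")
  }
  order <- local_rng(seed, sample(rep(levels, each = reps_per_level)))
  structure(
    list(levels = levels, reps_per_level = as.integer(reps_per_level),
         presentation_order = order, seed = as.integer(seed)),
    class = "mocs_design"
  )
}

#' @export
print.mocs_design <- function(x, ...) {
  cat(sprintf("MOCS design: levels {%s}, %d reps each (%d trials)\n",
              paste(x$levels, collapse = ", "), x$reps_per_level,
              length(x$presentation_order)))
  invisible(x)
}

#' Run a MOCS session against a responder
#'
#' Presents every trial of the design in its seeded order and tallies
#' per-level presentation and "seen" counts.
#'
#' @param responder A function of intensity returning 0/1, or a
#'   [sim_observer()].
#' @param design A [design_mocs()] object.
#' @return A tibble with columns `level`, `presented`, `seen` — the MOCS
#'   dataset consumed by [fit_weibull_ml()].
#' @export
run_mocs <- function(responder, design) {
  stopifnot(inherits(design, "mocs_design"))
  if (inherits(responder, "sim_observer")) responder <- as_responder(responder)
  responses <- vapply(design$presentation_order, responder, numeric(1))
  tibble(level = design$presentation_order, seen = as.integer(responses)) |>
    dplyr::group_by(level) |>
    dplyr::summarise(presented = dplyr::n(), seen = sum(seen), .groups = "drop") |>
    dplyr::arrange(level)
}

# Binomial negative log-likelihood of (alpha, beta) on a MOCS dataset,
# parameterized on the log scale for unconstrained optimization.
mocs_negloglik <- function(theta, data, guess, lapse) {
  alpha <- exp(theta[1]); beta <- exp(theta[2])
  p <- guess + (1 - guess - lapse) * (1 - exp(-(data$level / alpha)^beta))
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -sum(data$seen * log(p) + (data$presented - data$seen) * log(1 - p))
}

#' Maximum-likelihood Weibull fit to MOCS data
#'
#' Fits the position and slope of the lapse-corrected Weibull to per-level
#' binomial counts by maximizing the binomial log-likelihood with a
#' derivative-free simplex search from several starting points spread over
#' the sampled intensity range (the likelihood surface has flat regions
#' when the data pin the curve poorly). The guess and lapse rates are held
#' fixed (defaults 0 and 0.04, matching the staircase convention).
#' Thresholds are read off the fitted curve at 60% and 50% accuracy.
#'
#' @param data A data frame with columns `level`, `presented`, `seen`.
#' @param guess,lapse Fixed asymptotes of the fitted curve.
#' @param n_starts Number of multistart positions (default 5).
#' @return A `mocs_fit` with the fitted [weibull_params()], `log_likelihood`,
#'   `threshold_60`, `threshold_50`, the data, and (after
#'   [bootstrap_threshold_se()]) bootstrap standard errors.
#' @export
fit_weibull_ml <- function(data, guess = 0, lapse = 0.04, n_starts = 5L) {
  data <- as_tibble(data)
  if (!all(c("level", "presented", "seen") %in% names(data))) {
    abort("`data` needs columns level, presented, seen.",
          class = "phosphene_config_error")
  }
  data <- data[data$presented > 0, ]
  if (nrow(data) < 2L) {
    abort("Need at least 2 levels with presentations.",
          class = "phosphene_config_error")
  }
  if (any(data$seen < 0) || any(data$seen > data$presented)) {
    abort("`seen` must lie in [0, presented].", class = "phosphene_config_error")
  }
  if (sum(data$seen) == 0 || sum(data$seen) == sum(data$presented)) {
    abort("All responses identical across levels: threshold not identifiable within the sampled range.",
          class = "phosphene_fit_error")
  }
  starts <- expand.grid(
    alpha = exp(seq(log(min(data$level)), log(max(data$level)),
                    length.out = max(2L, ceiling(n_starts / 2)))),
    beta = c(2, 8)
  )
  starts <- starts[seq_len(min(nrow(starts), max(n_starts, 2L))), , drop = FALSE]
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(log(c(starts$alpha[i], starts$beta[i])), mocs_negloglik,
            data = data, guess = guess, lapse = lapse,
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0L) {
    abort("All optimization starts failed.", class = "phosphene_fit_error")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  params <- weibull_params(exp(best$par[1]), exp(best$par[2]),
                           guess = guess, lapse = lapse)
  structure(
    list(params = params,
         log_likelihood = -best$value,
         threshold_60 = threshold_at_accuracy(0.60, params),
         threshold_50 = threshold_at_accuracy(0.50, params),
         bootstrap_se = NULL,
         data = data),
    class = "mocs_fit"
  )
}

#' @export
print.mocs_fit <- function(x, ...) {
  cat(sprintf(
    paste0("MOCS maximum-likelihood Weibull fit\n",
           "  alpha = %.2f, beta = %.2f (guess %.2g, lapse %.2g fixed)\n",
           "  log-likelihood = %.2f\n",
           "  threshold at 60%%: %.2f   at 50%%: %.2f\n"),
    x$params$alpha, x$params$beta, x$params$guess, x$params$lapse,
    x$log_likelihood, x$threshold_60, x$threshold_50
  ))
  if (!is.null(x$bootstrap_se)) {
    cat(sprintf("  bootstrap SE: %.2f (60%%), %.2f (50%%) [%d resamples]\n",
                x$bootstrap_se$threshold_60, x$bootstrap_se$threshold_50,
                x$bootstrap_se$n_boot))
  }
  invisible(x)
}

#' Parametric-bootstrap standard errors for MOCS thresholds
#'
#' Simulates datasets from the fitted curve at the observed levels and
#' counts, refits each, and returns the standard deviation of the refitted
#' 60% and 50% thresholds.
#'
#' @param fit A [fit_weibull_ml()] result.
#' @param n_boot Number of bootstrap resamples (default 400; >= 1 accepted
#'   to make single-resample reproducibility testable, >= 100 recommended).
#' @param seed Integer seed for the resamples.
#' @param n_starts Multistart count for the refits (default 2, cheaper than
#'   the primary fit).
#' @return The `mocs_fit` with its `bootstrap_se` element filled in:
#'   `threshold_60`, `threshold_50`, `n_boot`, `n_failed`.
#' @export
bootstrap_threshold_se <- function(fit, n_boot = 400L, seed = 1L, n_starts = 2L) {
  stopifnot(inherits(fit, "mocs_fit"))
  if (n_boot < 1L) {
    abort("`n_boot` must be >= 1.", class = "phosphene_config_error")
  }
  p_fit <- detect_prob(fit$data$level, fit$params)
  draws <- local_rng(seed, {
    matrix(rbinom(n_boot * nrow(fit$data), fit$data$presented, p_fit),
           nrow = nrow(fit$data))
  })
  refits <- lapply(seq_len(n_boot), function(b) {
    d <- fit$data
    d$seen <- draws[, b]
    tryCatch(
      fit_weibull_ml(d, guess = fit$params$guess, lapse = fit$params$lapse,
                     n_starts = n_starts),
      error = function(e) NULL
    )
  })
  ok <- !vapply(refits, is.null, logical(1))
  if (mean(!ok) > 0.20) {
    abort(sprintf("%.0f%% of bootstrap refits failed; fit unstable.",
                  100 * mean(!ok)),
          class = "phosphene_unstable_fit_error")
  }
  t60 <- vapply(refits[ok], `[[`, numeric(1), "threshold_60")
  t50 <- vapply(refits[ok], `[[`, numeric(1), "threshold_50")
  fit$bootstrap_se <- list(
    threshold_60 = if (sum(ok) > 1) sd(t60) else 0,
    threshold_50 = if (sum(ok) > 1) sd(t50) else 0,
    replicates = tibble(threshold_60 = t60, threshold_50 = t50),
    n_boot = as.integer(n_boot),
    n_failed = as.integer(sum(!ok))
  )
  fit
}
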