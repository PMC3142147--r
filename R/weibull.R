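#' Weibull psychometric-function parameters
#'
#' Bundles the four parameters of the lapse-corrected Weibull psychometric
#' function used throughout the package:
#' \deqn{\psi(x) = \gamma + (1 - \gamma - \lambda)\,(1 - e^{-(x/\alpha)^\beta})}
#' where \eqn{\alpha} is the position parameter (the intensity at which the
#' lapse-free, guess-free curve reaches \eqn{1 - e^{-1} \approx 63\%}
#' detection), \eqn{\beta} the slope, \eqn{\gamma} the lower asymptote
#' (guess / false-alarm rate; 0 for yes/no phosphene detection, 0.5 for
#' 2AFC), and \eqn{\lambda} the lapse rate compressing the upper asymptote
#' to \eqn{1 - \lambda}.
#'
#' @param alpha Position parameter, in stimulus units (percent of maximum
#'   stimulator output for phosphene work, contrast for 2AFC validation).
#'   Must be positive.
#' @param beta Slope parameter, dimensionless, positive.
#' @param guess Lower asymptote \eqn{\gamma}, a probability in `[0, 1)`.
#' @param lapse Lapse rate \eqn{\lambda}, a probability in `[0, 1)`.
#'   `guess + lapse` must be below 1.
#'
#' @return An object of class `weibull_params`.
#' @examples
#' wp <- weibull_params(alpha = 65, beta = 8, guess = 0, lapse = 0.04)
#' detect_prob(65, wp)
#' @export
weibull_params <- function(alpha, beta, guess = 0, lapse = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number.", class = "phosphene_param_error")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.", class = "phosphene_param_error")
  }
  if (!is.numeric(guess) || length(guess) != 1L || guess < 0 || guess >= 1) {
    abort("`guess` must be a probability in [0, 1).", class = "phosphene_param_error")
  }
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse >= 1) {
    abort("`lapse` must be a probability in [0, 1).", class = "phosphene_param_error")
  }
  if (guess + lapse >= 1) {
    abort("`guess + lapse` must be strictly below 1.", class = "phosphene_param_error")
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         guess = as.numeric(guess), lapse = as.numeric(lapse)),
    class = "weibull_params"
  )
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf(
    "Weibull psychometric parameters: alpha = %.4g, beta = %.4g, guess = %.3g, lapse = %.3g\n",
    x$alpha, x$beta, x$guess, x$lapse
  ))
  invisible(x)
}

#' Detection probability of the lapse-corrected Weibull
#'
#' Evaluates \eqn{\psi(x) = \gamma + (1-\gamma-\lambda)(1 - e^{-(x/\alpha)^\beta})}.
#' At `x = alpha` with `guess = 0` and `lapse = 0` this is
#' \eqn{1 - e^{-1} \approx 0.632}, the conventional 63%-correct definition of
#' the Weibull threshold.
#'
#' @param x Stimulus intensity (vectorized), non-negative.
#' @param params A [weibull_params()] object.
#' @return Detection probabilities in `[guess, 1 - lapse]`.
#' @export
detect_prob <- function(x, params) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and non-negative.", class = "phosphene_domain_error")
  }
  params$guess + (1 - params$guess - params$lapse) *
    (1 - exp(-(x / params$alpha)^params$beta))
}

#' Stimulus intensity at a target detection probability
#'
#' Inverts the lapse-corrected Weibull in closed form:
#' \deqn{x = \alpha \left[-\log\!\big(1 - \tfrac{p - \gamma}{1-\gamma-\lambda}\big)\right]^{1/\beta}.}
#' Used to read the staircase threshold out at 60% accuracy (the convention
#' for the lapse-corrected yes/no curve) and the post-hoc 50% threshold.
#'
#' @param p_target Target probability (vectorized), strictly inside
#'   `(guess, 1 - lapse)`.
#' @param params A [weibull_params()] object.
#' @return Stimulus intensity `x` with `detect_prob(x, params) == p_target`.
#' @export
threshold_at_accuracy <- function(p_target, params) {
  stopifnot(inherits(params, "weibull_params"))
  lo <- params$guess
  hi <- 1 - params$lapse
  if (any(!is.finite(p_target)) || any(p_target <= lo) || any(p_target >= hi)) {
    abort(
      sprintf("`p_target` must lie strictly inside (%.3g, %.3g).", lo, hi),
      class = "phosphene_unattainable_accuracy_error"
    )
  }
  q <- (p_target - params$guess) / (1 - params$guess - params$lapse)
  params$alpha * (-log(1 - q))^(1 / params$beta)
}

#' Express an intensity as a level in decibels
#'
#' `20 * log10(x / reference)`, the convention used to quote staircase
#' precision (e.g. a threshold-estimate SD of 2 dB).
#'
#' @param x Intensity (vectorized), positive.
#' @param reference Reference intensity, positive.
#' @return Level in dB.
#' @export
to_decibels <- function(x, reference) {
  if (any(!is.finite(x)) || any(x <= 0) || !is.finite(reference) || reference <= 0) {
    abort("`x` and `reference` must be positive.", class = "phosphene_domain_error")
  }
  20 * log10(x / reference)
}
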