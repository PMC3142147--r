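#' Configuration for the Psi adaptive staircase
#'
#' Defaults match phosphene-threshold estimation on a percent-of-maximum-
#' stimulator-output axis: candidate positions `alpha` 1..100 in steps of 1,
#' ten log-spaced candidate slopes in `[0.5, 20]`, deliverable intensities
#' the integers 1..100, guess rate 0 (yes/no detection), lapse rate fixed at
#' 0.04, and a fixed run length of 30 trials. All axes are overridable, e.g.
#' log-spaced contrast axes for a 2AFC validation observer with `guess = 0.5`.
#'
#' @param alpha_grid Ordered vector of candidate position parameters.
#' @param beta_grid Ordered vector of candidate slopes.
#' @param x_grid Ordered vector of deliverable stimulus intensities.
#' @param guess Lower asymptote used in the likelihood table.
#' @param lapse Lapse rate used in the likelihood table (fixed, not estimated).
#' @param n_trials Fixed number of trials per run (default 30).
#' @param threshold_accuracy Accuracy level at which the reported threshold
#'   is read off the fitted curve (default 0.60, the lapse-corrected
#'   convention for yes/no detection). Must lie in `(guess, 1 - lapse)`.
#' @return A `psi_config` list.
#' @export
psi_config <- function(alpha_grid = seq(1, 100, by = 1),
                       beta_grid = exp(seq(log(0.5), log(20), length.out = 10)),
                       x_grid = 1:100,
                       guess = 0, lapse = 0.04,
                       n_trials = 30L,
                       threshold_accuracy = 0.60) {
  for (nm in c("alpha_grid", "beta_grid", "x_grid")) {
    v <- get(nm)
    if (length(v) == 0L || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE)) {
      abort(sprintf("`%s` must be non-empty and strictly increasing.", nm),
            class = "phosphene_config_error")
    }
  }
  if (min(alpha_grid) <= 0) {
    abort("`alpha_grid` must be positive.", class = "phosphene_config_error")
  }
  if (n_trials < 1) {
    abort("`n_trials` must be >= 1.", class = "phosphene_config_error")
  }
  if (threshold_accuracy <= guess || threshold_accuracy >= 1 - lapse) {
    abort("`threshold_accuracy` must lie in (guess, 1 - lapse).",
          class = "phosphene_config_error")
  }
  structure(
    list(alpha_grid = as.numeric(alpha_grid), beta_grid = as.numeric(beta_grid),
         x_grid = as.numeric(x_grid), guess = guess, lapse = lapse,
         n_trials = as.integer(n_trials), threshold_accuracy = threshold_accuracy),
    class = "psi_config"
  )
}

#' Initialize a Psi staircase state
#'
#' Builds the precomputed likelihood table `P(seen | alpha, beta, x)` over
#' the full (alpha, beta) x intensity grid and a uniform prior over the
#' (alpha, beta) nodes.
#'
#' @param config A [psi_config()].
#' @return A `psi_state`: the grid, the likelihood table (nodes x
#'   intensities), the posterior mass vector, and an empty trial history.
#' @export
psi_init <- function(config = psi_config()) {
  stopifnot(inherits(config, "psi_config"))
  nodes <- expand.grid(alpha = config$alpha_grid, beta = config$beta_grid,
                       KEEP.OUT.ATTRS = FALSE)
  # rows: (alpha, beta) nodes; cols: candidate intensities
  lik <- vapply(config$x_grid, function(x) {
    config$guess + (1 - config$guess - config$lapse) *
      (1 - exp(-(x / nodes$alpha)^nodes$beta))
  }, numeric(nrow(nodes)))
  structure(
    list(
      config = config,
      node_alpha = nodes$alpha,
      node_beta = nodes$beta,
      likelihood = lik,
      posterior = rep(1 / nrow(nodes), nrow(nodes)),
      history = tibble(trial = integer(), intensity = numeric(),
                       response = integer(), entropy = numeric())
    ),
    class = "psi_state"
  )
}

#' @export
print.psi_state <- function(x, ...) {
  cat(sprintf(
    "Psi staircase state: %d x %d (alpha x beta) grid, %d candidate intensities, %d/%d trials\n",
    length(x$config$alpha_grid), length(x$config$beta_grid),
    length(x$config$x_grid), nrow(x$history), x$config$n_trials
  ))
  invisible(x)
}

# x * log(x) with the 0 * log(0) = 0 convention (likelihoods can underflow
# to exactly 0 at extreme grid corners).
xlogx <- function(w) {
  out <- w * log(w)
  out[w == 0] <- 0
  out
}

posterior_entropy <- function(posterior) -sum(xlogx(posterior))

#' Expected posterior entropy after a hypothetical trial
#'
#' For each candidate intensity `x`, computes
#' \eqn{H_1 P(r{=}1|x) + H_0 P(r{=}0|x)}, where \eqn{P(r{=}1|x)} is the
#' posterior-predictive probability of "seen" and \eqn{H_r} the Shannon
#' entropy (nats) of the posterior after a Bayes update with outcome `r`.
#' The staircase delivers the intensity minimizing this quantity.
#'
#' @param state A `psi_state`.
#' @param x Candidate intensities; defaults to the whole grid.
#' @return Numeric vector of expected entropies, one per candidate.
#' @export
psi_expected_entropy <- function(state, x = state$config$x_grid) {
  stopifnot(inherits(state, "psi_state"))
  ix <- match(x, state$config$x_grid)
  if (any(is.na(ix))) {
    abort("Candidate intensity not on the configured grid.",
          class = "phosphene_domain_error")
  }
  post <- state$posterior
  w1 <- post * state$likelihood[, ix, drop = FALSE]
  w0 <- post - w1
  s1 <- .colSums(w1, nrow(w1), ncol(w1))
  s0 <- 1 - s1
  # s * H(w/s) = -sum(w log w) + s log s, summed over both outcomes
  -.colSums(xlogx(w1), nrow(w1), ncol(w1)) + xlogx(s1) -
    .colSums(xlogx(w0), nrow(w0), ncol(w0)) + xlogx(s0)
}

#' Next intensity chosen by expected-entropy minimization
#'
#' Deterministic given the state; ties are broken toward the lowest
#' intensity (least participant discomfort).
#'
#' @param state A `psi_state`.
#' @return A single intensity from the configured grid.
#' @export
psi_next_intensity <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  if (nrow(state$history) >= state$config$n_trials) {
    abort("Staircase already complete.", class = "phosphene_state_error")
  }
  eh <- psi_expected_entropy(state)
  state$config$x_grid[which.min(eh)]
}

#' Bayes-update the posterior with an observed response
#'
#' Multiplies the posterior by the Bernoulli likelihood of the response at
#' the delivered intensity and renormalizes; the trial is appended to the
#' history together with the post-update posterior entropy.
#'
#' @param state A `psi_state`.
#' @param x Delivered intensity (must be on the grid).
#' @param response Binary response: 1 = seen, 0 = not seen.
#' @return The updated `psi_state`.
#' @export
psi_update <- function(state, x, response) {
  stopifnot(inherits(state, "psi_state"))
  if (nrow(state$history) >= state$config$n_trials) {
    abort("Staircase already complete.", class = "phosphene_state_error")
  }
  j <- match(x, state$config$x_grid)
  if (is.na(j)) {
    abort("Intensity not on the configured grid.", class = "phosphene_domain_error")
  }
  if (!response %in% c(0, 1)) {
    abort("`response` must be 0 or 1.", class = "phosphene_domain_error")
  }
  lik <- if (response == 1) state$likelihood[, j] else 1 - state$likelihood[, j]
  post <- state$posterior * lik
  total <- sum(post)
  if (!is.finite(total) || total <= 0) {
    abort("Posterior mass vanished during update.", class = "phosphene_numeric_error")
  }
  state$posterior <- post / total
  state$history <- dplyr::bind_rows(state$history, tibble(
    trial = nrow(state$history) + 1L,
    intensity = as.numeric(x),
    response = as.integer(response),
    entropy = posterior_entropy(state$posterior)
  ))
  state
}

# Posterior point estimates: marginal means of alpha and beta.
psi_estimates <- function(state) {
  list(alpha = sum(state$posterior * state$node_alpha),
       beta = sum(state$posterior * state$node_beta))
}

#' Run a complete REPT staircase
#'
#' Executes the fixed-length select-deliver-update loop: on each of the
#' `n_trials` trials (30 by default) the expected-entropy-minimizing
#' intensity is delivered to the responder and the posterior updated with
#' its binary answer. The reported threshold is the intensity at which the
#' lapse-corrected curve fitted at the posterior-mean (alpha, beta) reaches
#' `threshold_accuracy` (60% by default), clamped to the intensity grid; a
#' post-hoc 50% threshold is included when 0.5 is attainable.
#'
#' @param responder A function of intensity returning 0/1 (see
#'   [as_responder()]), or a [sim_observer()].
#' @param config A [psi_config()].
#' @return A `rept_result` with elements `threshold`, `alpha_estimate`,
#'   `beta_estimate`, `threshold_50`, `n_trials`, `history` (a tibble), the
#'   final `posterior` and `config`.
#' @examples
#' obs <- sim_observer(weibull_params(60, 10, lapse = 0.04), seed = 7)
#' res <- run_rept(obs)
#' glance(res)
#' @export
run_rept <- function(responder, config = psi_config()) {
  if (inherits(responder, "sim_observer")) responder <- as_responder(responder)
  stopifnot(is.function(responder))
  state <- psi_init(config)
  for (i in seq_len(config$n_trials)) {
    x <- psi_next_intensity(state)
    r <- tryCatch(responder(x), error = function(e) {
      abort("Responder failed; session aborted.",
            class = "phosphene_session_error",
            partial_history = state$history, parent = e)
    })
    if (!isTRUE(r %in% c(0, 1))) {
      abort("Responder must return 0 or 1.", class = "phosphene_session_error",
            partial_history = state$history)
    }
    state <- psi_update(state, x, r)
  }
  est <- psi_estimates(state)
  fitted <- weibull_params(est$alpha, est$beta,
                           guess = config$guess, lapse = config$lapse)
  clamp <- function(v) min(max(v, min(config$x_grid)), max(config$x_grid))
  threshold <- clamp(threshold_at_accuracy(config$threshold_accuracy, fitted))
  threshold_50 <- if (config$guess < 0.5 && 1 - config$lapse > 0.5) {
    clamp(threshold_at_accuracy(0.5, fitted))
  } else {
    NA_real_
  }
  structure(
    list(threshold = threshold,
         alpha_estimate = est$alpha,
         beta_estimate = est$beta,
         threshold_50 = threshold_50,
         n_trials = nrow(state$history),
         history = state$history,
         posterior = state$posterior,
         config = config),
    class = "rept_result"
  )
}

#' @export
print.rept_result <- function(x, ...) {
  cat(sprintf(
    paste0("REPT staircase result (%d trials)\n",
           "  threshold (%.0f%% accuracy): %.2f\n",
           "  alpha estimate: %.2f   beta estimate: %.2f\n"),
    x$n_trials, 100 * x$config$threshold_accuracy, x$threshold,
    x$alpha_estimate, x$beta_estimate
  ))
  if (is.finite(x$threshold_50)) {
    cat(sprintf("  post-hoc 50%% threshold: %.2f\n", x$threshold_50))
  }
  invisible(x)
}
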