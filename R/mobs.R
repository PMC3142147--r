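#' Modified binary search (MOBS) staircase state
#'
#' MOBS brackets the threshold with two boundary stacks, initialized at the
#' full stimulator range (1--100% of maximum output by default), and tests
#' the integer midpoint of the current stack tops. A "seen" response pushes
#' the tested value as a new upper boundary, "not seen" as a new lower
#' boundary; after two consecutive identical responses the opposite stack
#' retreats one level (it pops, never below its initial value). The run
#' terminates at the sixth reversal — the sixth change of response category
#' between consecutive trials — with a hard 100-trial safety cap.
#'
#' @param lower,upper Initial boundary intensities (defaults 1 and 100).
#' @param n_reversals Reversal count at which the run terminates (default 6).
#' @param max_trials Safety cap guaranteeing termination (default 100).
#' @return A `mobs_state`.
#' @export
mobs_init <- function(lower = 1, upper = 100, n_reversals = 6L, max_trials = 100L) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    abort("`lower` must be below `upper`.", class = "phosphene_config_error")
  }
  structure(
    list(lower_stack = as.numeric(lower),
         upper_stack = as.numeric(upper),
         n_reversals = as.integer(n_reversals),
         max_trials = as.integer(max_trials),
         reversal_count = 0L,
         last_response = NA_integer_,
         terminated = FALSE,
         history = tibble(trial = integer(), intensity = numeric(),
                          response = integer(), reversal = logical())),
    class = "mobs_state"
  )
}

round_half_up <- function(x) floor(x + 0.5)

#' Next MOBS test intensity
#'
#' The integer midpoint of the current boundary-stack tops, rounding half
#' up (the stimulator accepts integer percent).
#'
#' @param state A `mobs_state`.
#' @return A single integer intensity.
#' @export
mobs_next <- function(state) {
  stopifnot(inherits(state, "mobs_state"))
  if (state$terminated) {
    abort("MOBS staircase already terminated.", class = "phosphene_state_error")
  }
  round_half_up((tail(state$lower_stack, 1) + tail(state$upper_stack, 1)) / 2)
}

#' Update the MOBS state with a response
#'
#' Applies the boundary push, the retreat rule and the reversal counter, and
#' sets the termination flag when the configured reversal count (or the
#' trial cap) is reached.
#'
#' @param state A `mobs_state`.
#' @param response Binary response: 1 = seen, 0 = not seen.
#' @return The updated `mobs_state`.
#' @export
mobs_update <- function(state, response) {
  stopifnot(inherits(state, "mobs_state"))
  if (state$terminated) {
    abort("MOBS staircase already terminated.", class = "phosphene_state_error")
  }
  if (!response %in% c(0, 1)) {
    abort("`response` must be 0 or 1.", class = "phosphene_domain_error")
  }
  response <- as.integer(response)
  current <- mobs_next(state)
  is_reversal <- !is.na(state$last_response) && response != state$last_response
  repeated <- !is.na(state$last_response) && response == state$last_response

  if (response == 1L) {
    # seen: current becomes the new upper boundary
    if (current > tail(state$lower_stack, 1)) {
      state$upper_stack <- c(state$upper_stack, current)
    }
    if (repeated && length(state$lower_stack) > 1L) {
      state$lower_stack <- head(state$lower_stack, -1L)
    }
  } else {
    # not seen: current becomes the new lower boundary
    if (current < tail(state$upper_stack, 1)) {
      state$lower_stack <- c(state$lower_stack, current)
    }
    if (repeated && length(state$upper_stack) > 1L) {
      state$upper_stack <- head(state$upper_stack, -1L)
    }
  }

  if (is_reversal) state$reversal_count <- state$reversal_count + 1L
  state$last_response <- response
  state$history <- dplyr::bind_rows(state$history, tibble(
    trial = nrow(state$history) + 1L,
    intensity = as.numeric(current),
    response = response,
    reversal = is_reversal
  ))
  if (state$reversal_count >= state$n_reversals ||
      nrow(state$history) >= state$max_trials) {
    state$terminated <- TRUE
  }
  state
}

#' MOBS threshold estimate at termination
#'
#' The pending midpoint of the final boundary brackets — the level the
#' bisection has converged on, a 50%-point estimate.
#'
#' @param state A terminated `mobs_state`.
#' @return A single intensity in the configured range.
#' @export
mobs_estimate <- function(state) {
  stopifnot(inherits(state, "mobs_state"))
  if (!state$terminated) {
    abort("MOBS staircase has not terminated.", class = "phosphene_state_error")
  }
  round_half_up((tail(state$lower_stack, 1) + tail(state$upper_stack, 1)) / 2)
}

#' Run a complete MOBS staircase
#'
#' @param responder A function of intensity returning 0/1, or a
#'   [sim_observer()].
#' @param lower,upper,n_reversals,max_trials Passed to [mobs_init()].
#' @return A `mobs_result` with elements `threshold`, `n_trials`,
#'   `reversals`, `history` (a tibble) and the final `state`.
#' @examples
#' obs <- sim_observer(weibull_params(60, 10, lapse = 0.04), seed = 3)
#' run_mobs(obs)
#' @export
run_mobs <- function(responder, lower = 1, upper = 100,
                     n_reversals = 6L, max_trials = 100L) {
  if (inherits(responder, "sim_observer")) responder <- as_responder(responder)
  stopifnot(is.function(responder))
  state <- mobs_init(lower, upper, n_reversals, max_trials)
  while (!state$terminated) {
    x <- mobs_next(state)
    r <- tryCatch(responder(x), error = function(e) {
      abort("Responder failed; session aborted.",
            class = "phosphene_session_error",
            partial_history = state$history, parent = e)
    })
    state <- mobs_update(state, r)
  }
  structure(
    list(threshold = mobs_estimate(state),
         n_trials = nrow(state$history),
         reversals = state$reversal_count,
         history = state$history,
         state = state),
    class = "mobs_result"
  )
}

#' @export
print.mobs_result <- function(x, ...) {
  cat(sprintf(
    "MOBS staircase result: threshold %.0f after %d trials (%d reversals)\n",
    x$threshold, x$n_trials, x$reversals
  ))
  invisible(x)
}
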