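#' Simulated phosphene / 2AFC observer
#'
#' A stochastic stand-in for a human participant: each pulse at intensity
#' `x` draws a Bernoulli "seen" response with probability
#' `detect_prob(x, params)`. The observer owns a private RNG stream, so two
#' observers built with the same seed and parameters produce identical
#' response sequences regardless of what else uses the global RNG.
#'
#' @param params A [weibull_params()] object with the observer's true
#'   psychometric function. Use `guess = 0` for yes/no phosphene detection
#'   and `guess = 0.5` for a 2AFC observer.
#' @param seed Integer seed for the observer's private response stream.
#' @param mode `"yes_no"` or `"2afc"`; informational label, the response
#'   model is fully determined by `params`.
#' @return An object of class `sim_observer`.
#' @examples
#' obs <- sim_observer(weibull_params(60, 10, lapse = 0.04), seed = 1)
#' respond(obs, 60)
#' @export
sim_observer <- function(params, seed, mode = c("yes_no", "2afc")) {
  stopifnot(inherits(params, "weibull_params"))
  mode <- match.arg(mode)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.", class = "phosphene_config_error")
  }
  env <- new.env(parent = emptyenv())
  env$rng_state <- NULL
  structure(
    list(params = params, seed = as.integer(seed), mode = mode, .env = env),
    class = "sim_observer"
  )
}

#' @export
print.sim_observer <- function(x, ...) {
  cat(sprintf("Simulated %s observer (seed %d):\n", x$mode, x$seed))
  print(x$params)
  invisible(x)
}

# Draw n uniforms from the observer's private stream without disturbing the
# global RNG state.
observer_runif <- function(observer, n) {
  env <- observer$.env
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  if (is.null(env$rng_state)) set.seed(observer$seed) else
    assign(".Random.seed", env$rng_state, envir = globalenv())
  u <- runif(n)
  env$rng_state <- get(".Random.seed", envir = globalenv())
  if (had_seed) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  u
}

#' Observer response to a single pulse
#'
#' @param observer A [sim_observer()].
#' @param x Stimulus intensity.
#' @return Integer response: 1 = seen (correct), 0 = not seen.
#' @export
respond <- function(observer, x) {
  stopifnot(inherits(observer, "sim_observer"))
  p <- detect_prob(x, observer$params)
  as.integer(observer_runif(observer, 1L) < p)
}

#' Turn an observer (or response vector) into a responder function
#'
#' Staircase runners accept any function of intensity returning a binary
#' response. This helper adapts a [sim_observer()], or a pre-recorded
#' response vector (consumed in order, for replay and scripted fixtures).
#'
#' @param x A `sim_observer` or an integer vector of 0/1 responses.
#' @return A function `f(intensity) -> 0/1`.
#' @export
as_responder <- function(x) {
  if (inherits(x, "sim_observer")) {
    function(intensity) respond(x, intensity)
  } else if (is.numeric(x) && all(x %in% c(0, 1))) {
    responses <- as.integer(x)
    i <- 0L
    function(intensity) {
      i <<- i + 1L
      if (i > length(responses)) {
        abort("Scripted responder exhausted.", class = "phosphene_responder_error")
      }
      responses[i]
    }
  } else {
    abort("`x` must be a sim_observer or a 0/1 vector.",
          class = "phosphene_config_error")
  }
}

#' Draw a reproducible panel of simulated observers
#'
#' Emulates a participant panel for in-silico validation: position parameters
#' drawn uniformly (default 40--80% of maximum stimulator output, bracketing
#' typical phosphene thresholds), slopes log-uniform (default 4--16), lapse
#' rate fixed at 0.04 and guess rate at 0 (yes/no detection).
#'
#' @param n Number of observers (>= 1).
#' @param alpha_range Length-2 range for the uniform draw of `alpha`.
#' @param beta_range Length-2 positive range for the log-uniform draw of `beta`.
#' @param lapse,guess Fixed asymptote parameters for every panel member.
#' @param seed Integer seed; the panel and each member's response stream are
#'   reproducible under it.
#' @return A list of [sim_observer()] objects.
#' @export
observer_panel <- function(n, alpha_range = c(40, 80), beta_range = c(4, 16),
                           lapse = 0.04, guess = 0, seed = 1L) {
  if (!is.numeric(n) || n < 1) {
    abort("`n` must be >= 1.", class = "phosphene_config_error")
  }
  if (length(alpha_range) != 2L || diff(alpha_range) <= 0 || alpha_range[1] <= 0 ||
      length(beta_range) != 2L || diff(beta_range) <= 0 || beta_range[1] <= 0) {
    abort("Parameter ranges must be increasing and positive.",
          class = "phosphene_config_error")
  }
  draws <- local_rng(seed, {
    list(alpha = runif(n, alpha_range[1], alpha_range[2]),
         beta = exp(runif(n, log(beta_range[1]), log(beta_range[2]))),
         seeds = sample.int(.Machine$integer.max, n))
  })
  lapply(seq_len(n), function(i) {
    sim_observer(
      weibull_params(draws$alpha[i], draws$beta[i], guess = guess, lapse = lapse),
      seed = draws$seeds[i]
    )
  })
}

# Evaluate `expr` under a temporary RNG seed, restoring global state after.
local_rng <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Serialize / restore observer specifications
#'
#' Observer specs (parameters, seed, mode) round-trip through JSON so that a
#' validation scenario can be archived and replayed exactly.
#'
#' @param observers A list of [sim_observer()] objects (or a single one).
#' @param path File path for the JSON spec.
#' @return `write_observer_spec` returns `path` invisibly;
#'   `read_observer_spec` returns a list of `sim_observer` objects.
#' @export
write_observer_spec <- function(observers, path) {
  if (inherits(observers, "sim_observer")) observers <- list(observers)
  spec <- lapply(observers, function(o) {
    list(alpha = o$params$alpha, beta = o$params$beta, guess = o$params$guess,
         lapse = o$params$lapse, seed = o$seed, mode = o$mode)
  })
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observer_spec
#' @export
read_observer_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(spec, function(s) {
    sim_observer(
      weibull_params(s$alpha, s$beta, guess = s$guess, lapse = s$lapse),
      seed = s$seed, mode = s$mode
    )
  })
}
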