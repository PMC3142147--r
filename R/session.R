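#' Mock pulse-delivery device
#'
#' A stand-in for a TMS stimulator exposing the three-method contract the
#' staircases need — set intensity, arm, trigger — plus a safety gate: a
#' pulse is refused (with a logged safety error) if requested before the
#' configured minimum inter-pulse interval has elapsed. The mock keeps a
#' virtual clock in seconds; simulated sessions advance it explicitly, so
#' runs are instantaneous yet produce realistic timestamps. A driver for a
#' real serial-controlled stimulator can implement the same contract.
#'
#' The default 2.5 s minimum interval, together with typical response
#' latencies, yields an average stimulation frequency of about 0.36 Hz over
#' a 30-trial run; a 6 s slow mode yields about 0.16 Hz.
#'
#' @param min_interval Minimum inter-pulse interval in seconds (default 2.5).
#' @return A `pulse_device` environment.
#' @export
mock_stimulator <- function(min_interval = 2.5) {
  if (!is.numeric(min_interval) || min_interval < 0) {
    abort("`min_interval` must be non-negative.", class = "phosphene_config_error")
  }
  dev <- new.env(parent = emptyenv())
  dev$min_interval <- min_interval
  dev$armed <- FALSE
  dev$intensity <- NA_real_
  dev$time <- 0
  dev$last_pulse_time <- -Inf
  dev$pulse_log <- tibble(time = numeric(), intensity = numeric())
  class(dev) <- "pulse_device"
  dev
}

#' @export
print.pulse_device <- function(x, ...) {
  cat(sprintf(
    "Mock pulse device: %s, intensity %s, %d pulses delivered, min interval %.2f s\n",
    if (x$armed) "armed" else "disarmed",
    if (is.na(x$intensity)) "unset" else sprintf("%.0f%%", x$intensity),
    nrow(x$pulse_log), x$min_interval
  ))
  invisible(x)
}

#' @rdname mock_stimulator
#' @param device A `pulse_device`.
#' @export
device_arm <- function(device) {
  stopifnot(inherits(device, "pulse_device"))
  device$armed <- TRUE
  invisible(device)
}

#' @rdname mock_stimulator
#' @param intensity Integer intensity in `[1, 100]` (% of maximum output).
#' @export
device_set_intensity <- function(device, intensity) {
  stopifnot(inherits(device, "pulse_device"))
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      intensity < 1 || intensity > 100 || intensity != round(intensity)) {
    abort("Intensity must be an integer in [1, 100].",
          class = "phosphene_domain_error")
  }
  device$intensity <- as.numeric(intensity)
  invisible(device)
}

#' @rdname mock_stimulator
#' @param seconds Seconds to advance the virtual clock.
#' @export
device_wait <- function(device, seconds) {
  stopifnot(inherits(device, "pulse_device"), seconds >= 0)
  device$time <- device$time + seconds
  invisible(device)
}

#' Deliver a pulse through the device contract
#'
#' Sets the intensity and triggers a pulse, enforcing the safety interval:
#' if the minimum inter-pulse interval has not elapsed on the device clock
#' the pulse is refused with a `phosphene_safety_error`.
#'
#' @param device A `pulse_device` (see [mock_stimulator()]).
#' @param intensity Integer intensity in `[1, 100]`.
#' @return The pulse timestamp (seconds from session start), invisibly the
#'   device is updated.
#' @export
deliver_pulse <- function(device, intensity) {
  stopifnot(inherits(device, "pulse_device"))
  if (!device$armed) {
    abort("Device is not armed.", class = "phosphene_safety_error")
  }
  device_set_intensity(device, intensity)
  elapsed <- device$time - device$last_pulse_time
  if (elapsed < device$min_interval - 1e-9) {
    abort(sprintf(
      "Pulse refused: %.2f s since last pulse, minimum interval %.2f s.",
      elapsed, device$min_interval
    ), class = "phosphene_safety_error")
  }
  device$last_pulse_time <- device$time
  device$pulse_log <- dplyr::bind_rows(
    device$pulse_log, tibble(time = device$time, intensity = device$intensity)
  )
  device$time
}

#' Keyboard responder for interactive sessions
#'
#' Maps two designated keys to seen / not seen (mirroring the right/left
#' Shift scheme of keyboard-response phosphene work). Reads one line per
#' trial from `con`, so it is scriptable in tests via a text connection.
#'
#' @param seen_key,notseen_key Single characters accepted as responses.
#' @param con Connection to read from (default stdin).
#' @param prompt Whether to print a prompt before each trial.
#' @return A responder function of intensity returning 0/1.
#' @export
keyboard_responder <- function(seen_key = "l", notseen_key = "a",
                               con = stdin(), prompt = TRUE) {
  function(intensity) {
    repeat {
      if (prompt) {
        cat(sprintf("Pulse at %d%% - seen [%s] / not seen [%s]? ",
                    as.integer(intensity), seen_key, notseen_key))
      }
      key <- tolower(trimws(readLines(con, n = 1L)))
      if (length(key) == 0L) {
        abort("Input stream closed.", class = "phosphene_responder_error")
      }
      if (key == tolower(seen_key)) return(1L)
      if (key == tolower(notseen_key)) return(0L)
    }
  }
}

#' Run a staircase as a timed, logged session
#'
#' Binds a staircase procedure to a responder through the pulse-device
#' contract: each trial waits out the safety interval on the device clock
#' (counted from the previous response, so inter-pulse gaps are interval
#' plus response latency), delivers the pulse, collects the response after
#' the configured latency, and records a timestamped trial. Returns a session log that can be
#' written to disk and deterministically replayed.
#'
#' @param procedure `"rept"`, `"mobs"` or `"mocs"`.
#' @param responder A responder function or [sim_observer()].
#' @param config A [psi_config()] (REPT), a list of [mobs_init()] arguments
#'   (MOBS), or a [design_mocs()] object (MOCS).
#' @param device A `pulse_device`; default [mock_stimulator()].
#' @param response_latency Seconds from pulse to response on the virtual
#'   clock (default 0.35).
#' @param observer_label Free-text label stored in the log (e.g. the
#'   observer spec or `"interactive"`).
#' @return A `session_log` with the procedure name, config snapshot, trial
#'   tibble (`trial`, `intensity`, `response`, `timestamp`) and the
#'   procedure result.
#' @examples
#' obs <- sim_observer(weibull_params(60, 10, lapse = 0.04), seed = 11)
#' log <- run_session("rept", obs)
#' session_frequency(log)
#' @export
run_session <- function(procedure = c("rept", "mobs", "mocs"),
                        responder, config = NULL,
                        device = mock_stimulator(),
                        response_latency = 0.35,
                        observer_label = NULL) {
  procedure <- match.arg(procedure)
  if (inherits(responder, "sim_observer")) {
    observer_label <- observer_label %||% sprintf(
      "sim_observer(alpha=%.3g, beta=%.3g, guess=%.3g, lapse=%.3g, seed=%d)",
      responder$params$alpha, responder$params$beta, responder$params$guess,
      responder$params$lapse, responder$seed
    )
    responder <- as_responder(responder)
  }
  observer_label <- observer_label %||% "interactive"
  device_arm(device)
  timestamps <- numeric(0)
  responses <- integer(0)
  intensities <- numeric(0)
  timed_responder <- function(x) {
    # conservative pacing: the participant gets the full minimum interval of
    # quiet after responding, so inter-pulse gaps are interval + latency
    if (is.finite(device$last_pulse_time)) device_wait(device, device$min_interval)
    t <- deliver_pulse(device, round_half_up(x))
    r <- responder(x)
    device_wait(device, response_latency)
    timestamps[length(timestamps) + 1L] <<- t
    responses[length(responses) + 1L] <<- as.integer(r)
    intensities[length(intensities) + 1L] <<- as.numeric(x)
    r
  }
  result <- switch(procedure,
    rept = {
      config <- config %||% psi_config()
      run_rept(timed_responder, config)
    },
    mobs = {
      config <- config %||% list()
      do.call(run_mobs, c(list(responder = timed_responder), config))
    },
    mocs = {
      if (!inherits(config, "mocs_design")) {
        abort("MOCS sessions need a `mocs_design` as config.",
              class = "phosphene_config_error")
      }
      run_mocs(timed_responder, config)
    }
  )
  trials <- tibble(trial = seq_along(timestamps),
                   intensity = intensities,
                   response = responses,
                   timestamp = timestamps)
  structure(
    list(procedure = procedure,
         config = config,
         observer = observer_label,
         trials = trials,
         result = result,
         min_interval = device$min_interval,
         response_latency = response_latency),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log: %s, %d trials, %.1f s, observer %s\n",
              toupper(x$procedure), nrow(x$trials),
              session_duration(x), x$observer))
  invisible(x)
}

#' Session duration and average stimulation frequency
#'
#' Duration runs from the first pulse to the last response; frequency is
#' pulses per second of session time (the conventional summary: 30 pulses
#' in 83 s is 0.36 Hz).
#'
#' @param log A `session_log`.
#' @return Seconds (`session_duration`) or Hz (`session_frequency`).
#' @export
session_duration <- function(log) {
  stopifnot(inherits(log, "session_log"))
  max(log$trials$timestamp) + log$response_latency - min(log$trials$timestamp)
}

#' @rdname session_duration
#' @export
session_frequency <- function(log) {
  nrow(log$trials) / session_duration(log)
}

config_snapshot <- function(log) {
  cfg <- log$config
  if (inherits(cfg, "psi_config") || inherits(cfg, "mocs_design")) {
    c(unclass(cfg), list(.class = class(cfg)))
  } else {
    cfg
  }
}

#' Write / read a session log
#'
#' The trial sequence goes to `<path>.csv` (columns trial, intensity,
#' response, timestamp) and the configuration snapshot, observer label and
#' result block to `<path>.json`.
#'
#' @param log A `session_log`.
#' @param path Base path (without extension).
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   a `session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  write.csv(log$trials, paste0(path, ".csv"), row.names = FALSE)
  result_block <- if (log$procedure == "mocs") {
    list(dataset = log$result)
  } else if (log$procedure == "rept") {
    list(threshold = log$result$threshold,
         alpha_estimate = log$result$alpha_estimate,
         beta_estimate = log$result$beta_estimate,
         threshold_50 = log$result$threshold_50,
         n_trials = log$result$n_trials)
  } else {
    list(threshold = log$result$threshold,
         n_trials = log$result$n_trials,
         reversals = log$result$reversals)
  }
  jsonlite::write_json(
    list(procedure = log$procedure,
         observer = log$observer,
         config = config_snapshot(log),
         min_interval = log$min_interval,
         response_latency = log$response_latency,
         result = result_block),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  trials <- as_tibble(read.csv(paste0(path, ".csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  if (!is.null(cfg$.class)) {
    cls <- cfg$.class
    cfg$.class <- NULL
    if ("psi_config" %in% cls) {
      cfg <- do.call(psi_config, cfg[c("alpha_grid", "beta_grid", "x_grid",
                                       "guess", "lapse", "n_trials",
                                       "threshold_accuracy")])
    } else if ("mocs_design" %in% cls) {
      cfg <- structure(
        list(levels = cfg$levels, reps_per_level = as.integer(cfg$reps_per_level),
             presentation_order = cfg$presentation_order,
             seed = as.integer(cfg$seed)),
        class = "mocs_design"
      )
    }
  }
  structure(
    list(procedure = meta$procedure,
         config = cfg,
         observer = meta$observer,
         trials = trials,
         result = meta$result,
         min_interval = meta$min_interval,
         response_latency = meta$response_latency),
    class = "session_log"
  )
}

logged_result_scalar <- function(log, field) {
  r <- log$result
  if (is.list(r) && !is.null(r[[field]])) r[[field]] else r[[field]]
}

#' Replay a logged session
#'
#' Re-runs the logged procedure, feeding back the logged responses, and
#' checks that the recomputed intensity sequence and threshold match the
#' log exactly. A mismatch (tampered or version-skewed log) raises a
#' `phosphene_replay_error`.
#'
#' @param log A `session_log` (in memory or from [read_session_log()]).
#' @return The recomputed procedure result.
#' @export
replay_session <- function(log) {
  stopifnot(inherits(log, "session_log"))
  responder <- as_responder(log$trials$response)
  recomputed <- switch(log$procedure,
    rept = run_rept(responder, log$config),
    mobs = do.call(run_mobs, c(list(responder = responder),
                               if (is.list(log$config) &&
                                   !inherits(log$config, "psi_config")) log$config)),
    mocs = run_mocs(responder, log$config),
    abort("Unknown procedure in log.", class = "phosphene_replay_error")
  )
  if (log$procedure == "mocs") {
    if (!isTRUE(all.equal(as.numeric(log$config$presentation_order),
                          as.numeric(log$trials$intensity)))) {
      abort("Replay diverged: presentation order does not match the log.",
            class = "phosphene_replay_error")
    }
  }
  if (log$procedure %in% c("rept", "mobs")) {
    if (!isTRUE(all.equal(recomputed$history$intensity, log$trials$intensity))) {
      abort("Replay diverged: intensity sequence does not match the log.",
            class = "phosphene_replay_error")
    }
    logged_threshold <- logged_result_scalar(log, "threshold")
    if (!isTRUE(all.equal(as.numeric(recomputed$threshold),
                          as.numeric(logged_threshold), tolerance = 1e-8))) {
      abort("Replay diverged: threshold does not match the log.",
            class = "phosphene_replay_error")
    }
  }
  recomputed
}
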