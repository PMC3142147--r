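# Independent brute-force oracles and small fixtures used across tests.
# Everything here is deliberately naive: plain loops and textbook formulas,
# kept separate from the package's vectorized implementations.

# Weibull detection probability written out longhand.
oracle_detect_prob <- function(x, alpha, beta, guess = 0, lapse = 0) {
  guess + (1 - guess - lapse) * (1 - exp(-(x / alpha)^beta))
}

# Threshold by bisection root-finding on the forward curve.
oracle_threshold <- function(p, alpha, beta, guess = 0, lapse = 0) {
  uniroot(function(x) oracle_detect_prob(x, alpha, beta, guess, lapse) - p,
          lower = 1e-9, upper = alpha * 100, tol = 1e-12)$root
}

# Shannon entropy of a normalized probability vector.
oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

# Expected posterior entropy at a candidate intensity by explicit double
# loop over nodes and outcomes.
oracle_expected_entropy <- function(posterior, likelihood_col) {
  p1 <- 0
  for (k in seq_along(posterior)) p1 <- p1 + posterior[k] * likelihood_col[k]
  post1 <- numeric(length(posterior))
  post0 <- numeric(length(posterior))
  for (k in seq_along(posterior)) {
    post1[k] <- posterior[k] * likelihood_col[k]
    post0[k] <- posterior[k] * (1 - likelihood_col[k])
  }
  h1 <- if (p1 > 0) oracle_entropy(post1 / p1) else 0
  h0 <- if (p1 < 1) oracle_entropy(post0 / (1 - p1)) else 0
  p1 * h1 + (1 - p1) * h0
}

# Exhaustive-search argmin of expected entropy over the intensity grid.
oracle_next_intensity <- function(state) {
  best_x <- NA
  best_eh <- Inf
  for (j in seq_along(state$config$x_grid)) {
    eh <- oracle_expected_entropy(state$posterior, state$likelihood[, j])
    if (eh < best_eh - 1e-15) {
      best_eh <- eh
      best_x <- state$config$x_grid[j]
    }
  }
  best_x
}

# Dense grid search for the binomial ML Weibull fit.
oracle_grid_fit <- function(data, alpha_grid, beta_grid, guess = 0, lapse = 0.04) {
  best <- list(alpha = NA, beta = NA, nll = Inf)
  for (a in alpha_grid) {
    for (b in beta_grid) {
      p <- oracle_detect_prob(data$level, a, b, guess, lapse)
      p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      nll <- -sum(data$seen * log(p) + (data$presented - data$seen) * log(1 - p))
      if (nll < best$nll) best <- list(alpha = a, beta = b, nll = nll)
    }
  }
  best
}

# MOBS re-implementation with exact (unrounded) midpoints: the update rules
# are perfectly mirror-symmetric about the range midpoint, which isolates
# the symmetry property from integer rounding.
oracle_mobs_float <- function(responses, lower = 1, upper = 100,
                              n_reversals = 6L, max_trials = 100L) {
  lower_stack <- lower
  upper_stack <- upper
  last <- NA_integer_
  reversals <- 0L
  i <- 0L
  while (reversals < n_reversals && i < max_trials) {
    i <- i + 1L
    mid <- (tail(lower_stack, 1) + tail(upper_stack, 1)) / 2
    r <- responses[i]
    repeated <- !is.na(last) && r == last
    if (!is.na(last) && r != last) reversals <- reversals + 1L
    if (r == 1L) {
      upper_stack <- c(upper_stack, mid)
      if (repeated && length(lower_stack) > 1L) lower_stack <- head(lower_stack, -1L)
    } else {
      lower_stack <- c(lower_stack, mid)
      if (repeated && length(upper_stack) > 1L) upper_stack <- head(upper_stack, -1L)
    }
    last <- r
  }
  list(estimate = (tail(lower_stack, 1) + tail(upper_stack, 1)) / 2,
       n_trials = i)
}

# Small Psi configuration that keeps oracle comparisons fast.
small_psi_config <- function() {
  psi_config(
    alpha_grid = seq(20, 80, length.out = 7),
    beta_grid = c(2, 6, 12),
    x_grid = seq(10, 90, by = 8),
    guess = 0, lapse = 0.04, n_trials = 10
  )
}

default_yesno_params <- function(alpha = 60, beta = 10) {
  weibull_params(alpha, beta, guess = 0, lapse = 0.04)
}
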