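test_that("initialization builds a uniform prior and a correct likelihood table", {
  cfg <- small_psi_config()
  state <- psi_init(cfg)
  n_nodes <- length(cfg$alpha_grid) * length(cfg$beta_grid)
  expect_length(state$posterior, n_nodes)
  expect_true(all(state$posterior == 1 / n_nodes))
  expect_equal(sum(state$posterior), 1, tolerance = 1e-12)

  # spot-check likelihood entries against the psychometric function
  for (k in c(1, 5, n_nodes)) {
    for (j in c(1, 4, length(cfg$x_grid))) {
      expect_equal(
        state$likelihood[k, j],
        oracle_detect_prob(cfg$x_grid[j], state$node_alpha[k],
                           state$node_beta[k], cfg$guess, cfg$lapse),
        tolerance = 1e-12
      )
    }
  }

  expect_error(psi_config(alpha_grid = c(3, 2, 1)),
               class = "phosphene_config_error")
  expect_error(psi_config(x_grid = numeric(0)),
               class = "phosphene_config_error")
})

test_that("expected entropy matches a brute-force double-loop oracle", {
  cfg <- small_psi_config()
  state <- psi_init(cfg)
  set.seed(11)
  for (rep in 1:5) {
    # random normalized posterior
    w <- rexp(length(state$posterior))
    state$posterior <- w / sum(w)
    eh <- psi_expected_entropy(state)
    oracle <- vapply(seq_along(cfg$x_grid), function(j) {
      oracle_expected_entropy(state$posterior, state$likelihood[, j])
    }, numeric(1))
    expect_equal(eh, oracle, tolerance = 1e-12)
  }
})

test_that("expected entropy is zero for a degenerate posterior and never exceeds current entropy", {
  cfg <- small_psi_config()
  state <- psi_init(cfg)
  state$posterior <- c(1, rep(0, length(state$posterior) - 1))
  expect_true(all(abs(psi_expected_entropy(state)) < 1e-12))

  set.seed(21)
  for (rep in 1:10) {
    w <- rexp(length(state$posterior))
    state$posterior <- w / sum(w)
    h_now <- -sum(state$posterior * log(state$posterior))
    expect_true(all(psi_expected_entropy(state) <= h_now + 1e-10))
  }
})

test_that("next intensity is the exhaustive-search entropy argmin, lowest-first on ties", {
  cfg <- small_psi_config()
  state <- psi_init(cfg)
  set.seed(31)
  for (rep in 1:10) {
    w <- rexp(length(state$posterior))
    state$posterior <- w / sum(w)
    expect_equal(psi_next_intensity(state), oracle_next_intensity(state))
  }

  # symmetric two-candidate tie: mirrored likelihood columns give equal
  # expected entropy, and the lower intensity must win
  tie <- psi_init(psi_config(alpha_grid = c(40, 60), beta_grid = 8,
                             x_grid = c(30, 70), n_trials = 5))
  tie$likelihood <- cbind(c(0.3, 0.7), c(0.7, 0.3))
  eh <- psi_expected_entropy(tie)
  expect_equal(eh[1], eh[2], tolerance = 1e-12)
  expect_equal(psi_next_intensity(tie), 30)
})

test_that("posterior updates follow Bayes rule and commute", {
  cfg <- small_psi_config()
  state <- psi_init(cfg)
  x <- cfg$x_grid[5]

  s_a <- psi_update(psi_update(state, x, 1), x, 0)
  s_b <- psi_update(psi_update(state, x, 0), x, 1)
  expect_equal(s_a$posterior, s_b$posterior, tolerance = 1e-12)
  expect_equal(sum(s_a$posterior), 1, tolerance = 1e-10)
  expect_equal(nrow(s_a$history), 2L)

  # pencil-and-paper two-node example: uniform prior, one "seen" at x = 55
  two <- psi_init(psi_config(alpha_grid = c(50, 70), beta_grid = 8,
                             x_grid = 55, n_trials = 3))
  upd <- psi_update(two, 55, 1)
  l1 <- 0.96 * (1 - exp(-(55 / 50)^8))
  l2 <- 0.96 * (1 - exp(-(55 / 70)^8))
  expect_equal(upd$posterior, c(l1, l2) / (l1 + l2), tolerance = 1e-12)
})

test_that("a completed REPT run has exactly the configured trial count", {
  obs <- sim_observer(default_yesno_params(), seed = 101)
  res <- run_rept(obs)
  expect_identical(res$n_trials, 30L)
  expect_identical(nrow(res$history), 30L)
  expect_true(all(res$history$intensity %in% 1:100))
  expect_true(res$threshold >= 1 && res$threshold <= 100)

  short <- run_rept(sim_observer(default_yesno_params(), seed = 5),
                    psi_config(n_trials = 12))
  expect_identical(short$n_trials, 12L)
})

test_that("identical configuration and responses give identical runs", {
  responses <- rep(c(1L, 0L, 1L, 1L, 0L), 6)
  r1 <- run_rept(as_responder(responses))
  r2 <- run_rept(as_responder(responses))
  expect_identical(r1$history$intensity, r2$history$intensity)
  expect_identical(r1$threshold, r2$threshold)
})

test_that("unrelenting 'not seen' evidence drives the estimate to the top of the grid", {
  res <- run_rept(function(x) 0L)
  expect_gte(res$alpha_estimate, 95)
  expect_gte(res$threshold, 95)
  expect_lte(res$threshold, 100)
})

test_that("posterior entropy declines on average across simulated runs", {
  entropies <- vapply(1:50, function(s) {
    obs <- sim_observer(default_yesno_params(alpha = 55, beta = 8), seed = s)
    run_rept(obs)$history$entropy
  }, numeric(30))
  mean_curve <- rowMeans(entropies)
  expect_true(all(diff(mean_curve) <= 1e-3))
  # normalization held at every trial of every run (entropy finite, >= 0)
  expect_true(all(is.finite(entropies)) && all(entropies >= 0))
})

test_that("threshold estimates recover the observer's true 60% point", {
  true_params <- default_yesno_params(alpha = 60, beta = 10)
  true60 <- threshold_at_accuracy(0.60, true_params)
  est <- vapply(1:60, function(s) {
    run_rept(sim_observer(true_params, seed = 1000 + s))$threshold
  }, numeric(1))
  expect_lt(abs(mean(est) - true60), 3)
})

test_that("state errors are raised for completed staircases and off-grid input", {
  cfg <- psi_config(n_trials = 1)
  state <- psi_init(cfg)
  state <- psi_update(state, 50, 1)
  expect_error(psi_next_intensity(state), class = "phosphene_state_error")
  expect_error(psi_update(state, 50, 0), class = "phosphene_state_error")
  expect_error(psi_expected_entropy(psi_init(cfg), x = 50.5),
               class = "phosphene_domain_error")
})
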