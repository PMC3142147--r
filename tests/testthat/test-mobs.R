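test_that("midpoints follow the round-half-up rule", {
  state <- mobs_init()
  expect_equal(mobs_next(state), 51)  # (1 + 100) / 2 = 50.5, half up

  state$lower_stack <- 40; state$upper_stack <- 60
  expect_equal(mobs_next(state), 50)

  state$lower_stack <- 50; state$upper_stack <- 51
  expect_equal(mobs_next(state), 51)  # degenerate bracket resolves upward
})

test_that("responses push boundaries and the retreat rule pops the opposite stack", {
  state <- mobs_init()
  state <- mobs_update(state, 1)          # seen at 51 -> new upper boundary
  expect_equal(tail(state$upper_stack, 1), 51)
  expect_equal(mobs_next(state), 26)

  state <- mobs_update(state, 0)          # not seen at 26 -> new lower boundary
  expect_equal(tail(state$lower_stack, 1), 26)

  # two consecutive "not seen": lower boundary pushed, upper stack pops
  state <- mobs_update(state, 0)
  expect_equal(tail(state$upper_stack, 1), 100)  # retreated from 51
  expect_equal(tail(state$lower_stack, 1), 39)   # midpoint of 26/51 pushed

  # boundary ordering is preserved throughout
  expect_lt(tail(state$lower_stack, 1), tail(state$upper_stack, 1))
})

test_that("an alternating response sequence terminates at the sixth reversal in 7 trials", {
  state <- mobs_init()
  responses <- c(1, 0, 1, 0, 1, 0, 1)  # first trial cannot be a reversal
  for (r in responses) state <- mobs_update(state, r)
  expect_true(state$terminated)
  expect_identical(state$reversal_count, 6L)
  expect_identical(nrow(state$history), 7L)
  expect_false(state$history$reversal[1])
  # the reversal counter equals the number of adjacent differing pairs
  expect_identical(state$reversal_count,
                   sum(diff(state$history$response) != 0))
})

test_that("monotone responders never reverse and hit the trial cap", {
  res <- run_mobs(function(x) 0L, max_trials = 25)
  expect_identical(res$reversals, 0L)
  expect_identical(res$n_trials, 25L)
  # lower boundary climbed toward the ceiling
  expect_gt(res$threshold, 95)
  expect_lte(res$threshold, 100)
})

test_that("the estimate is the pending midpoint of the final bracket", {
  state <- mobs_init()
  state$lower_stack <- c(1, 55)
  state$upper_stack <- c(100, 57)
  state$reversal_count <- 6L
  state$terminated <- TRUE
  expect_equal(mobs_estimate(state), 56)
  expect_error(mobs_estimate(mobs_init()), class = "phosphene_state_error")
})

test_that("boundary ordering and reversal bookkeeping hold on random runs", {
  set.seed(77)
  for (rep in 1:20) {
    responses <- sample(c(0L, 1L), 100, replace = TRUE)
    state <- mobs_init()
    i <- 0L
    while (!state$terminated) {
      i <- i + 1L
      expect_lt(tail(state$lower_stack, 1), tail(state$upper_stack, 1))
      x <- mobs_next(state)
      expect_true(x >= 1 && x <= 100 && x == round(x))
      state <- mobs_update(state, responses[i])
    }
    expect_identical(state$reversal_count,
                     sum(diff(state$history$response) != 0))
    expect_true(state$reversal_count == 6L || nrow(state$history) == 100L)
    est <- mobs_estimate(state)
    expect_true(est >= 1 && est <= 100)
  }
})

test_that("the estimate converges on a deterministic step-function observer", {
  for (T in c(23, 50, 77)) {
    res <- run_mobs(function(x) as.integer(x >= T))
    final_bracket <- abs(diff(c(tail(res$state$lower_stack, 1),
                                tail(res$state$upper_stack, 1))))
    expect_lte(abs(res$threshold - T), final_bracket + 1)
  }
})

test_that("the update rules are mirror-symmetric about the range midpoint", {
  set.seed(99)
  for (rep in 1:10) {
    responses <- sample(c(0L, 1L), 60, replace = TRUE)
    # with exact midpoints the symmetry is exact: flipping the responses
    # mirrors every boundary about 50.5, hence the estimate too
    run_f <- oracle_mobs_float(responses)
    mir_f <- oracle_mobs_float(1L - responses)
    expect_identical(mir_f$n_trials, run_f$n_trials)
    expect_equal(run_f$estimate + mir_f$estimate, 101, tolerance = 1e-12)

    # the integer implementation tracks its mirror up to accumulated
    # half-unit rounding of the midpoints
    run <- run_mobs(as_responder(responses))
    mirrored <- run_mobs(as_responder(1L - responses[seq_len(run$n_trials)]))
    expect_identical(mirrored$n_trials, run$n_trials)
    expect_lte(abs((run$threshold + mirrored$threshold) - 101), 5)
  }
})

test_that("updates after termination are refused", {
  state <- mobs_init()
  for (r in c(1, 0, 1, 0, 1, 0, 1)) state <- mobs_update(state, r)
  expect_error(mobs_update(state, 1), class = "phosphene_state_error")
  expect_error(mobs_next(state), class = "phosphene_state_error")
})
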