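test_that("the default design brackets the pilot threshold with 7 levels at 5% spacing", {
  d <- design_mocs(60)
  expect_identical(d$levels, c(45, 50, 55, 60, 65, 70, 75))
  expect_identical(length(d$presentation_order), 7L * 25L)
  expect_identical(sort(unique(d$presentation_order)), d$levels)

  # presentation order is a seeded permutation: reproducible, seed-sensitive
  expect_identical(design_mocs(60, seed = 9)$presentation_order,
                   design_mocs(60, seed = 9)$presentation_order)
  expect_false(identical(design_mocs(60, seed = 9)$presentation_order,
                         design_mocs(60, seed = 10)$presentation_order))
})

test_that("designs near the range edge clip but stay strictly increasing", {
  d <- design_mocs(98)
  expect_true(all(d$levels >= 1 & d$levels <= 100))
  expect_true(all(diff(d$levels) > 0))
  expect_gte(length(d$levels), 6L)
  # a pilot so extreme that fewer than 6 levels survive is refused
  expect_error(design_mocs(99, spacing = 30), class = "phosphene_design_error")
})

test_that("a MOCS session tallies counts consistent with the design", {
  d <- design_mocs(60, reps_per_level = 20, seed = 3)
  obs <- sim_observer(default_yesno_params(), seed = 8)
  dat <- run_mocs(obs, d)
  expect_identical(dat$level, as.numeric(d$levels))
  expect_true(all(dat$presented == 20L))
  expect_true(all(dat$seen >= 0 & dat$seen <= dat$presented))
})

test_that("near-noiseless data recover the generating parameters within 2%", {
  gen <- weibull_params(62, 9, lapse = 0.04)
  levels <- c(45, 50, 55, 60, 65, 70, 75)
  n <- 1000L
  dat <- tibble::tibble(
    level = levels, presented = n,
    seen = round(n * detect_prob(levels, gen))
  )
  fit <- fit_weibull_ml(dat)
  expect_lt(abs(fit$params$alpha - 62) / 62, 0.02)
  expect_lt(abs(fit$params$beta - 9) / 9, 0.02)
  expect_lt(fit$threshold_50, fit$threshold_60)
  expect_lte(fit$log_likelihood, 0)
})

test_that("the ML fit matches a dense grid-search oracle within one grid cell", {
  gen <- weibull_params(58, 7, lapse = 0.04)
  obs <- sim_observer(gen, seed = 14)
  dat <- run_mocs(obs, design_mocs(58, reps_per_level = 20, seed = 2))
  fit <- fit_weibull_ml(dat)
  alpha_grid <- seq(40, 80, by = 0.25)
  beta_grid <- exp(seq(log(1), log(30), length.out = 120))
  oracle <- oracle_grid_fit(dat, alpha_grid, beta_grid)
  expect_lte(abs(fit$params$alpha - oracle$alpha), 0.25)
  beta_step <- exp(diff(log(range(beta_grid))) / 119)
  expect_lte(abs(log(fit$params$beta) - log(oracle$beta)), log(beta_step))
  expect_lte(-fit$log_likelihood, oracle$nll + 1e-6)
})

test_that("the optimum log-likelihood is at least that of the generating parameters", {
  gen <- weibull_params(60, 10, lapse = 0.04)
  for (s in 1:5) {
    dat <- run_mocs(sim_observer(gen, seed = 100 + s),
                    design_mocs(60, reps_per_level = 20, seed = s))
    fit <- fit_weibull_ml(dat)
    p <- detect_prob(dat$level, gen)
    ll_gen <- sum(dat$seen * log(p) + (dat$presented - dat$seen) * log(1 - p))
    expect_gte(fit$log_likelihood, ll_gen - 1e-6)
  }
})

test_that("degenerate all-seen / all-unseen datasets are refused", {
  base <- tibble::tibble(level = c(40, 50, 60), presented = 10L)
  expect_error(fit_weibull_ml(dplyr::mutate(base, seen = 0L)),
               class = "phosphene_fit_error")
  expect_error(fit_weibull_ml(dplyr::mutate(base, seen = 10L)),
               class = "phosphene_fit_error")
})

test_that("fitted proportions stay inside binomial 99% envelopes of the data", {
  gen <- weibull_params(60, 8, lapse = 0.04)
  dat <- run_mocs(sim_observer(gen, seed = 31),
                  design_mocs(60, reps_per_level = 30, seed = 7))
  fit <- fit_weibull_ml(dat)
  p_hat <- detect_prob(dat$level, fit$params)
  lower <- qbinom(0.005, dat$presented, p_hat)
  upper <- qbinom(0.995, dat$presented, p_hat)
  expect_true(all(dat$seen >= lower & dat$seen <= upper))
})

test_that("parametric bootstrap errors behave like sampling errors", {
  gen <- weibull_params(60, 9, lapse = 0.04)
  dat <- run_mocs(sim_observer(gen, seed = 4), design_mocs(60, seed = 4))
  fit <- fit_weibull_ml(dat)

  # single resample under a fixed seed is reproducible
  one_a <- bootstrap_threshold_se(fit, n_boot = 1, seed = 5)
  one_b <- bootstrap_threshold_se(fit, n_boot = 1, seed = 5)
  expect_identical(one_a$bootstrap_se$replicates, one_b$bootstrap_se$replicates)

  boot <- bootstrap_threshold_se(fit, n_boot = 100, seed = 6)
  expect_gt(boot$bootstrap_se$threshold_60, 0)
  expect_gt(boot$bootstrap_se$threshold_50, 0)

  # doubling the per-level trial count shrinks the bootstrap SE (median
  # comparison over a few seeds)
  ses <- vapply(1:3, function(s) {
    d1 <- run_mocs(sim_observer(gen, seed = 40 + s),
                   design_mocs(60, reps_per_level = 15, seed = s))
    d2 <- run_mocs(sim_observer(gen, seed = 80 + s),
                   design_mocs(60, reps_per_level = 30, seed = s))
    f1 <- bootstrap_threshold_se(fit_weibull_ml(d1), n_boot = 60, seed = s)
    f2 <- bootstrap_threshold_se(fit_weibull_ml(d2), n_boot = 60, seed = s)
    c(f1$bootstrap_se$threshold_60, f2$bootstrap_se$threshold_60)
  }, numeric(2))
  expect_lt(median(ses[2, ]), median(ses[1, ]))
})

test_that("bootstrap intervals cover the generating threshold at a sane rate", {
  gen <- weibull_params(62, 9, lapse = 0.04)
  true60 <- threshold_at_accuracy(0.60, gen)
  covered <- vapply(1:20, function(s) {
    dat <- run_mocs(sim_observer(gen, seed = 200 + s),
                    design_mocs(62, reps_per_level = 30, seed = s))
    fit <- bootstrap_threshold_se(fit_weibull_ml(dat), n_boot = 100, seed = s)
    abs(fit$threshold_60 - true60) <= 1.96 * fit$bootstrap_se$threshold_60
  }, logical(1))
  expect_gte(mean(covered), 0.80)
})
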