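test_that("separated step data put the threshold between the flanking directions", {
  props <- data.frame(gaze_deg = c(0, 0.9, 2.2, 5.4, 13.9),
                      n_trials = 25,
                      n_direct = c(25, 25, 25, 0, 0)) # averted beyond 2.2
  fit <- fit_cumulative_gaussian(props)
  expect_gt(fit$threshold, 2.2)
  expect_lt(fit$threshold, 5.4)
  expect_lte(fit$loglik, 0)
})

test_that("cumulative fit agrees with the exhaustive grid oracle on seeded data", {
  d <- exp1_design()
  grid <- list(threshold = seq(0.5, 8, by = 0.1),
               sigma = seq(0.2, 4, by = 0.1))
  for (s in 1:5) {
    obs <- observer_params(criterion = 3.33, psycho_width = 1.5, lapse = 0,
                           seed = 100 + s)
    props <- aggregate_dyadic(simulate_dyadic_constant(obs, d))
    fit <- fit_cumulative_gaussian(props)
    oracle <- grid_fit_oracle(props, grid, model = "cumulative")
    expect_lte(abs(fit$threshold - oracle$best[["threshold"]]), 0.1 + 1e-9)
    expect_lte(abs(fit$sigma - oracle$best[["sigma"]]), 0.1 + 1e-9)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("response inversion leaves the fitted threshold unchanged", {
  obs <- observer_params(criterion = 3.0, psycho_width = 1.2, lapse = 0,
                         seed = 42)
  props <- aggregate_dyadic(simulate_dyadic_constant(obs, exp1_design()))
  fit <- fit_cumulative_gaussian(props)
  # invert every response and negate the axis: "direct" counts become
  # "averted" counts of the mirrored stimulus, so the fitted threshold is
  # the mirror image of the original
  flipped <- data.frame(gaze_deg = -props$gaze_deg,
                        n_trials = props$n_trials,
                        n_direct = props$n_trials - props$n_direct)
  refit <- fit_cumulative_gaussian(flipped)
  expect_equal(refit$threshold, -fit$threshold, tolerance = 1e-4)
  expect_equal(refit$sigma, fit$sigma, tolerance = 1e-4)
})

test_that("all-identical responses are rejected as non-identifiable", {
  props <- data.frame(gaze_deg = c(0, 2, 5), n_trials = 10, n_direct = 10)
  expect_error(fit_cumulative_gaussian(props), "non-identifiable")
  props$n_direct <- 0
  expect_error(fit_cumulative_gaussian(props), "non-identifiable")
  expect_error(
    fit_cumulative_gaussian(data.frame(gaze_deg = c(0, 1), n_trials = 50,
                                       n_direct = c(50, 0))),
    "distinct")
})

test_that("bell fit recovers a two-sided generative observer", {
  d <- linear_stimulus_design(3, 15, 35)
  obs <- observer_params(criterion = 0.1, psycho_width = 1, seed = 77)
  # generative bell: amplitude 0.98, center 0.69, width 3.51
  p <- 0.98 * exp(-(d$directions_deg - 0.69)^2 / (2 * 3.51^2))
  set.seed(31)
  props <- data.frame(gaze_deg = d$directions_deg, n_trials = d$repetitions,
                      n_direct = rbinom(length(p), d$repetitions, p))
  fit <- fit_gaussian_bell(props)
  grid <- list(center = seq(-3, 3, by = 0.1), width = seq(1, 8, by = 0.1),
               amplitude = c(0.9, 0.95, 1))
  oracle <- grid_fit_oracle(props, grid, model = "bell")
  expect_lte(abs(fit$center - oracle$best[["center"]]), 0.1 + 1e-9)
  expect_lte(abs(fit$width - oracle$best[["width"]]), 0.1 + 1e-9)
  expect_equal(fit$center, 0.69, tolerance = 0.75)
  expect_equal(fit$width, 3.51, tolerance = 0.75)
})

test_that("symmetric proportions give a centered bell and width scales with the data", {
  dirs <- seq(-15, 15, by = 3)
  p <- exp(-dirs^2 / (2 * 3.5^2))
  props <- data.frame(gaze_deg = dirs, n_trials = 1000,
                      n_direct = round(1000 * p))
  fit <- fit_gaussian_bell(props)
  expect_equal(fit$center, 0, tolerance = 0.05)
  # doubling the generative width doubles the fitted width (noiseless input)
  p2 <- exp(-dirs^2 / (2 * 7^2))
  props2 <- data.frame(gaze_deg = dirs, n_trials = 1000,
                       n_direct = round(1000 * p2))
  fit2 <- fit_gaussian_bell(props2)
  expect_equal(fit2$width / fit$width, 2, tolerance = 0.05)
})

test_that("flat two-sided data are rejected as non-identifiable", {
  dirs <- seq(-15, 15, by = 3)
  props <- data.frame(gaze_deg = dirs, n_trials = 20, n_direct = 10)
  expect_error(fit_gaussian_bell(props), "non-identifiable")
  one_side <- data.frame(gaze_deg = c(0, 3, 6, 9, 12), n_trials = 20,
                         n_direct = c(18, 12, 6, 2, 1))
  expect_error(fit_gaussian_bell(one_side), "both signs")
})

test_that("grid oracle degenerate and consistency properties hold", {
  props <- data.frame(gaze_deg = c(0, 0.9, 2.2, 5.4, 13.9), n_trials = 25,
                      n_direct = c(24, 20, 12, 3, 0))
  one <- grid_fit_oracle(props, list(threshold = 3, sigma = 1.5))
  expect_equal(unname(one$best["threshold"]), 3)
  expect_equal(nrow(one$surface), 1)
  expect_error(grid_fit_oracle(props, list(threshold = numeric(0), sigma = 1)),
               "grid error")
  # surface is unimodal in threshold at the best sigma for well-behaved data
  surf <- grid_fit_oracle(props, list(threshold = seq(0.5, 8, by = 0.25),
                                      sigma = seq(0.5, 3, by = 0.25)))
  best_sigma <- surf$best[["sigma"]]
  sl <- surf$surface[surf$surface$sigma == best_sigma, ]
  sl <- sl[order(sl$threshold), ]
  sign_changes <- sum(diff(sign(diff(sl$loglik))) != 0)
  expect_lte(sign_changes, 1)
})

test_that("mean recovered threshold tracks the generative criterion across cohorts", {
  recover_mean <- function(criterion, seed) {
    cfg <- cohort_config(n_observers = 6, criterion = c(criterion, 0.5),
                         lapse = 0, master_seed = seed,
                         adjustment = adjustment_plan("one", 1),
                         triadic_repetitions = 1)
    cohort <- simulate_cohort(cfg)
    fits <- fit_cohort_psychometric(cohort$dyadic, "one_sided")
    mean(fits$threshold_deg) - mean(cohort$truth$criterion)
  }
  errs <- vapply(1:4, function(s) recover_mean(3.3, s), numeric(1))
  expect_true(all(abs(errs) < 0.5))
  # shifting the criterion up by 1 degree shifts the recovered mean up too
  up <- vapply(1:4, function(s) {
    cfg_lo <- cohort_config(n_observers = 6, criterion = 3.0, lapse = 0,
                            master_seed = s,
                            adjustment = adjustment_plan("one", 1),
                            triadic_repetitions = 1)
    cfg_hi <- cohort_config(n_observers = 6, criterion = 4.0, lapse = 0,
                            master_seed = s,
                            adjustment = adjustment_plan("one", 1),
                            triadic_repetitions = 1)
    hi <- mean(fit_cohort_psychometric(simulate_cohort(cfg_hi)$dyadic,
                                       "one_sided")$threshold_deg)
    lo <- mean(fit_cohort_psychometric(simulate_cohort(cfg_lo)$dyadic,
                                       "one_sided")$threshold_deg)
    hi - lo
  }, numeric(1))
  expect_true(all(up > 0))
})
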