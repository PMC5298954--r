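test_that("config validation rejects out-of-bound parameters", {
  expect_error(simulation_config(0), "n_subjects")
  expect_error(simulation_config(10, effect_size = 1), "effect_size")
  expect_error(simulation_config(10, zero_inflation = 1), "zero_inflation")
  expect_error(simulation_config(10, choice_consistency = 0.5),
    "choice_consistency")
})

test_that("cohorts respect bounds and are seed-determined", {
  cfg <- simulation_config(n_subjects = 100, seed = 7)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 100)
  expect_true(all(cohort$d_near > 0 & cohort$d_near <= 1))
  expect_true(all(cohort$d_far > 0 & cohort$d_far <= 1))
  expect_true(all(cohort$choice_consistency > 0.5 &
    cohort$choice_consistency <= 1))
  expect_identical(cohort, generate_cohort(cfg))
  # a different seed gives a different cohort
  cfg2 <- simulation_config(n_subjects = 100, seed = 8)
  expect_false(identical(cohort$d_near, generate_cohort(cfg2)$d_near))
})

test_that("d_near matches its Beta distribution mean within 3 SE", {
  cfg <- simulation_config(n_subjects = 5000, seed = 1)
  cohort <- generate_cohort(cfg)
  a <- cfg$d_shape1
  b <- cfg$d_shape2
  mu <- a / (a + b)
  se <- sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(5000)
  expect_lt(abs(mean(cohort$d_near) - mu), 3 * se)
  # nonstationarity is present for most respondents
  expect_gt(mean(cohort$d_far != cohort$d_near), 0.5)
})

test_that("binary choices follow preference with the stated consistency", {
  profile <- data.frame(
    d_near = 0.5, d_far = 0.5, choice_consistency = 1,
    matching_jitter_sd = 0, careless_slip_rate = 0, catch_compliance = 1
  )
  set.seed(1)
  # 0.5 * 100 = 50 > 40: LL strictly preferred, consistency 1
  expect_equal(simulate_binary_choice(profile, 40, 100, "near"), "LL")
  expect_error(simulate_binary_choice(profile, -1, 100, "near"), "positive")

  profile$choice_consistency <- 0.75
  set.seed(2)
  draws <- replicate(10000, simulate_binary_choice(profile, 40, 100, "near"))
  band <- 2.576 * sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(mean(draws == "LL") - 0.75), band)

  # exact indifference: 0.4 * 100 = 40 -> fair coin regardless of consistency
  profile_tie <- profile
  profile_tie$d_far <- 0.4
  set.seed(3)
  ties <- replicate(
    10000,
    simulate_binary_choice(profile_tie, 40, 100, "far")
  )
  expect_lt(abs(mean(ties == "LL") - 0.5), 2.576 * sqrt(0.25 / 10000))
})

test_that("matching responses invert the discount factor with median-1 noise", {
  profile <- data.frame(
    d_near = 0.8, d_far = 0.5, choice_consistency = 1,
    matching_jitter_sd = 0
  )
  expect_equal(simulate_matching_response(profile, 40, "near"), 50)
  expect_equal(simulate_matching_response(profile, 1, "far"), 2)
  profile$matching_jitter_sd <- 0.1
  set.seed(4)
  draws <- replicate(10000, simulate_matching_response(profile, 40, "near"))
  expect_lt(abs(median(draws) / 50 - 1), 0.01)
  expect_true(all(draws > 0))
})

test_that("zero effect size decouples criteria from all latents", {
  cfg <- simulation_config(n_subjects = 2000, effect_size = 0, seed = 5)
  cohort <- generate_cohort(cfg)
  raw <- generate_study1_criteria(cohort, cfg)
  expect_lt(abs(cor(cohort$d_near, raw$tobacco)), 0.06)
  expect_lt(abs(cor(cohort$latent_z, raw$tobacco)), 0.06)
})

test_that("questionnaire answers respect their response formats", {
  cfg <- simulation_config(n_subjects = 1000, effect_size = 0.1, seed = 6)
  cohort <- generate_cohort(cfg)
  raw <- generate_study1_criteria(cohort, cfg)
  expect_true(all(raw$healthy_meals_pct >= 0 & raw$healthy_meals_pct <= 100))
  expect_true(all(raw$savings_pct >= 0 & raw$savings_pct <= 100))
  expect_true(all(raw$height_m > 0))
  expect_true(all(raw$weight_kg > 0))
  expect_true(all(raw$exercise_hours >= 0))
  expect_true(all(raw$tobacco %in% 0:1))
  expect_true(all(is.na(raw$cc_late_fees) == (raw$credit_user == 0)))
  expect_identical(raw, generate_study1_criteria(cohort, cfg))
})

test_that("probit coupling is calibrated on the Efron scale", {
  cfg <- simulation_config(n_subjects = 5000, effect_size = 0.3, seed = 8)
  cohort <- generate_cohort(cfg)
  raw <- generate_study1_criteria(cohort, cfg)
  fit <- fit_model(
    model_spec("binary"),
    cbind(1, cohort$latent_z), raw$tobacco
  )
  r2 <- efron_r2(raw$tobacco, predict(fit, cbind(1, cohort$latent_z)))
  expect_gt(r2, 0.2)
  expect_lt(r2, 0.4)
})

test_that("patience-pair responses are zero-inflated heavy-tailed integers", {
  cfg <- simulation_config(
    n_subjects = 10000, zero_inflation = 0.1, seed = 9
  )
  cohort <- generate_cohort(cfg)
  resp <- generate_study2_responses(cohort, cfg)
  expect_true(all(resp$month_amount >= 0))
  expect_true(all(resp$month_amount == round(resp$month_amount)))
  expect_true(all(resp$year_amount >= 0))
  band <- 2.576 * sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(resp$month_amount == 0) - 0.1), band)
  # heavy right tail: mean far above median among positives
  pos <- resp$month_amount[resp$month_amount > 0]
  expect_gt(mean(pos) / median(pos), 1.5)
  expect_identical(resp, generate_study2_responses(cohort, cfg))
  fam <- attr(resp, "dv_family")
  expect_equal(sum(fam == "binary"), 32)
  expect_equal(sum(fam == "median"), 8)
})

test_that("null simulations reject at the nominal rate", {
  set.seed(13)
  pvals <- replicate(400, {
    cfg <- simulation_config(
      n_subjects = 60, effect_size = 0,
      seed = sample.int(1e6, 1)
    )
    cohort <- generate_cohort(cfg)
    raw <- generate_study1_criteria(cohort, cfg)
    cor.test(cohort$d_near, log1p(raw$exercise_hours))$p.value
  })
  rate <- mean(pvals < 0.05)
  band <- 2.576 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), band)
})
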