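raw_fixture <- function() {
  data.frame(
    exercise_hours = c(0, 5, 12),
    healthy_meals_pct = c(50, 100, 0),
    savings_pct = c(10, 0, 100),
    packs_per_week = c(0, 2, 0),
    weight_kg = c(81, 60, 100),
    height_m = c(1.8, 1.7, 1.75),
    tobacco = c(0, 1, 0),
    gambling_days = c(0, 3, 0),
    floss_per_week = c(3, 8, 0),
    credit_user = c(1, 0, 1),
    cc_late_fees = c(2, NA, 0),
    cc_subpayment_pct = c(0, NA, 40)
  )
}

test_that("the default coding rules reproduce the declared transforms", {
  coded <- apply_coding(raw_fixture(), study1_coding_rules())
  expect_equal(coded$exercise[1], 0) # log(0 + 1)
  expect_equal(coded$exercise[2], log(6))
  # 100% clipped to 0.995 -> logit = log(199)
  expect_equal(coded$healthy_meals[2], log(0.995 / 0.005))
  expect_equal(coded$healthy_meals[2], 5.2933, tolerance = 1e-4)
  # 0% clipped to 0.005 -> -log(199)
  expect_equal(coded$savings[2], -log(199))
  # BMI 81 / 1.8^2 = 25.0 -> overweight (closed at 25)
  expect_equal(coded$overweight[1], 1)
  expect_equal(coded$overweight[2], 0)
  # flossing: 3/week -> middle category; 8 -> daily; 0 -> lowest
  expect_equal(coded$flossing, c(1, 2, 0))
  # credit rules apply only to credit-card users
  expect_equal(coded$cc_late_fees, c(1, NA, 0))
  expect_equal(coded$cc_subpayment, c(0, NA, 1))
  fam <- attr(coded, "dv_family")
  expect_equal(unname(fam["overweight"]), "binary")
  expect_equal(unname(fam["flossing"]), "ordinal")
  expect_equal(sum(fam == "continuous"), 4)
  expect_equal(length(fam), 10)
})

test_that("coded binary and ordinal columns take only their declared values", {
  cfg <- simulation_config(n_subjects = 500, effect_size = 0.1, seed = 3)
  coded <- apply_coding(
    generate_study1_criteria(generate_cohort(cfg), cfg),
    study1_coding_rules()
  )
  fam <- attr(coded, "dv_family")
  for (nm in names(fam)[fam == "binary"]) {
    expect_true(all(coded[[nm]] %in% c(0, 1, NA)), info = nm)
  }
  expect_true(all(coded$flossing %in% 0:2))
})

test_that("out-of-domain answers are flagged, not fatal", {
  raw <- raw_fixture()
  raw$exercise_hours[1] <- -2
  raw$healthy_meals_pct[2] <- 150
  coded <- apply_coding(raw, study1_coding_rules())
  expect_equal(attr(coded, "nonsense"), c(TRUE, TRUE, FALSE))
  expect_true(is.na(coded$exercise[1]))
  expect_true(is.na(coded$healthy_meals[2]))
})

test_that("identity coding is idempotent", {
  rules <- list(coding_rule("tobacco", "tobacco", "identity", "binary"))
  once <- apply_coding(raw_fixture(), rules)
  twice <- apply_coding(as.data.frame(once), rules)
  expect_equal(twice$tobacco, once$tobacco)
})

test_that("clipped_logit bounds are validated", {
  expect_error(
    coding_rule("x", "x", "clipped_logit", "continuous", lo = 0.9, hi = 0.1),
    "0 < lo < hi < 1"
  )
})

test_that("exclusion rules implement the three triggers and the retest rule", {
  subj <- data.frame(
    nonsense_answer = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    catch_failures = c(0, 3, 2, 0, 2),
    matching_errors = c(0, 0, 2, 0, 3),
    session2_minutes = c(6, 10, 2.9, NA, NA)
  )
  rep <- apply_study1_exclusions(subj)
  expect_equal(rep$subjects$excluded_main, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  # below-threshold counts retain the subject
  expect_false(rep$subjects$excluded_main[3])
  # fast session 2 excludes from retest only
  expect_false(rep$subjects$in_retest[3])
  expect_true(rep$subjects$in_retest[1])
  s <- rep$summary
  expect_equal(s$n_excluded_main, 3)
  expect_equal(s$n_main, 2)
  expect_equal(s$n_retest, 1)
  # deduplication: total excluded <= sum of per-reason counts
  expect_lte(s$n_excluded_main, s$n_nonsense + s$n_catch + s$n_matching)
  expect_error(
    apply_study1_exclusions(subj[, -1]), "missing columns"
  )
})

test_that("disjoint reasons make the deduplicated total equal the sum", {
  subj <- data.frame(
    nonsense_answer = c(TRUE, FALSE, FALSE, FALSE),
    catch_failures = c(0, 5, 0, 0),
    matching_errors = c(0, 0, 4, 0),
    session2_minutes = NA_real_
  )
  s <- apply_study1_exclusions(subj)$summary
  expect_equal(s$n_excluded_main, s$n_nonsense + s$n_catch + s$n_matching)
})
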