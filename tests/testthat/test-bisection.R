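test_that("the median-query update splits posterior mass p_c / (1 - p_c)", {
  s <- posterior_state(1024)
  up <- pba_update(s, 0.5, chose_ll = TRUE, p_c = 0.75)
  expect_equal(sum(up$density[up$support > 0.5]), 0.75, tolerance = 1e-12)
  expect_equal(sum(up$density), 1, tolerance = 1e-12)
  # closed form: piecewise-uniform CDF crosses 0.5 at 2/3
  expect_equal(pba_posterior_median(up), 2 / 3, tolerance = 2 / 1023)

  down <- pba_update(s, 0.5, chose_ll = FALSE, p_c = 0.75)
  expect_equal(sum(down$density[down$support <= 0.5]), 0.75,
    tolerance = 1e-12
  )
  # mirror symmetry of the two responses around the query
  expect_equal(rev(down$density), up$density, tolerance = 1e-12)
})

test_that("posterior median is the smallest grid point with half the mass", {
  expect_equal(pba_posterior_median(posterior_state(1024)), 0.5,
    tolerance = 1 / 1023
  )
  grid <- (0:10) / 10
  point <- posterior_state(
    support = grid,
    density = replace(numeric(11), 4, 1) # all mass at 0.3
  )
  expect_equal(pba_posterior_median(point), 0.3)
})

test_that("updates keep the density normalized and warn on degenerate states", {
  set.seed(42)
  s <- posterior_state(256)
  for (i in 1:50) {
    s <- pba_update(s, runif(1, 0.05, 0.95), runif(1) < 0.5, 0.75)
    expect_equal(sum(s$density), 1, tolerance = 1e-12)
    expect_true(all(s$density >= 0))
  }
  point <- posterior_state(
    support = (0:10) / 10,
    density = replace(numeric(11), 4, 1)
  )
  expect_warning(pba_update(point, 0.5, TRUE, 0.75), "uninformative")
})

test_that("mirroring the grid and the response mirrors the posterior", {
  set.seed(7)
  s <- posterior_state(128)
  queries <- runif(10, 0.1, 0.9)
  responses <- runif(10) < 0.5
  a <- s
  b <- s
  for (i in seq_along(queries)) {
    a <- pba_update(a, queries[i], responses[i], 0.75)
  }
  # mirrored run: query at 1 - q (grid is symmetric), flipped response.
  # Strictly mirrored queries fall between different grid points unless the
  # grid is symmetric about 0.5, which the equispaced [0, 1] grid is.
  for (i in seq_along(queries)) {
    b <- pba_update(b, 1 - queries[i] - 1e-12, !responses[i], 0.75)
  }
  expect_equal(rev(b$density), a$density, tolerance = 1e-9)
})

test_that("a truthful noiseless respondent is recovered to within 0.05", {
  set.seed(11)
  for (d in c(0.3, 0.7)) {
    res <- run_bisection_test(truthful_chooser(d), "near")
    expect_lte(abs(res$score - d), 0.05)
    expect_equal(res$catch_failures, 0L)
    expect_equal(nrow(res$trials), 22)
    expect_equal(sum(res$trials$is_catch), 2)
  }
})

test_that("catch trials count dominated choices and never update the posterior", {
  # always-LL respondent: fails only the ratio-1.13 catch (LL dominated)
  set.seed(3)
  res <- run_bisection_test(function(item) "LL", "near")
  expect_equal(res$catch_failures, 1L)
  # always-SS respondent: fails only the ratio-0.07 catch
  set.seed(3)
  res2 <- run_bisection_test(function(item) "SS", "near")
  expect_equal(res2$catch_failures, 1L)
  # catch trials carry no query
  expect_true(all(is.na(res$trials$query_d[res$trials$is_catch])))
})

test_that("a coin-flip respondent produces scores spread around one half", {
  set.seed(19)
  scores <- replicate(200, {
    run_bisection_test(function(item) {
      if (runif(1) < 0.5) "LL" else "SS"
    }, "near")$score
  })
  expect_gt(median(scores), 0.3)
  expect_lt(median(scores), 0.7)
  expect_gt(stats::sd(scores), 0.05) # genuinely spread, not collapsed
})

test_that("the far variant presents one-month versus two-month delays", {
  set.seed(2)
  res <- run_bisection_test(truthful_chooser(0.5), "far")
  expect_true(all(res$trials$ss_delay_days == 30))
  expect_true(all(res$trials$ll_delay_days == 60))
})

test_that("administration errors carry the failing trial", {
  set.seed(1)
  expect_error(
    run_bisection_test(function(item) "maybe", "near"),
    "administration error"
  )
})
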