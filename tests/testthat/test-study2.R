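test_that("the log design has exactly the nine declared columns", {
  expect_equal(
    unname(build_log_design(0, 0)),
    matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 1)
  )
  expect_equal(
    unname(build_log_design(1000, 0)),
    matrix(c(1, log(1000), 0, 0, 1, 0, log(1000), 0, 0), 1),
    tolerance = 1e-12
  )
  expect_equal(unname(build_log_design(1000, 0))[2], 6.9078,
    tolerance = 1e-4
  )
  e <- exp(1)
  expect_equal(
    unname(build_log_design(e, e)),
    matrix(c(1, 1, 1, 0, 0, 1, 0, 0, 0), 1)
  )
  expect_equal(
    colnames(build_log_design(5, 7)),
    c("intercept", "lm", "ly", "zm", "zy", "lm_ly", "lm_zy", "zm_ly", "zm_zy")
  )
  expect_error(build_log_design(-1, 0), "nonnegative")
})

test_that("probit log-model coefficients are recovered from simulated data", {
  set.seed(51)
  n <- 20000
  month <- ifelse(runif(n) < 0.1, 0, round(exp(rnorm(n, 5, 1.2))))
  year <- ifelse(runif(n) < 0.1, 0, round(exp(rnorm(n, 6, 1.2))))
  beta <- c(-0.5, 0.15, -0.1, 0.3, -0.2, 0.01, 0.05, -0.05, 0.1)
  X <- build_log_design(month, year)
  y <- as.numeric(runif(n) < pnorm(drop(X %*% beta)))
  fit <- fit_log_model(month, year, y, "binary")
  co <- fit$fit$coef
  # standard errors from the information matrix of the fitted probit
  eta <- drop(X[, fit$keep, drop = FALSE] %*% co)
  p <- pnorm(eta)
  w <- dnorm(eta)^2 / (p * (1 - p))
  info <- crossprod(X[, fit$keep, drop = FALSE] * w, X[, fit$keep, drop = FALSE])
  se <- sqrt(diag(solve(info)))
  expect_true(all(abs(co - beta[fit$keep]) <= 2.5 * se))
})

test_that("median-loss log model reproduces an exactly linear conditional median", {
  set.seed(52)
  n <- 400
  month <- round(exp(rnorm(n, 5, 1)))
  year <- round(exp(rnorm(n, 6, 1)))
  y <- 3 + 2 * log(month)
  # majority of points exactly on the line, minority shifted up
  y[1:100] <- y[1:100] + rexp(100, 0.1)
  fit <- fit_log_model(month, year, y, "continuous")
  pred <- predict(fit, month, year)
  expect_equal(pred, 3 + 2 * log(month), tolerance = 1e-3)
})

test_that("constant binary criteria are degenerate for the log model", {
  month <- c(10, 20, 30, 40, 0, 5, 100, 7, 90, 11, 13)
  year <- c(0, 25, 35, 45, 5, 50, 10, 70, 9, 120, 17)
  expect_error(
    fit_log_model(month, year, rep(1, 11), "binary"),
    "degenerate"
  )
})

test_that("nominal class construction pools singletons and breaks ties globally", {
  month <- c(10, 10, 10, 5)
  year <- c(20, 20, 20, 5)
  y <- c(1, 1, 0, 0)
  m <- nominal_fit(month, year, y, "binary")
  expect_equal(predict(m, 10, 20), 1) # class mode
  expect_equal(m$n_classes, 2) # (10,20) plus the pooled singleton
  expect_equal(length(m$singleton_keys), 1)

  # within-class tie 1-1 resolved by the global mode
  month2 <- c(1, 1, 2, 2, 3, 3)
  year2 <- c(1, 1, 2, 2, 3, 3)
  y2 <- c(1, 0, 1, 1, 0, 0)
  m2 <- nominal_fit(month2, year2, y2, "binary")
  # global y: three 1s, three 0s -> residual tie -> smaller value 0
  expect_equal(predict(m2, 1, 1), 0)
  y3 <- c(1, 0, 1, 1, 0, 1)
  m3 <- nominal_fit(month2, year2, y3, "binary")
  expect_equal(predict(m3, 1, 1), 1) # global mode is 1

  # continuous classes predict their median
  mc <- nominal_fit(c(1, 1, 1, 9), c(1, 1, 1, 9), c(5, 7, 100, 2),
    "continuous")
  expect_equal(predict(mc, 1, 1), 7)
  # unseen pairs route to the pooled singleton class
  expect_equal(predict(mc, 55, 55), 2)
  # without singletons, unseen pairs get the global fallback
  mn <- nominal_fit(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 3, 5, 7),
    "continuous")
  expect_equal(predict(mn, 55, 55), median(c(1, 3, 5, 7)))
})

test_that("class counts follow the singleton-pooling identity", {
  expect_equal(class_count(c(1, 1, 2, 3), c(5, 5, 6, 7)), 2)
  # 5 distinct pairs, none singleton
  expect_equal(class_count(rep(1:5, each = 2), rep(1:5, each = 2)), 5)
  # all singletons unify into one class
  expect_equal(class_count(1:4, 1:4), 1)
})

test_that("class counts match the identity over every multiset on a 3x3 grid", {
  pairs <- expand.grid(m = 1:3, y = 1:3)
  # enumerate all multisets of sizes 1..6 over the 9 possible pairs
  enumerate <- function(start, remaining, counts, visit) {
    if (remaining == 0) {
      visit(counts)
      return(invisible())
    }
    if (start > 9) {
      return(invisible())
    }
    for (take in 0:remaining) {
      counts[start] <- take
      enumerate(start + 1, remaining - take, counts, visit)
    }
  }
  for (n in 1:6) {
    enumerate(1, n, integer(9), function(counts) {
      idx <- rep(seq_len(9), counts)
      m <- pairs$m[idx]
      y <- pairs$y[idx]
      u <- sum(counts > 0)
      s <- sum(counts == 1)
      expected <- if (s >= 1) u - s + 1 else u
      expect_equal(class_count(m, y), expected)
    })
  }
})

test_that("the exact rank-sum branch reproduces direct enumeration", {
  expect_equal(
    rank_tests(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1), "binary")$p_value,
    0.1
  )
  set.seed(61)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    x <- sample(1:6, n, replace = TRUE) # ties likely
    g <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    got <- rank_tests(x, g, "binary", exact = TRUE)$p_value
    expect_equal(got, ranksum_enumeration_oracle(x, g), tolerance = 1e-12)
  }
})

test_that("exact and normal rank-sum branches agree at n = 8 per group", {
  # exhaustive over every attainable rank-sum of a tie-free sample: the
  # worst-case disagreement between the exact enumeration and the
  # continuity-corrected normal approximation is 0.0110 (at W = 60)
  x <- 1:16
  for (idx in list(1:8, c(1:6, 10, 16), c(1, 3, 5, 7, 9, 11, 13, 15),
    c(2, 3, 4, 8, 11, 12, 14, 16), 9:16)) {
    g <- as.numeric(seq_len(16) %in% idx)
    pe <- rank_tests(x, g, "binary", exact = TRUE)$p_value
    pn <- rank_tests(x, g, "binary", exact = FALSE)$p_value
    expect_lt(abs(pe - pn), 0.011)
  }
})

test_that("the tie-free branches agree with the reference implementation", {
  set.seed(63)
  x <- rnorm(30)
  g <- rep(c(0, 1), 15)
  ours <- rank_tests(x, g, "binary")$p_value
  ref <- wilcox.test(x[g == 1], x[g == 0], exact = FALSE,
    correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
  xs <- rnorm(10)
  gs <- rep(c(0, 1), 5)
  ours_e <- rank_tests(xs, gs, "binary")$p_value
  ref_e <- wilcox.test(xs[gs == 1], xs[gs == 0], exact = TRUE)$p.value
  expect_equal(ours_e, ref_e, tolerance = 1e-10)
})

test_that("rank-sum rejections occur at the nominal rate under the null", {
  set.seed(64)
  p <- replicate(1000, {
    rank_tests(rnorm(40), rep(c(0, 1), 20), "binary")$p_value
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 1000) + 0.005)
})

test_that("the Kendall branch detects a perfect monotone relation", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 8, 7)
  res <- rank_tests(x, x + 0.5, "continuous")
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 0.001)
  expect_error(
    rank_tests(c(1, 2, 3), c(1, 1, 1), "binary"),
    "two levels"
  )
})

test_that("Holm-Bonferroni is a step-down procedure at the declared family size", {
  expect_equal(
    holm_bonferroni(c(0.01, 0.03, 0.04)),
    c(TRUE, FALSE, FALSE)
  )
  expect_equal(holm_bonferroni(rep(1, 5)), rep(FALSE, 5))
  expect_true(holm_bonferroni(0.04))
  # larger declared family than supplied p-values
  expect_false(holm_bonferroni(0.04, m = 2))
  set.seed(65)
  for (i in 1:20) {
    p <- runif(10)
    expect_true(all(holm_bonferroni(p) <= (p <= 0.05)))
  }
})

test_that("a criterion that is a function of the pair is memorized in-sample", {
  set.seed(66)
  month <- sample(c(0, 100, 200, 500), 300, replace = TRUE)
  year <- sample(c(0, 1000, 2000), 300, replace = TRUE)
  y <- as.numeric(month > 100 | year == 0)
  cvs <- data.frame(target = y)
  a <- study2_assess(month, year, cvs,
    dv_family = c(target = "binary"), k = 10, seed = 3
  )
  expect_equal(a$binary$nom_acc_assoc, 1)
  expect_gte(a$binary$nom_acc_assoc, a$binary$log_acc_assoc)
})

test_that("nominal association dominates log association across the property suite", {
  for (seed in 1:5) {
    cfg <- simulation_config(
      n_subjects = 2000, effect_size = 0.03, seed = seed
    )
    cohort <- generate_cohort(cfg)
    resp <- generate_study2_responses(cohort, cfg)
    cols <- c("bin_01", "bin_16", "bin_32", "cont_01", "cont_08")
    a <- study2_assess(
      resp$month_amount, resp$year_amount, resp[cols],
      dv_family = attr(resp, "dv_family")[cols], k = 10, seed = seed
    )
    expect_true(all(a$binary$nom_acc_assoc >= a$binary$log_acc_assoc))
    expect_true(all(a$continuous$nom_mae_assoc <=
      a$continuous$log_mae_assoc + 1e-9))
  }
})

test_that("missing criterion values are dropped case-wise", {
  set.seed(67)
  month <- sample(c(0, 100, 200), 100, replace = TRUE)
  year <- sample(c(0, 500), 100, replace = TRUE)
  y <- as.numeric(runif(100) < 0.5)
  y[1:20] <- NA
  a <- study2_assess(month, year, data.frame(b = y),
    dv_family = c(b = "binary"), k = 5, seed = 1
  )
  expect_equal(a$binary$n, 80)
})
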