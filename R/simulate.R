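#' Configuration for synthetic-respondent simulation
#'
#' Bundles and validates the parameters of the synthetic cohort: how many
#' respondents, how strongly criterion variables couple to the latent
#' patience trait (on the in-sample Efron's-R-squared scale), the
#' zero-inflation and lognormal-tail parameters of the patience-pair
#' responses, and the RNG seed. Behavioral parameters of the respondents
#' themselves (choice consistency, matching jitter, the Beta shape of the
#' discount-factor distribution) are also carried here so a single config
#' determines every downstream table.
#'
#' @param n_subjects Number of respondents (>= 1).
#' @param effect_size Target in-sample Efron's R-squared of a probit
#'   regression of a binary criterion on the latent trait, in `[0, 1)`.
#'   `0` makes all criteria independent of every latent.
#' @param zero_inflation Probability that a patience-pair item is answered
#'   with 0, in `[0, 1)`.
#' @param lognormal_mu,lognormal_sigma Log-scale location and spread of the
#'   positive patience-pair responses (the month item; the year item sits
#'   `year_shift` higher on the log scale).
#' @param seed Integer RNG seed; identical configs give identical output.
#' @param choice_consistency Probability a respondent chooses the option
#'   they truly prefer, in (0.5, 1].
#' @param matching_jitter_sd Log-scale SD of multiplicative noise on
#'   matching responses (>= 0).
#' @param d_shape1,d_shape2 Beta shape parameters of the near discount
#'   factor (defaults give a median near 0.7).
#' @param stationary_fraction Fraction of respondents with `d_far` exactly
#'   equal to `d_near`.
#' @param nonstationary_sd SD of the perturbation applied to `d_far` for
#'   the non-stationary fraction.
#' @param trait_loading Correlation, on the normal scale, between the
#'   latent patience trait and the (transformed) discount factors.
#' @param patience_slope How strongly the log of a patience-pair response
#'   decreases in the latent trait.
#' @param year_shift Log-scale increment of the year item over the month
#'   item.
#' @param nonsense_rate Probability a respondent gives one out-of-domain
#'   questionnaire answer (exercises the exclusion rules).
#' @param careless_fraction Fraction of respondents who are inattentive:
#'   low compliance on catch trials and occasional matching slips below
#'   the SS amount. These are the respondents the exclusion rules are
#'   meant to remove.
#' @param catch_compliance Probability an attentive respondent answers a
#'   catch trial with the non-dominated option. Catch items are obvious
#'   by design, so this is higher than `choice_consistency`, which
#'   describes choices near indifference.
#' @param careless_catch_compliance Catch-trial compliance of careless
#'   respondents.
#' @param careless_slip_rate Per-trial probability that a careless
#'   respondent's matching answer slips below the SS amount.
#' @return A validated list of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(n_subjects = 100, seed = 7)
#' @export
simulation_config <- function(n_subjects,
                              effect_size = 0.03,
                              zero_inflation = 0.05,
                              lognormal_mu = log(150),
                              lognormal_sigma = 1.3,
                              seed = 1L,
                              choice_consistency = 0.75,
                              matching_jitter_sd = 0.1,
                              d_shape1 = 7,
                              d_shape2 = 3,
                              stationary_fraction = 0.1,
                              nonstationary_sd = 0.1,
                              trait_loading = 0.7,
                              patience_slope = 0.5,
                              year_shift = 1.0,
                              nonsense_rate = 0,
                              careless_fraction = 0.05,
                              catch_compliance = 0.97,
                              careless_catch_compliance = 0.55,
                              careless_slip_rate = 0.15) {
  check_number(n_subjects, "n_subjects", lower = 1)
  check_number(effect_size, "effect_size", lower = 0, upper = 1,
               upper_open = TRUE)
  check_number(zero_inflation, "zero_inflation", lower = 0, upper = 1,
               upper_open = TRUE)
  check_number(lognormal_sigma, "lognormal_sigma", lower = 0)
  check_number(seed, "seed")
  check_number(choice_consistency, "choice_consistency",
               lower = 0.5, upper = 1, lower_open = TRUE)
  check_number(matching_jitter_sd, "matching_jitter_sd", lower = 0)
  check_number(d_shape1, "d_shape1", lower = 0, lower_open = TRUE)
  check_number(d_shape2, "d_shape2", lower = 0, lower_open = TRUE)
  check_number(stationary_fraction, "stationary_fraction",
               lower = 0, upper = 1)
  check_number(nonstationary_sd, "nonstationary_sd", lower = 0)
  check_number(trait_loading, "trait_loading", lower = -1, upper = 1)
  check_number(nonsense_rate, "nonsense_rate", lower = 0, upper = 1)
  check_number(careless_fraction, "careless_fraction", lower = 0, upper = 1)
  check_number(catch_compliance, "catch_compliance", lower = 0, upper = 1)
  check_number(careless_catch_compliance, "careless_catch_compliance",
               lower = 0, upper = 1)
  check_number(careless_slip_rate, "careless_slip_rate",
               lower = 0, upper = 1)
  structure(
    list(
      n_subjects = as.integer(n_subjects), effect_size = effect_size,
      zero_inflation = zero_inflation, lognormal_mu = lognormal_mu,
      lognormal_sigma = lognormal_sigma, seed = as.integer(seed),
      choice_consistency = choice_consistency,
      matching_jitter_sd = matching_jitter_sd,
      d_shape1 = d_shape1, d_shape2 = d_shape2,
      stationary_fraction = stationary_fraction,
      nonstationary_sd = nonstationary_sd,
      trait_loading = trait_loading, patience_slope = patience_slope,
      year_shift = year_shift, nonsense_rate = nonsense_rate,
      careless_fraction = careless_fraction,
      catch_compliance = catch_compliance,
      careless_catch_compliance = careless_catch_compliance,
      careless_slip_rate = careless_slip_rate
    ),
    class = "simulation_config"
  )
}

#' Generate a seeded cohort of synthetic respondents
#'
#' Each respondent carries a near discount factor `d_near` (value today of
#' $1 delivered in a month) drawn Beta-shaped on (0, 1], a far discount
#' factor `d_far` under a one-month front-end delay (equal to `d_near` for
#' `stationary_fraction` of subjects, perturbed otherwise), a choice
#' consistency, a matching-response jitter SD, and a standardized latent
#' patience trait `latent_z` that drives the criterion variables. The
#' discount factors are coupled to `latent_z` through a Gaussian copula
#' with correlation `trait_loading`, so test scores and criteria share a
#' weak common cause, the regime the evaluation engine is designed to
#' probe.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `c("respondent_cohort", "data.frame")`
#'   with columns `subject_id`, `d_near`, `d_far`, `choice_consistency`,
#'   `matching_jitter_sd`, `latent_z`. Fully determined by `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_subjects
    z <- stats::rnorm(n)
    rho <- config$trait_loading
    u_near <- stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
    d_near <- stats::qbeta(u_near, config$d_shape1, config$d_shape2)
    d_near <- pmin(pmax(d_near, 1e-4), 1)
    stationary <- stats::runif(n) < config$stationary_fraction
    d_far <- d_near + ifelse(stationary, 0,
      stats::rnorm(n, 0, config$nonstationary_sd))
    d_far <- pmin(pmax(d_far, 1e-4), 1)
    careless <- stats::runif(n) < config$careless_fraction
    out <- data.frame(
      subject_id = sprintf("s%04d", seq_len(n)),
      d_near = d_near,
      d_far = d_far,
      choice_consistency = config$choice_consistency,
      matching_jitter_sd = config$matching_jitter_sd,
      latent_z = z,
      careless = careless,
      catch_compliance = ifelse(careless,
        config$careless_catch_compliance, config$catch_compliance),
      careless_slip_rate = ifelse(careless, config$careless_slip_rate, 0)
    )
    class(out) <- c("respondent_cohort", "data.frame")
    out
  })
}

profile_d <- function(profile, horizon = c("near", "far")) {
  horizon <- match.arg(horizon)
  if (horizon == "near") profile$d_near else profile$d_far
}

#' Simulate one binary intertemporal choice
#'
#' The respondent truly prefers LL iff `d * ll_amount > ss_amount`, with
#' `d` the near or far discount factor per `horizon`; the returned choice
#' equals the preferred option with probability `choice_consistency`.
#' Exact indifference (`d * ll == ss`) is resolved by a fair coin.
#'
#' @param profile One row of a [generate_cohort()] data frame.
#' @param ss_amount,ll_amount Positive dollar amounts.
#' @param horizon `"near"` or `"far"`.
#' @return `"SS"` or `"LL"`.
#' @export
simulate_binary_choice <- function(profile, ss_amount, ll_amount,
                                   horizon = c("near", "far")) {
  if (ss_amount <= 0 || ll_amount <= 0) stopf("amounts must be positive")
  d <- profile_d(profile, horizon)
  v_ll <- d * ll_amount
  preferred <- if (v_ll > ss_amount) {
    "LL"
  } else if (v_ll < ss_amount) {
    "SS"
  } else {
    if (stats::runif(1) < 0.5) "LL" else "SS" # exact indifference: fair coin
  }
  if (stats::runif(1) < profile$choice_consistency) {
    preferred
  } else {
    if (preferred == "LL") "SS" else "LL"
  }
}

#' Simulate one matching (fill-in-the-blank) response
#'
#' A respondent indifferent at discount factor `d` states
#' `ss_amount / d`, perturbed by multiplicative lognormal noise with
#' log-scale SD `matching_jitter_sd` (median multiplier 1) and rounded to
#' cents. Always strictly positive.
#'
#' @inheritParams simulate_binary_choice
#' @return A dollar amount with cent precision.
#' @export
simulate_matching_response <- function(profile, ss_amount,
                                       horizon = c("near", "far")) {
  if (ss_amount <= 0) stopf("ss_amount must be positive")
  d <- profile_d(profile, horizon)
  noise <- exp(stats::rnorm(1, 0, profile$matching_jitter_sd))
  max(0.01, round(ss_amount / d * noise, 2))
}

#' Response callbacks for one synthetic respondent
#'
#' Wires a cohort row into the test administrators: `choice` answers
#' forced-choice items (fixed and bisection tests) via
#' [simulate_binary_choice()], and `matching` answers fill-in items via
#' [simulate_matching_response()]. The horizon is inferred from the
#' item's SS delay (0 days = near).
#'
#' Catch trials are obvious by construction, so they are answered with
#' the respondent's true preference with probability `catch_compliance`
#' rather than `choice_consistency` (which describes choices near
#' indifference). Attentive respondents never state a matching answer
#' below the SS amount — an LL smaller than SS is transparently dominated
#' — while careless respondents slip below it with their per-trial slip
#' rate.
#'
#' @param profile One row of a [generate_cohort()] data frame.
#' @return A list with functions `choice(item)` and `matching(item)`.
#' @export
respondent_callbacks <- function(profile) {
  list(
    choice = function(item) {
      horizon <- if (item$ss_delay_days == 0) "near" else "far"
      if (isTRUE(item$is_catch)) {
        d <- profile_d(profile, horizon)
        preferred <- if (d * item$ll_amount > item$ss_amount) "LL" else "SS"
        comply <- stats::runif(1) < profile$catch_compliance
        if (comply) preferred else setdiff(c("SS", "LL"), preferred)
      } else {
        simulate_binary_choice(profile, item$ss_amount, item$ll_amount,
          horizon)
      }
    },
    matching = function(item) {
      horizon <- if (item$ss_delay_days == 0) "near" else "far"
      ans <- simulate_matching_response(profile, item$ss_amount, horizon)
      if (profile$careless_slip_rate > 0 &&
        stats::runif(1) < profile$careless_slip_rate) {
        round(item$ss_amount * stats::runif(1, 0.5, 0.99), 2)
      } else {
        max(ans, item$ss_amount + 0.01)
      }
    }
  )
}

# Probit loading calibration: find lambda such that a probit of
# y = 1(lambda * z + e > t) on z has asymptotic Efron's R^2 equal to
# `effect_size`, with the threshold t set to hit `base_rate`. Quadrature
# over the standard-normal latent; no simulation involved.
probit_loading <- function(effect_size, base_rate) {
  if (effect_size <= 0) {
    return(0)
  }
  target_r2 <- function(lambda) {
    t0 <- -stats::qnorm(base_rate) * sqrt(1 + lambda^2)
    m2 <- stats::integrate(
      function(z) stats::pnorm(lambda * z - t0)^2 * stats::dnorm(z),
      -Inf, Inf
    )$value
    (m2 - base_rate^2) / (base_rate * (1 - base_rate))
  }
  stats::uniroot(function(l) target_r2(l) - effect_size,
    lower = 1e-6, upper = 25, tol = 1e-8
  )$root
}

# One binary criterion: probit-coupled to the trait z with calibrated
# loading; `sign` < 0 means the behavior is *less* likely for the patient.
coupled_binary <- function(z, effect_size, base_rate, sign = 1) {
  lambda <- probit_loading(effect_size, base_rate)
  t0 <- -stats::qnorm(base_rate) * sqrt(1 + lambda^2)
  as.integer(sign * lambda * z + stats::rnorm(length(z)) > t0)
}

# One continuous latent on the coded (analysis) scale with linear
# R^2 = effect_size against z.
coupled_normal <- function(z, effect_size, sign = 1) {
  sign * sqrt(effect_size) * z + sqrt(1 - effect_size) * stats::rnorm(length(z))
}

#' Generate raw criterion-questionnaire answers for a cohort
#'
#' Produces one row per respondent with every questionnaire field in its
#' stated response format: demographics (sex, age, height in meters,
#' weight in kilograms), tobacco use and packs per week, hours of weekly
#' exercise, percentage of health-conscious meals, weekly flossing count,
#' credit-card use with late-fee counts and subpayment percentages,
#' percentage of income saved, and monthly gambling days. Each behavior is
#' weakly coupled to the cohort's latent patience trait at the configured
#' `effect_size` (probit-calibrated for the dichotomized behaviors); with
#' `effect_size = 0` all answers are independent of every latent.
#'
#' With `nonsense_rate > 0`, a corresponding fraction of respondents give
#' one out-of-domain answer (a negative count or an impossible
#' percentage), which the coding stage flags for exclusion.
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param config The [simulation_config()] used to build the cohort.
#' @return A data frame of raw questionnaire answers, one row per subject.
#' @export
generate_study1_criteria <- function(cohort, config) {
  stopifnot(nrow(cohort) >= 1)
  with_seed(derive_seed(config$seed, 2L), {
    n <- nrow(cohort)
    z <- cohort$latent_z
    es <- config$effect_size

    sex <- ifelse(stats::runif(n) < 0.37, "Female", "Male")
    age <- pmin(pmax(round(stats::rlnorm(n, log(31), 0.28)), 18), 80)
    height_m <- round(stats::rnorm(n, 1.70, 0.10), 2)

    # Overweight: BMI latent coupled negatively (patient -> lower BMI)
    bmi <- 26.5 + 4.5 * coupled_normal(z, es, sign = -1)
    weight_kg <- round(pmax(35, bmi * height_m^2), 1)

    tobacco <- coupled_binary(z, es, base_rate = 0.24, sign = -1)
    packs_raw <- coupled_normal(z, es, sign = -1)
    packs_per_week <- ifelse(tobacco == 1,
      pmax(0, round(exp(1.2 + 0.5 * packs_raw))), 0L)

    exercise_hours <- pmax(0, round(expm1(1.5 + 0.9 *
      coupled_normal(z, es, sign = 1))))
    healthy_meals_pct <- round(100 * stats::plogis(-0.4 + 1.5 *
      coupled_normal(z, es, sign = 1)))
    savings_pct <- round(100 * stats::plogis(-1.6 + 1.4 *
      coupled_normal(z, es, sign = 1)))
    floss_per_week <- pmin(14, pmax(0, round(3 + 3.5 *
      coupled_normal(z, es, sign = 1))))

    gamble_bin <- coupled_binary(z, es, base_rate = 0.17, sign = -1)
    gambling_days <- ifelse(gamble_bin == 1,
      1 + stats::rpois(n, 2), 0L)

    credit_user <- as.integer(stats::runif(n) < 0.80)
    latefee_bin <- coupled_binary(z, es, base_rate = 0.27, sign = -1)
    cc_late_fees <- ifelse(credit_user == 1 & latefee_bin == 1,
      1 + stats::rpois(n, 1.2), 0L)
    cc_late_fees[credit_user == 0] <- NA_integer_
    subpay_bin <- coupled_binary(z, es, base_rate = 0.40, sign = -1)
    cc_subpayment_pct <- ifelse(subpay_bin == 1,
      round(100 * stats::rbeta(n, 2, 2)), 0L)
    cc_subpayment_pct[credit_user == 0] <- NA_integer_

    out <- data.frame(
      subject_id = cohort$subject_id,
      sex = sex, age = age, height_m = height_m, weight_kg = weight_kg,
      tobacco = tobacco, packs_per_week = packs_per_week,
      exercise_hours = exercise_hours,
      healthy_meals_pct = healthy_meals_pct,
      floss_per_week = floss_per_week,
      credit_user = credit_user, cc_late_fees = cc_late_fees,
      cc_subpayment_pct = cc_subpayment_pct,
      savings_pct = savings_pct, gambling_days = gambling_days
    )
    if (config$nonsense_rate > 0) {
      bad <- which(stats::runif(n) < config$nonsense_rate)
      if (length(bad)) {
        # one impossible answer each: negative exercise or >100 percentage
        flip <- stats::runif(length(bad)) < 0.5
        out$exercise_hours[bad[flip]] <- -1L
        out$healthy_meals_pct[bad[!flip]] <- 150L
      }
    }
    out
  })
}

#' Generate patience-pair responses and criterion variables (large-survey style)
#'
#' Emulates the $1000-prize patience items: for each respondent, the
#' smallest extra amount that would convince them to wait one month
#' (`month_amount`) and one year (`year_amount`), each a nonnegative
#' integer with a point mass at 0 (probability `zero_inflation`) and a
#' heavy-tailed lognormal body whose location decreases in the latent
#' patience trait. Positive responses are heaped onto round numbers (one
#' or two significant digits), reproducing the mix of very common response
#' pairs and singletons that the nominal class-based model feeds on.
#'
#' Alongside the pair, 40 criterion columns are generated: 32 binary
#' (`bin_01`..`bin_32`, base rates spread over 0.52--0.95, alternating
#' coupling sign) and 8 continuous (`cont_01`..`cont_08`; heavy-tailed
#' log-scale quantities, two symmetric sleep-style quantities, and one
#' square-root-scale income-style quantity), all coupled to the trait at
#' the configured `effect_size`.
#'
#' @inheritParams generate_study1_criteria
#' @return A data frame with `subject_id`, `month_amount`, `year_amount`,
#'   32 `bin_*` and 8 `cont_*` columns, plus an attribute `dv_family`
#'   naming each criterion column `"binary"` or `"median"` (continuous
#'   criteria are evaluated with median loss).
#' @export
generate_study2_responses <- function(cohort, config) {
  stopifnot(nrow(cohort) >= 1)
  with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(cohort)
    z <- cohort$latent_z
    es <- config$effect_size
    sig <- config$lognormal_sigma

    heap <- function(x) {
      digits <- ifelse(stats::runif(length(x)) < 0.7, 1, 2)
      pmax(1, round(signif(x, digits)))
    }
    shared <- stats::rnorm(n, 0, 0.8 * sig)
    draw_amount <- function(mu) {
      pos <- exp(mu - config$patience_slope * z + shared +
        stats::rnorm(n, 0, 0.6 * sig))
      amt <- heap(pos)
      amt[stats::runif(n) < config$zero_inflation] <- 0L
      as.integer(amt)
    }
    month_amount <- draw_amount(config$lognormal_mu)
    year_amount <- draw_amount(config$lognormal_mu + config$year_shift)

    base_rates <- rep(seq(0.52, 0.95, length.out = 8), 4)
    signs <- rep(c(-1, 1), length.out = 32)
    bins <- vapply(seq_len(32), function(j) {
      coupled_binary(z, es, base_rates[j], signs[j])
    }, integer(n))
    colnames(bins) <- sprintf("bin_%02d", 1:32)

    conts <- matrix(0, n, 8)
    # five heavy-tailed log-scale quantities (minutes of exercise, drinks,
    # dollars of debt, ...)
    for (j in 1:5) {
      conts[, j] <- round(exp(6 + j / 2 + 1.1 *
        coupled_normal(z, es, sign = if (j %% 2) 1 else -1)))
    }
    # two symmetric sleep-style quantities (minutes)
    conts[, 6] <- round(420 + 60 * coupled_normal(z, es, sign = 1))
    conts[, 7] <- round(450 + 70 * coupled_normal(z, es, sign = 1))
    # one sqrt-scale income-style quantity
    conts[, 8] <- round(pmax(0, (230 + 60 *
      coupled_normal(z, es, sign = 1)))^2)
    colnames(conts) <- sprintf("cont_%02d", 1:8)

    out <- data.frame(
      subject_id = cohort$subject_id,
      month_amount = month_amount, year_amount = year_amount,
      bins, conts
    )
    attr(out, "dv_family") <- c(
      stats::setNames(rep("binary", 32), colnames(bins)),
      stats::setNames(rep("median", 8), colnames(conts))
    )
    out
  })
}
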