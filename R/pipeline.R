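#' Administer all six preference tests to a cohort
#'
#' Runs the fixed, bisection, and matching tests, near and far variants,
#' for every respondent of a synthetic cohort, in a per-subject random
#' test order, for the requested rounds. Round-level RNG streams are
#' derived from `seed` so each round is independently reproducible.
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param rounds Integer vector of round numbers to administer.
#' @param seed Integer seed for the administration streams.
#' @param bank Fixed-test item bank.
#' @return A list with `scores` (data frame: `subject_id`, `round`,
#'   `family`, `variant`, `score`), `catch_failures` and
#'   `matching_errors` (data frames per subject and round).
#' @export
administer_tests <- function(cohort, rounds = 1:3, seed = 1L,
                             bank = kirby_medium_bank()) {
  families <- c("fixed", "bisection", "matching")
  variants <- c("near", "far")
  score_rows <- list()
  catch_rows <- list()
  err_rows <- list()
  for (rd in rounds) {
    with_seed(derive_seed(seed, 100L + rd), {
      for (i in seq_len(nrow(cohort))) {
        profile <- cohort[i, ]
        cb <- respondent_callbacks(profile)
        tests <- expand.grid(
          family = families, variant = variants,
          stringsAsFactors = FALSE
        )
        tests <- tests[sample.int(nrow(tests)), ]
        catch <- 0L
        merr <- 0L
        for (j in seq_len(nrow(tests))) {
          fam <- tests$family[j]
          var <- tests$variant[j]
          res <- switch(fam,
            fixed = run_fixed_test(cb$choice, bank, var),
            bisection = run_bisection_test(cb$choice, var),
            matching = run_matching_test(cb$matching, var)
          )
          if (fam == "bisection") catch <- catch + res$catch_failures
          if (fam == "matching") merr <- merr + sum(res$trials$flagged)
          score_rows[[length(score_rows) + 1L]] <- data.frame(
            subject_id = profile$subject_id, round = rd,
            family = fam, variant = var, score = res$score
          )
        }
        catch_rows[[length(catch_rows) + 1L]] <- data.frame(
          subject_id = profile$subject_id, round = rd,
          catch_failures = catch
        )
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          subject_id = profile$subject_id, round = rd,
          matching_errors = merr
        )
      }
    })
  }
  list(
    scores = do.call(rbind, score_rows),
    catch_failures = do.call(rbind, catch_rows),
    matching_errors = do.call(rbind, err_rows)
  )
}

wide_scores <- function(scores, rd) {
  sub <- scores[scores$round == rd, ]
  key <- paste(sub$family, sub$variant, sep = "_")
  ids <- unique(sub$subject_id)
  cols <- unique(key)
  m <- matrix(NA_real_, length(ids), length(cols),
    dimnames = list(ids, cols)
  )
  m[cbind(match(sub$subject_id, ids), match(key, cols))] <- sub$score
  data.frame(subject_id = ids, m, row.names = NULL)
}

#' Run the full small-sample study pipeline
#'
#' End-to-end orchestration: simulates a cohort and its criterion
#' questionnaire, administers all six preference tests in three rounds
#' (rounds 1 and 2 back to back in session 1, round 3 a month later in
#' session 2, with a simulated return rate and session-2 durations),
#' applies the coding and exclusion rules, and produces the
#' report tables: score descriptives, association versus cross-validated
#' predictive accuracy per test family and criterion, self-prediction
#' reliability over both retest intervals, convergent validity,
#' nonstationarity classification counts, and near-to-far
#' cross-prediction. A manifest records the configuration so a bundle can
#' be reproduced bit for bit.
#'
#' @param config A [simulation_config()].
#' @param k_folds Cross-validation folds (reduced, with a warning, to the
#'   sample size when `n < k_folds`).
#' @param return_rate Probability a subject returns for session 2.
#' @param bank Fixed-test item bank.
#' @return A list of class `"study1_report"` with elements `manifest`,
#'   `cohort`, `scores`, `coded`, `exclusions`, `descriptives`,
#'   `assessment`, `reliability`, `convergent`, `nonstationarity`,
#'   `near_to_far`.
#' @export
run_study1_pipeline <- function(config, k_folds = 10, return_rate = 0.52,
                                bank = kirby_medium_bank()) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- generate_cohort(config)
  raw <- generate_study1_criteria(cohort, config)
  admin <- administer_tests(cohort, rounds = 1:3, seed = config$seed,
    bank = bank)

  # session-1 totals (rounds 1 and 2): 8 catch trials, 40 matching trials
  s1 <- admin$catch_failures$round %in% 1:2
  catch1 <- tapply(
    admin$catch_failures$catch_failures[s1],
    admin$catch_failures$subject_id[s1], sum
  )
  m1 <- admin$matching_errors$round %in% 1:2
  merr1 <- tapply(
    admin$matching_errors$matching_errors[m1],
    admin$matching_errors$subject_id[m1], sum
  )

  coded_all <- apply_coding(raw, study1_coding_rules())
  nonsense <- attr(coded_all, "nonsense")

  session2_minutes <- with_seed(derive_seed(config$seed, 200L), {
    returned <- stats::runif(nrow(cohort)) < return_rate
    mins <- round(stats::rlnorm(nrow(cohort), log(6), 0.45), 1)
    ifelse(returned, mins, NA_real_)
  })

  subjects <- data.frame(
    subject_id = cohort$subject_id,
    nonsense_answer = nonsense,
    catch_failures = as.integer(catch1[cohort$subject_id]),
    matching_errors = as.integer(merr1[cohort$subject_id]),
    session2_minutes = session2_minutes
  )
  excl <- apply_study1_exclusions(subjects)
  main <- !excl$subjects$excluded_main
  retest <- excl$subjects$in_retest

  w1 <- wide_scores(admin$scores, 1)
  w2 <- wide_scores(admin$scores, 2)
  w3 <- wide_scores(admin$scores, 3)
  stopifnot(identical(w1$subject_id, cohort$subject_id))

  fams <- c("fixed", "bisection", "matching")
  test_cols <- as.vector(outer(fams, c("near", "far"), paste, sep = "_"))

  descriptives <- do.call(rbind, lapply(test_cols, function(tc) {
    d <- describe_scores(w1[[tc]][main])
    data.frame(test = tc, q1 = d$q1, median = d$median, q3 = d$q3,
      mad = d$mad)
  }))

  # association vs prediction per family x CV
  fam_map <- attr(coded_all, "dv_family")
  k_use <- min(k_folds, sum(main))
  if (k_use < k_folds) {
    warning(sprintf("reducing k_folds to %d for n = %d", k_use, sum(main)),
      call. = FALSE
    )
  }
  assess_rows <- list()
  for (cv in names(fam_map)) {
    y_all <- coded_all[[cv]]
    for (fam in fams) {
      near <- w1[[paste0(fam, "_near")]]
      far <- w1[[paste0(fam, "_far")]]
      keep <- main & !is.na(y_all)
      spec <- model_spec(fam_map[[cv]])
      pa <- assess_prediction(
        spec, design_matrix_study1(near[keep], far[keep]), y_all[keep],
        k = min(k_use, sum(keep)),
        seed = derive_seed(config$seed, 300L + match(cv, names(fam_map)))
      )
      assess_rows[[length(assess_rows) + 1L]] <- data.frame(
        cv = cv, family = fam, dv_family = fam_map[[cv]], n = pa$n,
        association = pa$association, predictive = pa$predictive,
        baseline = pa$baseline, pred_metric = pa$pred_metric,
        higher_is_better = pa$higher_is_better
      )
    }
  }
  assessment <- do.call(rbind, assess_rows)

  rel_rows <- list()
  for (tc in test_cols) {
    r12 <- reliability_report(w1[[tc]][main], w2[[tc]][main])
    r13 <- reliability_report(w1[[tc]][retest], w3[[tc]][retest])
    rel_rows[[length(rel_rows) + 1L]] <- data.frame(
      test = tc, interval = c("round2", "round3"),
      pvaf = c(r12$pvaf, r13$pvaf),
      abs_err_median = c(r12$abs_err_median, r13$abs_err_median),
      abs_err_p90 = c(r12$abs_err_p90, r13$abs_err_p90),
      abs_err_p95 = c(r12$abs_err_p95, r13$abs_err_p95),
      bias = c(r12$bias, r13$bias),
      kendall_tau = c(r12$kendall_tau, r13$kendall_tau),
      pearson_r = c(r12$pearson_r, r13$pearson_r)
    )
  }
  reliability <- do.call(rbind, rel_rows)

  k_max <- 2 * nrow(bank)
  legal <- list(
    fixed = c(0, k_max), bisection = c(0, 1), matching = c(0, 1)
  )
  conv_rows <- list()
  for (a in test_cols) {
    for (b in test_cols) {
      if (a == b) next
      fam_b <- sub("_(near|far)$", "", b)
      conv_rows[[length(conv_rows) + 1L]] <- data.frame(
        predictor = a, target = b,
        pvaf = convergent_validity(
          w1[[a]][main], w1[[b]][main], legal[[fam_b]],
          k = k_use, seed = derive_seed(config$seed, 400L)
        )
      )
    }
  }
  convergent <- do.call(rbind, conv_rows)

  nonstat <- do.call(rbind, lapply(fams, function(fam) {
    cls <- classify_nonstationarity(
      w1[[paste0(fam, "_near")]][main], w1[[paste0(fam, "_far")]][main]
    )
    data.frame(family = fam, t(as.matrix(table(cls))))
  }))

  near_to_far <- do.call(rbind, lapply(fams, function(fam) {
    r <- reliability_report(
      w1[[paste0(fam, "_near")]][main], w2[[paste0(fam, "_far")]][main]
    )
    data.frame(
      family = fam, pvaf = r$pvaf, abs_err_median = r$abs_err_median,
      abs_err_p90 = r$abs_err_p90, abs_err_p95 = r$abs_err_p95,
      bias = r$bias, kendall_tau = r$kendall_tau, pearson_r = r$pearson_r
    )
  }))

  manifest <- list(
    config = unclass(config), k_folds = k_use, return_rate = return_rate,
    n_subjects = nrow(cohort), n_main = sum(main), n_retest = sum(retest),
    stages = c(
      cohort = nrow(cohort), raw = nrow(raw),
      scores = nrow(admin$scores), coded = nrow(coded_all)
    )
  )
  structure(
    list(
      manifest = manifest, cohort = cohort, scores = admin$scores,
      coded = coded_all, exclusions = excl, descriptives = descriptives,
      assessment = assessment, reliability = reliability,
      convergent = convergent, nonstationarity = nonstat,
      near_to_far = near_to_far
    ),
    class = "study1_report"
  )
}

#' Run the full large-survey study pipeline
#'
#' Generates patience-pair responses and 40 criterion variables for a
#' synthetic cohort, runs the nonparametric association tests (rank-sum
#' for binary criteria, Kendall for continuous, two per criterion: month
#' and year) with Holm-Bonferroni correction at the family sizes implied
#' by the criterion counts, and assesses the log and nominal models with
#' [study2_assess()].
#'
#' @param config A [simulation_config()].
#' @param k_folds Cross-validation folds.
#' @param cv_columns Criterion columns to analyze (`NULL` = all; an empty
#'   character vector yields an empty report).
#' @return A list of class `"study2_report"` with elements `manifest`,
#'   `responses`, `class_count`, `tests` (per-test p-values and Holm
#'   flags), `assessment`.
#' @export
run_study2_pipeline <- function(config, k_folds = 10, cv_columns = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- generate_cohort(config)
  responses <- generate_study2_responses(cohort, config)
  fam_map <- attr(responses, "dv_family")
  if (!is.null(cv_columns)) {
    fam_map <- fam_map[names(fam_map) %in% cv_columns]
  }

  if (length(fam_map) == 0L) {
    return(structure(
      list(
        manifest = list(config = unclass(config), n_cvs = 0L),
        responses = responses, class_count = class_count(
          responses$month_amount, responses$year_amount
        ),
        tests = NULL, assessment = NULL
      ),
      class = "study2_report"
    ))
  }

  test_rows <- list()
  for (nm in names(fam_map)) {
    fam <- if (fam_map[[nm]] == "binary") "binary" else "continuous"
    for (item in c("month", "year")) {
      pat <- responses[[paste0(item, "_amount")]]
      res <- tryCatch(
        rank_tests(pat, responses[[nm]], fam),
        error = function(e) list(p_value = NA_real_, statistic = NA_real_,
          method = "failed")
      )
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        cv = nm, item = item, dv_family = fam, p_value = res$p_value,
        statistic = res$statistic, method = res$method
      )
    }
  }
  tests <- do.call(rbind, test_rows)
  tests$holm_reject <- NA
  for (fam in c("binary", "continuous")) {
    idx <- tests$dv_family == fam & !is.na(tests$p_value)
    if (any(idx)) {
      tests$holm_reject[idx] <- holm_bonferroni(
        tests$p_value[idx], alpha = 0.05, m = sum(idx)
      )
    }
  }

  assessment <- study2_assess(
    responses$month_amount, responses$year_amount,
    responses[names(fam_map)],
    dv_family = fam_map, k = k_folds, seed = derive_seed(config$seed, 500L)
  )

  manifest <- list(
    config = unclass(config), k_folds = k_folds,
    n_subjects = nrow(responses), n_cvs = length(fam_map),
    family_sizes = c(
      binary = 2L * sum(fam_map == "binary"),
      continuous = 2L * sum(fam_map != "binary")
    )
  )
  structure(
    list(
      manifest = manifest, responses = responses,
      class_count = class_count(
        responses$month_amount, responses$year_amount
      ),
      tests = tests, assessment = assessment
    ),
    class = "study2_report"
  )
}

#' Write a report bundle to disk
#'
#' Writes each tabular element of a pipeline report as CSV and the
#' manifest as JSON into `dir`.
#'
#' @param report A `"study1_report"` or `"study2_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  elements <- report[!names(report) %in%
    c("manifest", "exclusions", "assessment")]
  if (inherits(report$assessment, "study2_assessment")) {
    elements$assessment_binary <- report$assessment$binary
    elements$assessment_continuous <- report$assessment$continuous
  } else if (!is.null(report$assessment)) {
    elements$assessment <- report$assessment
  }
  if (!is.null(report$exclusions)) {
    elements$exclusions <- report$exclusions$subjects
  }
  for (nm in names(elements)) {
    el <- elements[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(el, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}
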