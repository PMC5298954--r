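#' Criterion-variable coding rules
#'
#' A coding rule maps one or more raw questionnaire fields onto a single
#' analysis-ready dependent variable (DV) and declares its family. The
#' available transforms cover the codings used for the criterion
#' variables: `log1p` (increment by 1 and log), `clipped_logit` (clip a
#' proportion to `[lo, hi]` and logit-transform), `dichotomize`
#' (threshold, with direction `">"` or `">="`), `ordinal` (cut into
#' ordered categories at the given break points), `log_positive_only`
#' (natural log, zero/negative to `NA`), `sqrt`, `identity`, and
#' `bmi_dichotomize` (body mass index from weight in kilograms and height
#' in meters, dichotomized at >= 25, "overweight").
#'
#' @param name Output column name.
#' @param source Raw field name(s) the rule reads.
#' @param transform One of the transform names above.
#' @param dv_family `"continuous"`, `"binary"`, or `"ordinal"`.
#' @param ... Transform parameters: `lo`, `hi` (clipped_logit; require
#'   `0 < lo < hi < 1`), `threshold`, `direction` (dichotomize), `breaks`
#'   (ordinal), `scale` (divide the raw value first, e.g. 100 for
#'   percentages), `subset_field` (apply only where this raw field is 1,
#'   `NA` elsewhere — used for credit-card rules).
#' @return A list of class `"coding_rule"`.
#' @export
coding_rule <- function(name, source,
                        transform = c(
                          "log1p", "clipped_logit", "dichotomize",
                          "ordinal", "log_positive_only", "sqrt",
                          "identity", "bmi_dichotomize"
                        ),
                        dv_family = c("continuous", "binary", "ordinal"),
                        ...) {
  transform <- match.arg(transform)
  dv_family <- match.arg(dv_family)
  params <- list(...)
  if (transform == "clipped_logit") {
    lo <- params$lo %||% 0.005
    hi <- params$hi %||% 0.995
    if (!(0 < lo && lo < hi && hi < 1)) {
      stopf("clipped_logit requires 0 < lo < hi < 1")
    }
    params$lo <- lo
    params$hi <- hi
  }
  structure(
    list(
      name = name, source = source, transform = transform,
      dv_family = dv_family, params = params
    ),
    class = "coding_rule"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default Study-1 coding rules
#'
#' The declarative rule set that turns the raw criterion questionnaire
#' into the coded analysis table: exercise hours incremented by 1 and
#' log-transformed; healthy-meal and savings percentages clipped to
#' `[0.005, 0.995]` and logit-transformed; overweight from BMI (weight /
#' height^2) dichotomized at 25 or more; gambling, credit-card late fees
#' and credit-card subpayments dichotomized at greater than 0 (the two
#' credit rules applied only to credit-card users); tobacco kept as a
#' binary; flossing cut into three ordered categories (0 = less than once
#' per week, 1--6 = less than once per day, 7 or more = at least daily);
#' and packs of cigarettes per week kept as a tenth, continuous,
#' log1p-coded DV.
#'
#' @return A list of [coding_rule()] objects.
#' @export
study1_coding_rules <- function() {
  list(
    coding_rule("exercise", "exercise_hours", "log1p", "continuous"),
    coding_rule("healthy_meals", "healthy_meals_pct", "clipped_logit",
      "continuous", scale = 100),
    coding_rule("savings", "savings_pct", "clipped_logit",
      "continuous", scale = 100),
    coding_rule("packs", "packs_per_week", "log1p", "continuous"),
    coding_rule("overweight", c("weight_kg", "height_m"),
      "bmi_dichotomize", "binary", threshold = 25),
    coding_rule("tobacco", "tobacco", "identity", "binary"),
    coding_rule("gambling", "gambling_days", "dichotomize", "binary",
      threshold = 0, direction = ">"),
    coding_rule("flossing", "floss_per_week", "ordinal", "ordinal",
      breaks = c(1, 7)),
    coding_rule("cc_late_fees", "cc_late_fees", "dichotomize", "binary",
      threshold = 0, direction = ">", subset_field = "credit_user"),
    coding_rule("cc_subpayment", "cc_subpayment_pct", "dichotomize",
      "binary", threshold = 0, direction = ">",
      subset_field = "credit_user")
  )
}

# Domains used to flag out-of-domain ("nonsense") raw answers. Values
# outside these bounds mark the row but never abort coding.
default_domains <- function() {
  list(
    age = c(0, 125), height_m = c(1.2, 2.5), weight_kg = c(30, 300),
    exercise_hours = c(0, 168), healthy_meals_pct = c(0, 100),
    savings_pct = c(0, 100), cc_subpayment_pct = c(0, 100),
    floss_per_week = c(0, Inf), gambling_days = c(0, 31),
    cc_late_fees = c(0, Inf), packs_per_week = c(0, Inf)
  )
}

apply_one_rule <- function(rule, raw) {
  missing_src <- setdiff(rule$source, names(raw))
  if (length(missing_src)) {
    stopf("coding rule '%s': missing source field(s) %s",
      rule$name, paste(missing_src, collapse = ", "))
  }
  p <- rule$params
  if (rule$transform == "bmi_dichotomize") {
    bmi <- raw[[rule$source[1]]] / raw[[rule$source[2]]]^2
    out <- as.numeric(bmi >= (p$threshold %||% 25))
  } else {
    x <- raw[[rule$source[1]]]
    if (!is.numeric(x)) stopf("coding rule '%s': source not numeric", rule$name)
    if (!is.null(p$scale)) x <- x / p$scale
    out <- switch(rule$transform,
      log1p = log1p(x),
      clipped_logit = stats::qlogis(pmin(pmax(x, p$lo), p$hi)),
      dichotomize = {
        dir <- p$direction %||% ">="
        if (dir == ">") as.numeric(x > p$threshold) else
          as.numeric(x >= p$threshold)
      },
      ordinal = {
        findInterval(x, p$breaks)
      },
      log_positive_only = ifelse(x > 0, log(x), NA_real_),
      sqrt = sqrt(pmax(x, 0)),
      identity = as.numeric(x)
    )
  }
  if (!is.null(p$subset_field)) {
    out[raw[[p$subset_field]] != 1] <- NA_real_
  }
  out
}

#' Apply coding rules to a raw criterion table
#'
#' Produces the coded analysis table: one output column per rule, with the
#' declared DV family recorded in the `dv_family` attribute. Raw values
#' outside their declared domain (negative counts, percentages above 100,
#' physiologically impossible heights or weights) do not stop coding; the
#' affected rows are flagged in the logical `nonsense` attribute for the
#' exclusion stage, and the offending coded values are set to `NA`.
#'
#' @param raw Data frame of raw questionnaire answers.
#' @param rules List of [coding_rule()]s, e.g. [study1_coding_rules()].
#' @param domains Named list of `c(lower, upper)` bounds per raw field;
#'   see `default_domains` in the package source for the defaults.
#' @return A data frame of class `c("coded_table", "data.frame")` with
#'   attributes `dv_family` (named character vector) and `nonsense`
#'   (logical, one flag per row).
#' @examples
#' raw <- data.frame(
#'   exercise_hours = c(0, 5), healthy_meals_pct = c(50, 100),
#'   savings_pct = c(10, 0), packs_per_week = c(0, 2),
#'   weight_kg = c(81, 60), height_m = c(1.8, 1.7),
#'   tobacco = c(0, 1), gambling_days = c(0, 3),
#'   floss_per_week = c(3, 8), credit_user = c(1, 0),
#'   cc_late_fees = c(2, NA), cc_subpayment_pct = c(0, NA)
#' )
#' coded <- apply_coding(raw, study1_coding_rules())
#' attr(coded, "dv_family")
#' @export
apply_coding <- function(raw, rules, domains = default_domains()) {
  nonsense <- rep(FALSE, nrow(raw))
  for (field in intersect(names(domains), names(raw))) {
    x <- raw[[field]]
    if (is.numeric(x)) {
      bad <- !is.na(x) & (x < domains[[field]][1] | x > domains[[field]][2])
      if (any(bad)) {
        nonsense <- nonsense | bad
        raw[[field]][bad] <- NA
      }
    }
  }
  cols <- lapply(rules, apply_one_rule, raw = raw)
  out <- as.data.frame(cols, col.names = vapply(rules, `[[`, "", "name"))
  fam <- stats::setNames(
    vapply(rules, `[[`, "", "dv_family"),
    vapply(rules, `[[`, "", "name")
  )
  structure(out,
    dv_family = fam, nonsense = nonsense,
    class = c("coded_table", "data.frame")
  )
}

#' Apply the subject-exclusion rules
#'
#' A subject is excluded from the main analysis sample iff they gave a
#' nonsensical (out-of-domain) questionnaire answer, took the designated
#' incorrect choice in at least `catch_threshold` of the session-1 catch
#' trials, or gave an LL response smaller than SS in at least
#' `matching_threshold` of the session-1 matching trials. The retest
#' sample additionally excludes subjects who completed session 2 in under
#' `min_session2_minutes` minutes (and, of course, those who did not
#' return for session 2).
#'
#' @param subjects Data frame with one row per subject and columns
#'   `nonsense_answer` (logical), `catch_failures` (count over the 8
#'   session-1 catch trials), `matching_errors` (count over the 40
#'   session-1 matching trials), and `session2_minutes` (numeric; `NA` for
#'   subjects who did not complete session 2).
#' @param catch_threshold,matching_threshold,min_session2_minutes Rule
#'   parameters; defaults 3, 3, and 3 minutes.
#' @return An object of class `"exclusion_report"`: the per-subject flag
#'   table plus a `summary` list with per-reason counts, the deduplicated
#'   totals, and the main and retest sample sizes.
#' @examples
#' subj <- data.frame(
#'   nonsense_answer = c(FALSE, TRUE, FALSE),
#'   catch_failures = c(0, 1, 3),
#'   matching_errors = c(2, 0, 0),
#'   session2_minutes = c(6, NA, 10)
#' )
#' apply_study1_exclusions(subj)
#' @export
apply_study1_exclusions <- function(subjects, catch_threshold = 3,
                                    matching_threshold = 3,
                                    min_session2_minutes = 3) {
  needed <- c(
    "nonsense_answer", "catch_failures", "matching_errors",
    "session2_minutes"
  )
  missing_col <- setdiff(needed, names(subjects))
  if (length(missing_col)) {
    stopf("missing columns: %s", paste(missing_col, collapse = ", "))
  }
  flags <- data.frame(
    nonsense = subjects$nonsense_answer,
    catch = subjects$catch_failures >= catch_threshold,
    matching = subjects$matching_errors >= matching_threshold
  )
  excluded_main <- flags$nonsense | flags$catch | flags$matching
  returned <- !is.na(subjects$session2_minutes)
  fast <- returned & subjects$session2_minutes < min_session2_minutes
  in_retest <- returned & !excluded_main & !fast
  report <- cbind(subjects, flags,
    excluded_main = excluded_main,
    fast_session2 = fast, in_retest = in_retest
  )
  summary <- list(
    n = nrow(subjects),
    n_nonsense = sum(flags$nonsense),
    n_catch = sum(flags$catch),
    n_matching = sum(flags$matching),
    n_excluded_main = sum(excluded_main),
    n_main = sum(!excluded_main),
    n_returned = sum(returned),
    n_returned_already_excluded = sum(returned & excluded_main),
    n_fast_session2 = sum(fast & !excluded_main),
    n_retest = sum(in_retest)
  )
  structure(list(subjects = report, summary = summary),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "Exclusion report: %d subjects\n",
      "  nonsense answers: %d, >=3 catch failures: %d, >=3 matching errors: %d\n",
      "  excluded (deduplicated): %d -> main sample %d\n",
      "  returned for session 2: %d (%d already excluded, %d too fast)",
      " -> retest sample %d\n"
    ),
    s$n, s$n_nonsense, s$n_catch, s$n_matching, s$n_excluded_main,
    s$n_main, s$n_returned, s$n_returned_already_excluded,
    s$n_fast_session2, s$n_retest
  ))
  invisible(x)
}
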