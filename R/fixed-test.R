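#' Build the near or far variant of the fixed test
#'
#' The near variant presents the bank items as-is, with the SS reward
#' available today (`ss_delay_days = 0`). The far variant adds a one-month
#' (30-day) front-end delay to both options: the SS delay becomes 30 days
#' and every LL delay is incremented by 30, so the delay gap between the two
#' options is preserved while both recede into the future.
#'
#' @param bank A fixed item bank, e.g. [kirby_medium_bank()].
#' @param variant `"near"` or `"far"`.
#' @return A data frame of presentation items with columns `item_rank`,
#'   `ss_amount`, `ss_delay_days`, `ll_amount`, `ll_delay_days`, `is_catch`.
#' @examples
#' build_fixed_test(kirby_medium_bank(), "far")
#' @export
build_fixed_test <- function(bank, variant = c("near", "far")) {
  variant <- match.arg(variant)
  validate_item_bank(bank)
  shift <- if (variant == "far") 30 else 0
  data.frame(
    item_rank = bank$item_rank,
    ss_amount = bank$ss_amount,
    ss_delay_days = shift,
    ll_amount = bank$ll_amount,
    ll_delay_days = bank$ll_delay_days + shift,
    is_catch = FALSE
  )
}

#' Score a fixed-test response pattern by its most consistent rank
#'
#' Rather than estimating a discount rate, the fixed test is scored by the
#' candidate indifference rank that is most consistent with the observed
#' choices. Candidate rank r (r = 1, ..., K+1) predicts LL choices on
#' exactly the r - 1 highest-ranked items (the items demanding the least
#' patience) and SS on the rest; its consistency is the number of observed
#' choices the prediction matches. The score is an affine transform of the
#' best rank, by default `2 * rank - 2`, so that all-SS scores 0 and greater
#' scores imply greater patience. When several ranks tie for maximal
#' consistency the arithmetic mean of the tied ranks is used, which is why
#' occasional non-integer scores arise.
#'
#' @param choices Character vector of `"SS"`/`"LL"`, one per bank item, in
#'   rank order.
#' @param bank The item bank the choices answer.
#' @param transform Length-2 numeric `c(a, b)`: score = `a * rank + b`.
#' @return A scalar score, in `[0, a * (K + 1) + b]` for the default
#'   transform `[0, 2K]`.
#' @examples
#' score_fixed(rep("SS", 7), kirby_medium_bank()) # 0: minimal patience
#' score_fixed(rep("LL", 7), kirby_medium_bank()) # 14: maximal patience
#' @export
score_fixed <- function(choices, bank, transform = c(2, -2)) {
  validate_item_bank(bank)
  k <- nrow(bank)
  if (length(choices) != k || anyNA(choices)) {
    stopf("need one non-missing choice per item (%d)", k)
  }
  if (!all(choices %in% c("SS", "LL"))) {
    stopf("choices must be \"SS\" or \"LL\"")
  }
  chose_ll <- choices == "LL"
  # candidate r predicts LL on the r-1 highest ranks: ranks > k - (r - 1)
  consistency <- vapply(1:(k + 1), function(r) {
    predicted_ll <- bank$item_rank > k - (r - 1)
    sum(predicted_ll == chose_ll)
  }, numeric(1))
  best <- which(consistency == max(consistency))
  rank <- mean(best)
  transform[1] * rank + transform[2]
}

#' Administer a fixed test against a response callback
#'
#' Presents each item of the requested variant to `respond` and scores the
#' resulting pattern with [score_fixed()].
#'
#' @param respond A function taking one presentation item (a one-row data
#'   frame) and returning `"SS"` or `"LL"`.
#' @inheritParams build_fixed_test
#' @inheritParams score_fixed
#' @return A [test_result] object with `family = "fixed"`.
#' @export
run_fixed_test <- function(respond, bank = kirby_medium_bank(),
                           variant = c("near", "far"), transform = c(2, -2)) {
  variant <- match.arg(variant)
  items <- build_fixed_test(bank, variant)
  choices <- character(nrow(items))
  for (i in seq_len(nrow(items))) {
    choices[i] <- respond(items[i, , drop = FALSE])
  }
  trials <- cbind(items, choice = choices)
  test_result(
    family = "fixed", variant = variant,
    score = score_fixed(choices, bank, transform),
    trials = trials, catch_failures = 0L
  )
}

#' Test-administration results
#'
#' Container for one administration of a preference test: the family and
#' variant, the scalar score (scored so that greater values mean greater
#' patience), the per-trial log, and the number of failed catch trials.
#'
#' @param family `"fixed"`, `"bisection"`, or `"matching"`.
#' @param variant `"near"` or `"far"`.
#' @param score Scalar test score.
#' @param trials Data frame, one row per presented trial.
#' @param catch_failures Count of catch trials answered with the dominated
#'   option.
#' @return An object of class `"test_result"`.
#' @export
test_result <- function(family, variant, score, trials,
                        catch_failures = 0L) {
  structure(
    list(
      family = family, variant = variant, score = score,
      trials = trials, catch_failures = as.integer(catch_failures)
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf(
    "<%s test, %s variant>  score = %.4g  (%d trials, %d catch failures)\n",
    x$family, x$variant, x$score, nrow(x$trials), x$catch_failures
  ))
  invisible(x)
}
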