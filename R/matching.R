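#' Administer the free-response matching test
#'
#' In each trial the SS reward amount is drawn uniformly from $1--$95 and
#' the respondent fills in the LL amount that would make them indifferent
#' between the two options (up to 1-cent precision). Trials in which the
#' stated LL amount is smaller than the SS amount are flagged as errors —
#' an LL smaller than SS makes the later option dominated — but still enter
#' scoring; the flags feed the subject-exclusion rules.
#'
#' @param respond Function taking a presentation item (named list or one-row
#'   data frame; fields `ss_amount`, `ss_delay_days`, `ll_delay_days`) and returning a
#'   positive dollar amount.
#' @param variant `"near"` (today vs. 1 month) or `"far"` (1 month vs. 2
#'   months).
#' @param n_trials Number of trials (default 10).
#' @return A [test_result] with `family = "matching"`; `score` is the
#'   median SS/LL ratio (a discount factor in `[0, 1]` for error-free
#'   responding). The trial log has columns `ss`, `ll`, `flagged`.
#' @export
run_matching_test <- function(respond, variant = c("near", "far"),
                              n_trials = 10) {
  variant <- match.arg(variant)
  check_number(n_trials, "n_trials", lower = 1)
  delays <- bisection_delays(variant)
  ss <- sample(1:95, n_trials, replace = TRUE)
  ll <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    item <- list(
      ss_amount = ss[i], ss_delay_days = delays[["ss"]],
      ll_delay_days = delays[["ll"]]
    )
    ans <- respond(item)
    if (!is.numeric(ans) || length(ans) != 1L || !is.finite(ans) || ans <= 0) {
      stopf("matching administration error at trial %d: response must be a positive amount", i)
    }
    ll[i] <- round(ans, 2) # cent precision
  }
  trials <- data.frame(
    trial = seq_len(n_trials), ss_amount = ss, ll_amount = ll,
    ss_delay_days = delays[["ss"]], ll_delay_days = delays[["ll"]],
    flagged = ll < ss
  )
  res <- test_result(
    family = "matching", variant = variant, score = NA_real_,
    trials = trials
  )
  res$score <- score_matching(res)
  res
}

#' Score a matching test
#'
#' The score is the median of the per-trial SS/LL amount ratios. With an
#' even number of trials the midpoint of the two central order statistics
#' is used. Flagged trials (LL < SS) are included; they simply contribute a
#' ratio above 1.
#'
#' @param result A matching [test_result] (or any object with a `trials`
#'   data frame holding `ss_amount` and `ll_amount`).
#' @return The median SS/LL ratio.
#' @export
score_matching <- function(result) {
  trials <- result$trials
  if (is.null(trials) || nrow(trials) < 1L) stopf("no trials to score")
  stats::median(trials$ss_amount / trials$ll_amount)
}
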