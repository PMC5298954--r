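#' Reliability as self-prediction
#'
#' Assesses how well one set of scores predicts another *without a
#' statistical model*: the predictor scores are used unaltered as
#' predictions of the target scores, so no cross-validation is needed and
#' bias is penalized (unlike a correlation). Reports the proportion of
#' variance accounted for (PVAF, `1 - MSE / var(target)`, population
#' variance), the median, 90th and 95th percentiles of the absolute
#' error, the bias (mean of target minus predictor), Kendall's tau-b, and
#' Pearson's r.
#'
#' @param predictor_scores Scores used as predictions (e.g., round 1).
#' @param target_scores Scores being predicted (e.g., round 2), on the
#'   same scale.
#' @return An object of class `"reliability_report"`: a list with `pvaf`,
#'   `abs_err_median`, `abs_err_p90`, `abs_err_p95`, `bias`,
#'   `kendall_tau`, `pearson_r`, `n`. `pvaf` is `NA` (with a warning) for
#'   a zero-variance target; the other fields are still returned.
#' @examples
#' r1 <- c(0.7, 0.5, 0.9, 0.4)
#' reliability_report(r1, r1 + 0.1)
#' @export
reliability_report <- function(predictor_scores, target_scores) {
  if (length(predictor_scores) != length(target_scores)) {
    stopf("paired scores required")
  }
  if (length(target_scores) == 0L) {
    warning("no paired scores: empty reliability report", call. = FALSE)
    na <- NA_real_
    return(structure(
      list(
        pvaf = na, abs_err_median = na, abs_err_p90 = na,
        abs_err_p95 = na, bias = na, kendall_tau = na, pearson_r = na,
        n = 0L
      ),
      class = "reliability_report"
    ))
  }
  t <- target_scores
  p <- predictor_scores
  err <- abs(t - p)
  v <- mean((t - mean(t))^2)
  pvaf <- if (v == 0) {
    warning("zero-variance target: PVAF undefined", call. = FALSE)
    NA_real_
  } else {
    1 - mean((t - p)^2) / v
  }
  q <- stats::quantile(err, c(0.5, 0.9, 0.95), names = FALSE, type = 7)
  structure(
    list(
      pvaf = pvaf,
      abs_err_median = q[1], abs_err_p90 = q[2], abs_err_p95 = q[3],
      bias = mean(t - p),
      kendall_tau = suppressWarnings(stats::cor(p, t, method = "kendall")),
      pearson_r = suppressWarnings(stats::cor(p, t)),
      n = length(t)
    ),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Self-prediction reliability (n = %d)\n",
      "  PVAF %.2f | abs err median %.3g, p90 %.3g, p95 %.3g\n",
      "  bias %+.3g | Kendall tau %.2f | Pearson r %.2f\n"
    ),
    x$n, x$pvaf, x$abs_err_median, x$abs_err_p90, x$abs_err_p95,
    x$bias, x$kendall_tau, x$pearson_r
  ))
  invisible(x)
}

#' Convert a correlation to a proportion of variance accounted for
#'
#' For comparing correlation-based reports with PVAF-based ones: an
#' unbiased linear predictor with correlation r accounts for r^2 of the
#' target's variance (e.g., r = 0.75 corresponds to PVAF 0.56 and
#' r = 0.33 to PVAF 0.11).
#'
#' @param r Correlation coefficient(s).
#' @return `r^2`.
#' @export
pvaf_from_correlation <- function(r) {
  if (any(abs(r) > 1)) stopf("correlations must lie in [-1, 1]")
  r^2
}

#' Classify nonstationarity from near and far scores
#'
#' Greater patience on the far test than the near test is classical
#' nonstationarity — the agent plans to be more patient in the future than
#' the present; the reverse is planning to be less patient later; equal
#' scores are perfect stationarity.
#'
#' @param near_score,far_score Scores from the near and far variants of
#'   the *same* test family (same scale).
#' @return A factor with levels `less_patient_later`, `stationary`,
#'   `more_patient_later`, one value per score pair.
#' @examples
#' classify_nonstationarity(c(0.7, 0.7, 0.8), c(0.8, 0.7, 0.7))
#' @export
classify_nonstationarity <- function(near_score, far_score) {
  if (length(near_score) != length(far_score)) stopf("paired scores required")
  factor(
    ifelse(far_score > near_score, "more_patient_later",
      ifelse(far_score < near_score, "less_patient_later", "stationary")
    ),
    levels = c("less_patient_later", "stationary", "more_patient_later")
  )
}

#' Descriptive statistics for test scores
#'
#' Quartiles (linear-interpolation convention, R's default type 7) and a
#' dispersion statistic. The default dispersion is the median absolute
#' deviation from the median (unscaled); `mad_type = "mean"` gives the
#' mean absolute deviation from the median instead, the baseline used in
#' the absolute-error analyses.
#'
#' @param scores Numeric vector.
#' @param mad_type `"median"` or `"mean"` absolute deviation from the
#'   median.
#' @return A list with `q1`, `median`, `q3`, `mad`.
#' @examples
#' describe_scores(1:7) # median 4, MAD 2
#' @export
describe_scores <- function(scores, mad_type = c("median", "mean")) {
  mad_type <- match.arg(mad_type)
  if (!length(scores)) stopf("scores must be nonempty")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  dev <- abs(scores - q[2])
  list(
    q1 = q[1], median = q[2], q3 = q[3],
    mad = if (mad_type == "median") stats::median(dev) else mean(dev)
  )
}
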