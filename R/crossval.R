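# Balanced, unstratified, seeded fold assignment.
kfold_assign <- function(n, k, seed = NULL) {
  if (k < 2) stopf("k_folds must be >= 2")
  if (n < k) stopf("need at least k cases")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Out-of-fold predictions by k-fold cross-validation
#'
#' Splits the cases into `k` balanced folds (sizes differing by at most
#' one, unstratified, determined by `seed`), and predicts each case
#' exactly once from a model trained on the other folds. A training fold
#' whose response is degenerate (e.g., one class only) or whose fit fails
#' falls back to an intercept-only model; the number of such folds is
#' recorded in the `"fallback_folds"` attribute.
#'
#' @inheritParams fit_model
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Out-of-fold predictions: a vector (probabilities for binary,
#'   values for continuous/median) or a category-probability matrix
#'   (ordinal).
#' @export
kfold_predict <- function(spec, X, y, k = 10, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- kfold_assign(n, k, seed)
  fam <- spec$dv_family
  levels <- if (fam == "ordinal") sort(unique(y)) else NULL
  out <- if (fam == "ordinal") {
    matrix(NA_real_, n, length(levels), dimnames = list(NULL, levels))
  } else {
    rep(NA_real_, n)
  }
  fallbacks <- 0L
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- tryCatch(
      fit_model(spec, X[!test, , drop = FALSE], y[!test]),
      error = function(e) NULL
    )
    if (is.null(fit) ||
      (fam == "ordinal" && !identical(fit$levels, levels))) {
      fit <- fallback_fit(spec, y[!test])
      if (fam == "ordinal") {
        # align fallback categories with the full response's levels
        probs <- as.numeric(table(factor(y[!test], levels = levels))) /
          sum(!test)
        fit$levels <- levels
        fit$probs <- probs
      }
      fallbacks <- fallbacks + 1L
    }
    pred <- predict(fit, X[test, , drop = FALSE])
    if (fam == "ordinal") out[test, ] <- pred else out[test] <- pred
  }
  attr(out, "fallback_folds") <- fallbacks
  out
}

classify_binary <- function(p) as.numeric(p >= 0.5)

classify_ordinal <- function(probs) {
  levels <- as.numeric(colnames(probs))
  levels[max.col(probs, ties.method = "first")]
}

#' Association versus cross-validated predictive accuracy
#'
#' The core contrast of the evaluation engine. For one DV, fits the model
#' in-sample to measure *association* (R-squared for continuous DVs,
#' Efron's R-squared for binary DVs, an Efron-style statistic on the
#' expected category index for ordinal DVs, in-sample mean absolute error
#' for median-loss DVs) and runs tenfold cross-validation to measure
#' *predictive accuracy* (out-of-fold RMSE, proportion of correct class
#' predictions, or out-of-fold MAE). The *baseline* is what a
#' predictor-free guess achieves: the population SD of the DV, the modal
#' class's base rate, or the mean absolute deviation from the median.
#'
#' @inheritParams kfold_predict
#' @return An object of class `"prediction_assessment"`: a list with
#'   `association`, `predictive`, `baseline`, `assoc_metric`,
#'   `pred_metric`, `higher_is_better` (whether larger predictive values
#'   beat the baseline), `n`, `k_folds`, `seed`, `fallback_folds`.
#' @export
assess_prediction <- function(spec, X, y, k = 10, seed = NULL) {
  X <- as.matrix(X)
  fam <- spec$dv_family
  fit <- tryCatch(fit_model(spec, X, y), error = function(e) {
    fallback_fit(spec, y)
  })
  in_pred <- predict(fit, X)
  oof <- kfold_predict(spec, X, y, k = k, seed = seed)
  res <- switch(fam,
    continuous = list(
      association = if (stats::var(y) == 0) NA_real_ else
        1 - sum((y - in_pred)^2) / sum((y - mean(y))^2),
      predictive = sqrt(mean((y - oof)^2)),
      baseline = sqrt(mean((y - mean(y))^2)),
      assoc_metric = "r_squared", pred_metric = "rmse",
      higher_is_better = FALSE
    ),
    binary = list(
      association = if (stats::var(y) == 0) NA_real_ else
        efron_r2(y, in_pred),
      predictive = mean(classify_binary(oof) == y),
      baseline = max(mean(y), 1 - mean(y)),
      assoc_metric = "efron_r2", pred_metric = "prop_correct",
      higher_is_better = TRUE
    ),
    ordinal = {
      idx <- as.numeric(y)
      exp_idx <- if (isTRUE(fit$fallback)) {
        rep(sum(fit$probs * fit$levels), length(y))
      } else {
        drop(in_pred %*% as.numeric(colnames(in_pred)))
      }
      list(
        association = if (stats::var(idx) == 0) NA_real_ else
          1 - sum((idx - exp_idx)^2) / sum((idx - mean(idx))^2),
        predictive = mean(classify_ordinal(oof) == y),
        baseline = max(table(y)) / length(y),
        assoc_metric = "efron_r2_expected_index",
        pred_metric = "prop_correct", higher_is_better = TRUE
      )
    },
    median = list(
      association = mean(abs(y - in_pred)),
      predictive = mean(abs(y - oof)),
      baseline = mean(abs(y - stats::median(y))),
      assoc_metric = "mae_insample", pred_metric = "mae",
      higher_is_better = FALSE
    )
  )
  structure(
    c(res, list(
      n = length(y), k_folds = k, seed = seed,
      fallback_folds = attr(oof, "fallback_folds"), dv_family = fam
    )),
    class = "prediction_assessment"
  )
}

#' @export
print.prediction_assessment <- function(x, ...) {
  cat(sprintf(
    "<%s DV, n = %d, %d-fold CV>\n  association (%s): %.4f\n  predictive (%s): %.4f  vs baseline %.4f\n",
    x$dv_family, x$n, x$k_folds, x$assoc_metric, x$association,
    x$pred_metric, x$predictive, x$baseline
  ))
  invisible(x)
}

#' Convergent validity by clipped cross-validated mutual prediction
#'
#' Predicts score `b` from score `a` with tenfold cross-validated simple
#' linear regression, clips the out-of-fold predictions to the legal range
#' of the DV, and reports the proportion of variance accounted for
#' (PVAF) of the clipped predictions.
#'
#' @param scores_a Predictor scores.
#' @param scores_b Target scores (the DV).
#' @param legal_range Length-2 numeric range predictions are clipped to.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @return The PVAF (at most 1; negative when mutual prediction is worse
#'   than guessing the mean).
#' @export
convergent_validity <- function(scores_a, scores_b, legal_range = c(0, 1),
                                k = 10, seed = NULL) {
  if (length(scores_a) != length(scores_b)) stopf("paired scores required")
  X <- cbind(intercept = 1, a = scores_a)
  oof <- kfold_predict(model_spec("continuous"), X, scores_b,
    k = k, seed = seed
  )
  clipped <- pmin(pmax(oof, legal_range[1]), legal_range[2])
  pvaf_stat(scores_b, clipped)
}
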