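#' Nine-term log design for patience-pair responses
#'
#' Builds the design matrix of the "log model" for a pair of nonnegative
#' integer patience responses (the extra dollars demanded to wait a month
#' and a year for a $1000 prize): an intercept, the natural logarithms of
#' the two responses, dummy variables for responses of exactly 0, and all
#' non-trivial one-way interactions. A log term is set to 0 when its
#' response is 0 (the zero dummy carries that information), which makes
#' the two within-item products log x zero identically 0; excluding them
#' leaves 9 columns.
#'
#' @param month_amount,year_amount Nonnegative integer vectors.
#' @return An n-by-9 matrix with columns `intercept`, `lm`, `ly`, `zm`,
#'   `zy`, `lm_ly`, `lm_zy`, `zm_ly`, `zm_zy`.
#' @examples
#' build_log_design(0, 0)
#' build_log_design(1000, 0)
#' @export
build_log_design <- function(month_amount, year_amount) {
  if (length(month_amount) != length(year_amount)) {
    stopf("month and year responses must be paired")
  }
  ok <- function(x) all(is.finite(x) & x >= 0)
  if (!ok(month_amount) || !ok(year_amount)) {
    stopf("patience responses must be nonnegative")
  }
  lm_ <- ifelse(month_amount > 0, log(month_amount), 0)
  ly_ <- ifelse(year_amount > 0, log(year_amount), 0)
  zm <- as.numeric(month_amount == 0)
  zy <- as.numeric(year_amount == 0)
  cbind(
    intercept = 1, lm = lm_, ly = ly_, zm = zm, zy = zy,
    lm_ly = lm_ * ly_, lm_zy = lm_ * zy, zm_ly = zm * ly_, zm_zy = zm * zy
  )
}

#' Fit the log model for a criterion variable
#'
#' Probit regression (binary criteria) or median regression (continuous
#' criteria, quantile-0.5 loss) of the criterion on the nine-term
#' [build_log_design()] of the patience pair. Columns that are constant in
#' the training data (e.g., a zero dummy when no response is 0) are
#' dropped before fitting and handled transparently at prediction time.
#'
#' @param month_amount,year_amount Nonnegative integer patience responses.
#' @param y The criterion: 0/1 for `dv_family = "binary"`, numeric for
#'   `"continuous"`.
#' @param dv_family `"binary"` or `"continuous"`.
#' @return A list of class `"log_model"` with the underlying `"tp_model"`
#'   and the retained columns; use `predict()` with new response pairs.
#' @export
fit_log_model <- function(month_amount, year_amount, y,
                          dv_family = c("binary", "continuous")) {
  dv_family <- match.arg(dv_family)
  X <- build_log_design(month_amount, year_amount)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col) {
    stats::var(col) > 0
  }))
  # drop collinear columns beyond constants
  Xk <- X[, keep, drop = FALSE]
  q <- qr(Xk)
  if (q$rank < ncol(Xk)) {
    drop_idx <- q$pivot[-seq_len(q$rank)]
    keep[which(keep)[drop_idx]] <- FALSE
    Xk <- X[, keep, drop = FALSE]
  }
  spec <- model_spec(if (dv_family == "binary") "binary" else "median")
  fit <- fit_model(spec, Xk, y)
  structure(list(fit = fit, keep = keep, dv_family = dv_family),
    class = "log_model"
  )
}

#' @export
predict.log_model <- function(object, month_amount, year_amount, ...) {
  X <- build_log_design(month_amount, year_amount)
  predict(object$fit, X[, object$keep, drop = FALSE])
}

pair_key <- function(month_amount, year_amount) {
  paste(month_amount, year_amount, sep = ":")
}

#' Count nominal-model classes for a set of response pairs
#'
#' Every distinct (month, year) response pair is a class, except that all
#' singleton pairs (pairs given by exactly one respondent) are unified
#' into a single class. With u distinct pairs of which s >= 1 are
#' singletons the count is u - s + 1; with no singletons it is u.
#'
#' @inheritParams build_log_design
#' @return Integer class count.
#' @examples
#' class_count(c(1, 1, 2, 3), c(5, 5, 6, 7)) # (1,5) x2 + 2 singletons -> 2
#' @export
class_count <- function(month_amount, year_amount) {
  tab <- table(pair_key(month_amount, year_amount))
  u <- length(tab)
  s <- sum(tab == 1L)
  if (s >= 1L) u - s + 1L else u
}

#' Fit the nominal (class-based) model
#'
#' The most flexible model possible on the patience pair: each distinct
#' training pair is a class (singleton pairs unified into one class), and
#' the class predicts the most common criterion value among its training
#' members (binary; ties broken by the most common value in all the
#' training data, with a residual tie going to the smaller value) or the
#' class median (continuous). Pairs unseen in training are routed to the
#' unified singleton class when one exists — it is the model's pool of
#' rare responses — and otherwise to the global modal value / median.
#'
#' @inheritParams fit_log_model
#' @return A list of class `"nominal_model"`; predict with new pairs via
#'   `predict()`.
#' @export
nominal_fit <- function(month_amount, year_amount, y,
                        dv_family = c("binary", "continuous")) {
  dv_family <- match.arg(dv_family)
  if (!length(y)) stopf("empty training set")
  key <- pair_key(month_amount, year_amount)
  dt <- data.table::data.table(pkey = key, y = y)
  cnt <- dt[, list(n = .N), by = "pkey"]
  singleton_keys <- cnt$pkey[cnt$n == 1L]
  dt[, "cls" := ifelse(pkey %chin% singleton_keys, ".singleton", pkey)]
  class_prob <- NULL
  if (dv_family == "binary") {
    if (!all(y %in% c(0, 1))) stopf("binary y must be 0/1")
    # global mode; residual global tie broken to the smaller value
    global_pred <- as.numeric(sum(y) * 2 > length(y))
    agg <- dt[, list(s = sum(y), n = .N), by = "cls"]
    pred <- ifelse(agg$s * 2 > agg$n, 1,
      ifelse(agg$s * 2 < agg$n, 0, global_pred))
    class_pred <- stats::setNames(pred, agg$cls)
    class_prob <- stats::setNames(agg$s / agg$n, agg$cls)
  } else {
    global_pred <- stats::median(y)
    agg <- dt[, list(pred = stats::median(y)), by = "cls"]
    class_pred <- stats::setNames(agg$pred, agg$cls)
  }
  structure(
    list(
      class_pred = class_pred,
      class_prob = class_prob,
      singleton_keys = singleton_keys,
      has_singletons = length(singleton_keys) > 0L,
      global_pred = global_pred,
      dv_family = dv_family,
      n_classes = length(class_pred)
    ),
    class = "nominal_model"
  )
}

#' @export
predict.nominal_model <- function(object, month_amount, year_amount, ...) {
  nominal_lookup(object, month_amount, year_amount, object$class_pred,
    if (object$has_singletons) {
      object$class_pred[[".singleton"]]
    } else {
      object$global_pred
    }
  )
}

nominal_lookup <- function(object, month_amount, year_amount, values,
                           unseen_value) {
  key <- pair_key(month_amount, year_amount)
  cls <- ifelse(key %chin% object$singleton_keys, ".singleton", key)
  pred <- unname(values[cls])
  pred[is.na(pred)] <- unseen_value
  pred
}

# Training-proportion "fitted probabilities" of the binary nominal model,
# for the in-sample Efron statistic.
nominal_class_prob <- function(object, month_amount, year_amount) {
  stopifnot(object$dv_family == "binary")
  unseen <- if (object$has_singletons) {
    object$class_prob[[".singleton"]]
  } else {
    mean(object$class_prob)
  }
  nominal_lookup(object, month_amount, year_amount, object$class_prob,
    unseen)
}

#' @export
print.nominal_model <- function(x, ...) {
  cat(sprintf(
    "<nominal class model: %d classes (%s singleton pairs pooled), %s DV>\n",
    x$n_classes, length(x$singleton_keys), x$dv_family
  ))
  invisible(x)
}

# Exact two-sided rank-sum p-value by enumeration over all assignments of
# the (mid)ranks to group 1; convention 2 * min(lower, upper) capped at 1.
ranksum_exact <- function(x, g) {
  r <- rank(x) # midranks for ties
  n1 <- sum(g == 1)
  combos <- utils::combn(length(x), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  w <- sum(r[g == 1])
  lower <- mean(sums <= w + 1e-9)
  upper <- mean(sums >= w - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Midrank normal approximation with tie correction and continuity
# correction.
ranksum_normal <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  n1 <- sum(g == 1)
  n2 <- n - n1
  w <- sum(r[g == 1])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(1)
  }
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Nonparametric association test between patience and one criterion
#'
#' For a binary criterion: a Wilcoxon rank-sum test comparing the
#' patience amounts across the two criterion levels (patience treated as
#' the DV, as is usual in this literature), using exact enumeration with
#' midranks when the total sample is small (<= `exact_limit`) and a
#' tie-corrected normal approximation with continuity correction
#' otherwise. For a continuous criterion: a Kendall rank-correlation test
#' (tau-b, standard tie-adjusted large-sample test).
#'
#' @param patience Numeric patience amounts.
#' @param cv_column The criterion values (two levels if binary).
#' @param dv_family `"binary"` or `"continuous"`.
#' @param exact_limit Total-n threshold below which the exact rank-sum
#'   branch is used; set `exact = TRUE` to force it.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   `NULL` (default) decides by `exact_limit`.
#' @return A list with `p_value`, `statistic`, `method`.
#' @examples
#' rank_tests(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1), "binary")$p_value # 0.1
#' @export
rank_tests <- function(patience, cv_column,
                       dv_family = c("binary", "continuous"),
                       exact_limit = 12, exact = NULL) {
  dv_family <- match.arg(dv_family)
  keep <- !is.na(patience) & !is.na(cv_column)
  patience <- patience[keep]
  cv_column <- cv_column[keep]
  if (dv_family == "binary") {
    lev <- sort(unique(cv_column))
    if (length(lev) != 2L) {
      stopf("test error: binary criterion must have exactly two levels present")
    }
    g <- as.integer(cv_column == lev[2])
    use_exact <- if (is.null(exact)) length(patience) <= exact_limit else exact
    p <- if (use_exact) {
      ranksum_exact(patience, g)
    } else {
      ranksum_normal(patience, g)
    }
    list(
      p_value = p, statistic = sum(rank(patience)[g == 1]),
      method = if (use_exact) "ranksum_exact" else "ranksum_normal"
    )
  } else {
    if (length(patience) < 3L) stopf("Kendall test needs n >= 3")
    ct <- suppressWarnings(
      stats::cor.test(patience, cv_column, method = "kendall")
    )
    list(
      p_value = ct$p.value, statistic = unname(ct$estimate),
      method = "kendall_tau_b"
    )
  }
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Standard step-down Holm procedure at level `alpha` over a declared
#' family size `m` (defaulting to the number of p-values supplied).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Familywise error level.
#' @param m Family size for the correction.
#' @return Logical rejection flags, one per p-value.
#' @examples
#' holm_bonferroni(c(0.01, 0.03, 0.04)) # TRUE FALSE FALSE
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm", n = max(m, length(p_values))) <=
    alpha
}

#' Assess log and nominal models for every criterion variable
#'
#' For each criterion column, drops cases missing on the predictors or the
#' criterion, then computes association and tenfold cross-validated
#' predictive accuracy for both the [fit_log_model()] log model and the
#' [nominal_fit()] nominal model. Binary criteria report Efron's
#' R-squared, the in-sample proportion of correct classifications
#' (`*_acc_assoc`), and the out-of-fold proportion correct
#' (`*_acc_pred`), against the modal base rate; continuous criteria
#' report in-sample and out-of-fold mean absolute error against the mean
#' absolute deviation from the median (MAD). For the nominal model the
#' in-sample Efron statistic uses each class's training proportion of
#' the criterion as the fitted probability.
#'
#' @param month_amount,year_amount Patience-pair responses.
#' @param cvs Data frame of criterion columns.
#' @param dv_family Named character vector (`"binary"`/`"median"` or
#'   `"continuous"`) per criterion column; defaults to the `dv_family`
#'   attribute of `cvs`.
#' @param k Number of CV folds.
#' @param seed Seed for fold assignment.
#' @return A data frame, one row per criterion, with the metric columns
#'   described above plus `n` and `baseline`.
#' @export
study2_assess <- function(month_amount, year_amount, cvs,
                          dv_family = attr(cvs, "dv_family"),
                          k = 10, seed = 1L) {
  if (is.null(dv_family)) stopf("dv_family must be supplied")
  cv_names <- names(cvs)[names(cvs) %in% names(dv_family)]
  rows <- lapply(cv_names, function(nm) {
    fam <- if (dv_family[[nm]] %in% c("median", "continuous")) {
      "continuous"
    } else {
      "binary"
    }
    y_all <- cvs[[nm]]
    keep <- !is.na(y_all) & !is.na(month_amount) & !is.na(year_amount)
    y <- y_all[keep]
    mo <- month_amount[keep]
    yr <- year_amount[keep]
    n <- length(y)
    folds <- kfold_assign(n, k, derive_seed(seed, match(nm, cv_names)))

    log_in <- tryCatch(
      predict(fit_log_model(mo, yr, y, fam), mo, yr),
      error = function(e) rep(if (fam == "binary") mean(y) else
        stats::median(y), n)
    )
    nom_model <- nominal_fit(mo, yr, y, fam)
    nom_in <- predict(nom_model, mo, yr)
    # in-sample class proportions for the nominal Efron statistic
    nom_prob_in <- if (fam == "binary") {
      nominal_class_prob(nom_model, mo, yr)
    } else {
      NULL
    }

    log_oof <- rep(NA_real_, n)
    nom_oof <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- folds == f
      tr_mo <- mo[!test]
      tr_yr <- yr[!test]
      tr_y <- y[!test]
      lp <- tryCatch(
        predict(fit_log_model(tr_mo, tr_yr, tr_y, fam), mo[test], yr[test]),
        error = function(e) rep(if (fam == "binary") mean(tr_y) else
          stats::median(tr_y), sum(test))
      )
      log_oof[test] <- lp
      nom_oof[test] <- predict(
        nominal_fit(tr_mo, tr_yr, tr_y, fam), mo[test], yr[test]
      )
    }

    if (fam == "binary") {
      data.frame(
        cv = nm, dv_family = "binary", n = n,
        baseline = max(mean(y), 1 - mean(y)),
        log_efron_r2 = efron_r2(y, pmin(pmax(log_in, 0), 1)),
        log_acc_assoc = mean(classify_binary(log_in) == y),
        log_acc_pred = mean(classify_binary(log_oof) == y),
        nom_efron_r2 = efron_r2(y, nom_prob_in),
        nom_acc_assoc = mean(nom_in == y),
        nom_acc_pred = mean(nom_oof == y)
      )
    } else {
      data.frame(
        cv = nm, dv_family = "continuous", n = n,
        baseline = mean(abs(y - stats::median(y))),
        log_mae_assoc = mean(abs(y - log_in)),
        log_mae_pred = mean(abs(y - log_oof)),
        nom_mae_assoc = mean(abs(y - nom_in)),
        nom_mae_pred = mean(abs(y - nom_oof))
      )
    }
  })
  binary_rows <- Filter(function(r) r$dv_family == "binary", rows)
  cont_rows <- Filter(function(r) r$dv_family == "continuous", rows)
  out <- list(
    binary = if (length(binary_rows)) do.call(rbind, binary_rows) else NULL,
    continuous = if (length(cont_rows)) do.call(rbind, cont_rows) else NULL
  )
  structure(out, class = "study2_assessment")
}

#' @export
print.study2_assessment <- function(x, ...) {
  if (!is.null(x$binary)) {
    cat("Binary criteria (proportion correct vs base rate):\n")
    print(x$binary, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$continuous)) {
    cat("Continuous criteria (MAE vs MAD):\n")
    print(x$continuous, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
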