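#' Model specification for criterion-variable analysis
#'
#' Declares the dependent-variable family and, implicitly, the fitting
#' method: ordinary least squares for continuous DVs, maximum-likelihood
#' dichotomous probit for binary DVs, maximum-likelihood ordinal probit
#' for ordered-categorical DVs, and median (quantile-0.5) loss for
#' continuous DVs analyzed in absolute-error terms.
#'
#' @param dv_family `"continuous"`, `"binary"`, `"ordinal"`, or
#'   `"median"`.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(dv_family = c("continuous", "binary", "ordinal",
                                     "median")) {
  dv_family <- match.arg(dv_family)
  structure(list(dv_family = dv_family), class = "model_spec")
}

#' Four-term design matrix for near/far test scores
#'
#' An intercept, main effects for the near and far test scores, and their
#' interaction.
#'
#' @param near_score,far_score Numeric vectors of test scores.
#' @return An n-by-4 matrix with columns `intercept`, `near`, `far`,
#'   `near_far`.
#' @examples
#' design_matrix_study1(2, 3) # 1 2 3 6
#' @export
design_matrix_study1 <- function(near_score, far_score) {
  if (any(!is.finite(near_score)) || any(!is.finite(far_score))) {
    stopf("scores must be finite")
  }
  cbind(
    intercept = 1, near = near_score, far = far_score,
    near_far = near_score * far_score
  )
}

# Intercept-only fallback used when a training fold is degenerate.
fallback_fit <- function(spec, y) {
  fam <- spec$dv_family
  const <- switch(fam,
    continuous = mean(y),
    median = stats::median(y),
    binary = mean(y),
    ordinal = NULL
  )
  levels <- if (fam == "ordinal") sort(unique(y)) else NULL
  probs <- if (fam == "ordinal") {
    as.numeric(table(factor(y, levels = levels))) / length(y)
  } else {
    NULL
  }
  structure(
    list(
      spec = spec, coef = NULL, fallback = TRUE, const = const,
      levels = levels, probs = probs
    ),
    class = "tp_model"
  )
}

#' Fit a criterion-variable model
#'
#' Fits the model implied by `spec`'s DV family to a design matrix `X`
#' (including its intercept column) and response `y`: least squares
#' (continuous), maximum-likelihood dichotomous probit (binary),
#' maximum-likelihood ordinal probit (ordinal; constant design columns
#' are absorbed into the cutpoints), or median regression (median loss,
#' fit with the Barrodale-Roberts simplex algorithm).
#'
#' @param spec A [model_spec()].
#' @param X Numeric design matrix, n rows.
#' @param y Response: numeric (continuous/median), 0/1 (binary), or
#'   integer-coded ordered categories (ordinal).
#' @return An object of class `"tp_model"`; use [predict.tp_model()] for
#'   predictions.
#' @seealso [kfold_predict()], [assess_prediction()]
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stopf("X and y lengths differ")
  if (n <= ncol(X)) stopf("need more cases than design terms")
  if (qr(X)$rank < ncol(X)) stopf("fitting error: singular design")
  fam <- spec$dv_family
  out <- switch(fam,
    continuous = {
      fit <- stats::lm.fit(X, y)
      list(coef = fit$coefficients)
    },
    median = {
      # Barrodale-Roberts simplex is exact and fast for moderate n;
      # Frisch-Newton interior point scales better for large n.
      fit <- suppressWarnings(
        if (n <= 2000) {
          quantreg::rq.fit.br(X, y, tau = 0.5)
        } else {
          quantreg::rq.fit.fnb(X, y, tau = 0.5)
        }
      )
      list(coef = fit$coefficients)
    },
    binary = {
      if (!all(y %in% c(0, 1))) stopf("binary y must be 0/1")
      if (length(unique(y)) < 2L) stopf("fitting error: degenerate response (constant y)")
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial(link = "probit"))
      )
      p <- fit$fitted.values
      if (all(abs(p - y) < 1e-6)) {
        stopf("fitting error: perfect separation")
      }
      list(coef = fit$coefficients)
    },
    ordinal = {
      levels <- sort(unique(y))
      if (length(levels) < 2L) stopf("fitting error: degenerate response (constant y)")
      yf <- factor(y, levels = levels, ordered = TRUE)
      varying <- apply(X, 2, function(col) stats::var(col) > 0)
      Xv <- X[, varying, drop = FALSE]
      if (ncol(Xv) == 0L) stopf("ordinal fit needs at least one varying term")
      df <- data.frame(Xv)
      df$.y <- yf
      # polr's internal start-value glm can warn about separation at tiny
      # n; degenerate fits are handled by the caller's fallback instead
      fit <- suppressWarnings(
        MASS::polr(.y ~ ., data = df, method = "probit", Hess = FALSE)
      )
      list(
        coef = stats::coef(fit), zeta = fit$zeta, levels = levels,
        varying = varying
      )
    }
  )
  structure(
    c(list(spec = spec, fallback = FALSE), out),
    class = "tp_model"
  )
}

#' Predict from a fitted criterion-variable model
#'
#' Returns the expected value (continuous), the probability of class 1
#' (binary), a matrix of category probabilities (ordinal), or the
#' conditional median (median loss).
#'
#' @param object A `"tp_model"` from [fit_model()].
#' @param X New design matrix (same columns as at fit time).
#' @param ... Unused.
#' @export
predict.tp_model <- function(object, X, ...) {
  X <- as.matrix(X)
  fam <- object$spec$dv_family
  if (isTRUE(object$fallback)) {
    if (fam == "ordinal") {
      return(matrix(object$probs, nrow(X), length(object$probs),
        byrow = TRUE, dimnames = list(NULL, object$levels)
      ))
    }
    return(rep(object$const, nrow(X)))
  }
  if (fam %in% c("continuous", "median")) {
    return(drop(X %*% object$coef))
  }
  if (fam == "binary") {
    return(stats::pnorm(drop(X %*% object$coef)))
  }
  # ordinal probit: P(Y = k) from cutpoints
  eta <- drop(X[, object$varying, drop = FALSE] %*% object$coef)
  zeta <- c(-Inf, object$zeta, Inf)
  m <- length(object$levels)
  probs <- vapply(seq_len(m), function(k) {
    stats::pnorm(zeta[k + 1] - eta) - stats::pnorm(zeta[k] - eta)
  }, numeric(length(eta)))
  probs <- matrix(probs, ncol = m, dimnames = list(NULL, object$levels))
  probs
}

#' Efron's R-squared for binary outcomes
#'
#' `1 - sum((y - p)^2) / sum((y - mean(y))^2)`: the proportional reduction
#' in squared error from using fitted probabilities instead of the base
#' rate.
#'
#' @param y 0/1 outcomes.
#' @param p_hat Fitted probabilities in `[0, 1]`.
#' @return The statistic (at most 1; negative when the model does worse
#'   than the base rate).
#' @examples
#' efron_r2(c(0, 1, 1, 0), c(0.25, 0.75, 0.75, 0.25)) # 0.75
#' @export
efron_r2 <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stopf("lengths differ")
  if (any(p_hat < 0 | p_hat > 1)) stopf("p_hat must be in [0, 1]")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stopf("Efron's R-squared undefined for constant y")
  1 - sum((y - p_hat)^2) / denom
}
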