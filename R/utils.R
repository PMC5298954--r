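# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic fan-out of one user seed into per-stage seeds, kept inside
# the 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 747796405 + 2654435769 * stage) %%
    .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (x < lower || (lower_open && x == lower)) {
    stopf("`%s` must be %s %s", name, if (lower_open) ">" else ">=", lower)
  }
  if (x > upper || (upper_open && x == upper)) {
    stopf("`%s` must be %s %s", name, if (upper_open) "<" else "<=", upper)
  }
  invisible(x)
}

# Population-variance PVAF used for self-prediction and clipped
# cross-prediction: 1 - MSE / var(target), var with denominator n.
pvaf_stat <- function(target, predictor) {
  v <- mean((target - mean(target))^2)
  if (v == 0) {
    return(NA_real_)
  }
  1 - mean((target - predictor)^2) / v
}

# Statistical mode; ties broken toward the smaller value (declared tie rule).
modal_value <- function(x) {
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  out <- sort(winners)[1L]
  if (is.numeric(x)) as.numeric(out) else out
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
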