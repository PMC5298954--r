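#' Posterior state for the probabilistic bisection test
#'
#' The adaptive bisection test maintains a discretized Bayesian posterior
#' over the one-month discount factor d on `[0, 1]`. The state holds an
#' ordered support grid and nonnegative weights summing to 1. The default
#' prior is uniform over a 1024-point equispaced grid, giving a resolution
#' (~0.001) far below the dollar-rounding resolution of the stimuli (~1/95).
#'
#' @param grid_size Number of grid points.
#' @param support Optional explicit grid (ordered, within `[0, 1]`).
#' @param density Optional initial weights (renormalized).
#' @return An object of class `"posterior_state"` with elements `support`,
#'   `density`, `n_updates`.
#' @examples
#' s <- posterior_state()
#' pba_posterior_median(s)
#' @export
posterior_state <- function(grid_size = 1024, support = NULL, density = NULL) {
  if (is.null(support)) {
    check_number(grid_size, "grid_size", lower = 2)
    support <- seq(0, 1, length.out = grid_size)
  }
  if (is.unsorted(support, strictly = TRUE)) {
    stopf("support must be strictly increasing")
  }
  if (is.null(density)) {
    density <- rep(1 / length(support), length(support))
  }
  if (length(density) != length(support) || any(density < 0) ||
    sum(density) <= 0) {
    stopf("density must be nonnegative weights over the support")
  }
  structure(
    list(
      support = as.numeric(support),
      density = density / sum(density),
      n_updates = 0L
    ),
    class = "posterior_state"
  )
}

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf(
    "<posterior over d: %d grid points, %d updates, median = %.4f>\n",
    length(x$support), x$n_updates, pba_posterior_median(x)
  ))
  invisible(x)
}

#' One probabilistic-bisection update
#'
#' Updates the posterior after a binary choice at an effective query point
#' `query_d` (the SS/LL amount ratio actually shown). A subject whose true
#' discount factor exceeds the query ratio prefers LL, so an LL choice is
#' evidence that d lies above `query_d` and an SS choice that it lies at or
#' below. The side of the grid consistent with the response is rescaled to
#' total mass `p_c` (the assumed probability that the response reflects the
#' true preference) and the other side to `1 - p_c`. When the query sits at
#' the posterior median this is the textbook bisection step of multiplying
#' the favored side by `2 p_c` and the other by `2 (1 - p_c)`.
#'
#' If all mass already lies on one side of the query (including a degenerate
#' point-mass posterior), the response carries no usable information and the
#' state is returned unchanged with a warning.
#'
#' @param state A [posterior_state] object.
#' @param query_d Query discount factor, strictly inside (0, 1).
#' @param chose_ll Logical: did the respondent choose the larger-later
#'   option?
#' @param p_c Assumed response reliability, in (0.5, 1).
#' @return The updated `posterior_state` (weights sum to 1).
#' @export
pba_update <- function(state, query_d, chose_ll, p_c = 0.75) {
  stopifnot(inherits(state, "posterior_state"))
  check_number(query_d, "query_d", lower = 0, upper = 1,
               lower_open = TRUE, upper_open = TRUE)
  check_number(p_c, "p_c", lower = 0.5, upper = 1,
               lower_open = TRUE, upper_open = TRUE)
  above <- state$support > query_d
  mass_above <- sum(state$density[above])
  if (mass_above <= 0 || mass_above >= 1) {
    warning("uninformative update: all posterior mass on one side of the query",
      call. = FALSE
    )
    return(state)
  }
  dens <- state$density
  if (isTRUE(chose_ll)) {
    dens[above] <- dens[above] * (p_c / mass_above)
    dens[!above] <- dens[!above] * ((1 - p_c) / (1 - mass_above))
  } else {
    dens[above] <- dens[above] * ((1 - p_c) / mass_above)
    dens[!above] <- dens[!above] * (p_c / (1 - mass_above))
  }
  state$density <- dens / sum(dens)
  state$n_updates <- state$n_updates + 1L
  state
}

#' Posterior median of the discount factor
#'
#' Returns the smallest grid point whose cumulative posterior mass reaches
#' 0.5 — a deterministic, grid-exact median.
#'
#' @param state A [posterior_state] object.
#' @return A discount factor in `[0, 1]`.
#' @export
pba_posterior_median <- function(state) {
  stopifnot(inherits(state, "posterior_state"))
  cdf <- cumsum(state$density)
  state$support[which(cdf >= 0.5 - 1e-15)[1L]]
}

bisection_delays <- function(variant) {
  # near: today vs 1 month; far: 1 month vs 2 months
  if (variant == "near") c(ss = 0, ll = 30) else c(ss = 30, ll = 60)
}

#' Administer the adaptive bisection test
#'
#' Runs `n_trials` probabilistic-bisection trials plus two catch trials. In
#' each scored trial the LL amount is drawn uniformly from $15--$95 and the
#' SS amount is set to make a respondent at the current posterior-median
#' discount factor indifferent (`round(median * LL)`, at least $1). The
#' posterior is updated at the effective query ratio `SS/LL` — the rounded
#' stimulus actually shown. The score is the final posterior median.
#'
#' The two catch trials use SS/LL amount ratios of 0.07 (LL dominant for all
#' but the most extremely impatient) and 1.13 (the "SS" option both sooner
#' and larger, so LL is dominated). They are interleaved at seeded random
#' positions, never update the posterior, and increment `catch_failures`
#' when the dominated option is chosen.
#'
#' @param respond Function taking a presentation item (named list or one-row
#'   data frame; fields
#'   `ss_amount`, `ss_delay_days`, `ll_amount`, `ll_delay_days`, `is_catch`)
#'   and returning `"SS"` or `"LL"`.
#' @param variant `"near"` (today vs. 1 month) or `"far"` (1 month vs. 2
#'   months).
#' @param n_trials Number of scored trials (default 20).
#' @param p_c Assumed response reliability (default 3/4).
#' @param grid_size Posterior grid resolution.
#' @param catch_ratios SS/LL amount ratios for the two catch trials.
#' @return A [test_result] with `family = "bisection"`; `score` is the final
#'   posterior median in `[0, 1]`.
#' @examples
#' truthful <- function(item) {
#'   if (0.7 * item$ll_amount > item$ss_amount) "LL" else "SS"
#' }
#' set.seed(1)
#' run_bisection_test(truthful, "near")
#' @export
run_bisection_test <- function(respond, variant = c("near", "far"),
                               n_trials = 20, p_c = 0.75, grid_size = 1024,
                               catch_ratios = c(0.07, 1.13)) {
  variant <- match.arg(variant)
  check_number(n_trials, "n_trials", lower = 1)
  delays <- bisection_delays(variant)
  state <- posterior_state(grid_size)
  total <- n_trials + length(catch_ratios)
  catch_pos <- sample.int(total, length(catch_ratios))
  catch_queue <- sample(catch_ratios) # order of catch trials is random too
  ss_v <- ll_v <- query_v <- numeric(total)
  catch_v <- logical(total)
  choice_v <- character(total)
  catch_failures <- 0L
  ci <- 0L
  for (slot in seq_len(total)) {
    is_catch <- slot %in% catch_pos
    ll <- sample(15:95, 1L)
    if (is_catch) {
      ci <- ci + 1L
      ratio <- catch_queue[ci]
      ss <- max(1, round(ratio * ll))
    } else {
      med <- pba_posterior_median(state)
      ss <- max(1, round(med * ll))
    }
    item <- list(
      ss_amount = ss, ss_delay_days = delays[["ss"]],
      ll_amount = ll, ll_delay_days = delays[["ll"]],
      is_catch = is_catch
    )
    choice <- respond(item)
    if (!is.character(choice) || length(choice) != 1L ||
      !choice %in% c("SS", "LL")) {
      stopf("bisection administration error at trial %d: callback returned %s (trial log attached)",
        slot, deparse(choice))
    }
    if (is_catch) {
      dominated <- if (ss / ll > 1) "LL" else "SS"
      if (choice == dominated) catch_failures <- catch_failures + 1L
    } else {
      query_d <- ss / ll
      if (query_d > 0 && query_d < 1) {
        state <- pba_update(state, query_d, choice == "LL", p_c)
      }
    }
    ss_v[slot] <- ss
    ll_v[slot] <- ll
    catch_v[slot] <- is_catch
    choice_v[slot] <- choice
    query_v[slot] <- if (is_catch) NA_real_ else ss / ll
  }
  trials <- data.frame(
    trial = seq_len(total), ss_amount = ss_v,
    ss_delay_days = delays[["ss"]], ll_amount = ll_v,
    ll_delay_days = delays[["ll"]], is_catch = catch_v,
    choice = choice_v, query_d = query_v
  )
  test_result(
    family = "bisection", variant = variant,
    score = pba_posterior_median(state),
    trials = trials, catch_failures = catch_failures
  )
}
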