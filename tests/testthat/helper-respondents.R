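# Deterministic and noisy respondent callbacks used across test files.

# Always chooses the truly preferred option for discount factor d
# (SS at exact indifference).
truthful_chooser <- function(d) {
  function(item) {
    if (d * item$ll_amount > item$ss_amount) "LL" else "SS"
  }
}

# Chooses the preferred option with the given probability.
noisy_chooser <- function(d, consistency) {
  function(item) {
    preferred <- if (d * item$ll_amount > item$ss_amount) "LL" else "SS"
    if (stats::runif(1) < consistency) {
      preferred
    } else {
      setdiff(c("SS", "LL"), preferred)
    }
  }
}

# Matching respondent answering exactly ss / d.
exact_matcher <- function(d) {
  function(item) item$ss_amount / d
}

# O(n^2) pair-counting Kendall tau-b, independent of stats::cor.
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  concordant <- 0
  discordant <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) concordant <- concordant + 1
      if (s < 0) discordant <- discordant + 1
    }
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(choose(table(x), 2))
  t2 <- sum(choose(table(y), 2))
  (concordant - discordant) / sqrt((n0 - t1) * (n0 - t2))
}

# Exhaustive fixed-test scoring oracle: enumerate every candidate
# indifference rank, score its consistency by explicit prediction vectors,
# and average the argmax set.
score_fixed_oracle <- function(chose_ll, a = 2, b = -2) {
  k <- length(chose_ll)
  consistency <- sapply(1:(k + 1), function(r) {
    predicted <- c(rep(FALSE, k - (r - 1)), rep(TRUE, r - 1))
    sum(predicted == chose_ll)
  })
  a * mean(which(consistency == max(consistency))) + b
}

# Direct two-sided exact rank-sum p-value, written independently of the
# package implementation (explicit subset enumeration over indices).
ranksum_enumeration_oracle <- function(x, g) {
  r <- rank(x)
  idx1 <- which(g == 1)
  w_obs <- sum(r[idx1])
  subsets <- utils::combn(seq_along(x), length(idx1))
  w_all <- apply(subsets, 2, function(s) sum(r[s]))
  p_low <- mean(w_all <= w_obs + 1e-9)
  p_high <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}
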