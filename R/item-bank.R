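#' Fixed-test item banks
#'
#' A fixed item bank is an ordered set of smaller-sooner (SS) versus
#' larger-later (LL) monetary choices, ranked by the discount rate at which
#' a decision-maker would be indifferent between the two options. Rank 1 is
#' the item requiring the least patience to take LL (the $54 today vs. $55
#' later item), rank 2 the $47 vs. $50 item, and so on: a perfectly
#' consistent respondent switches from SS to LL at some rank, and more
#' patient respondents switch earlier.
#'
#' `kirby_medium_bank()` returns the classic medium-magnitude monetary-choice
#' items (LL rewards of $50--$60). The full instrument has nine such items;
#' by default the first `n_items = 7` ranks are used, matching a 7-trial
#' administration. The bank is an ordinary data frame and can be edited or
#' replaced wholesale; `validate_item_bank()` checks the structural
#' invariants (LL amount exceeds SS amount, ranks 1..K in order of strictly
#' increasing indifference discount rate).
#'
#' @param n_items Number of items to keep, from rank 1 upward (1--9).
#' @return A data frame with columns `item_rank`, `ss_amount`, `ll_amount`,
#'   `ll_delay_days`, of class `c("fixed_item_bank", "data.frame")`.
#' @examples
#' bank <- kirby_medium_bank()
#' bank
#' @export
kirby_medium_bank <- function(n_items = 7) {
  check_number(n_items, "n_items", lower = 1, upper = 9)
  bank <- data.frame(
    item_rank = 1:9,
    ss_amount = c(54, 47, 54, 49, 40, 34, 27, 25, 20),
    ll_amount = c(55, 50, 60, 60, 55, 50, 50, 60, 55),
    ll_delay_days = c(117, 160, 111, 89, 62, 30, 21, 14, 7)
  )
  bank <- bank[seq_len(n_items), , drop = FALSE]
  class(bank) <- c("fixed_item_bank", "data.frame")
  validate_item_bank(bank)
  bank
}

#' @rdname kirby_medium_bank
#' @param bank A candidate item bank data frame.
#' @export
validate_item_bank <- function(bank) {
  needed <- c("item_rank", "ss_amount", "ll_amount", "ll_delay_days")
  if (!all(needed %in% names(bank))) {
    stopf("item bank must have columns %s", paste(needed, collapse = ", "))
  }
  if (nrow(bank) < 1L) stopf("item bank is empty")
  if (!identical(as.integer(bank$item_rank), seq_len(nrow(bank)))) {
    stopf("item_rank must be 1..K in order")
  }
  if (any(bank$ll_amount <= bank$ss_amount)) {
    stopf("every LL amount must exceed its SS amount")
  }
  if (any(bank$ss_amount <= 0) || any(bank$ll_delay_days <= 0)) {
    stopf("amounts and delays must be positive")
  }
  # indifference discount rate per day, for rank-ordering
  k <- (bank$ll_amount / bank$ss_amount - 1) / bank$ll_delay_days
  if (any(diff(k) <= 0)) {
    stopf("item_rank must strictly increase in the indifference discount rate")
  }
  invisible(bank)
}

#' Read or write an item bank as CSV
#'
#' @param path File path of a CSV with columns `item_rank`, `ss_amount`,
#'   `ll_amount`, `ll_delay_days`.
#' @return `read_item_bank()` returns a validated item bank;
#'   `write_item_bank()` invisibly returns `path`.
#' @export
read_item_bank <- function(path) {
  bank <- utils::read.csv(path)
  class(bank) <- c("fixed_item_bank", "data.frame")
  validate_item_bank(bank)
  bank
}

#' @rdname read_item_bank
#' @param bank An item bank data frame.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE)
  invisible(path)
}
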