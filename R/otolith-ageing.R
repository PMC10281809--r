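# Replicate-count QC, pelagic larval duration, and hatch-date
# back-calculation.

#' Quality-control three replicate increment counts
#'
#' A fish's post-settlement age is accepted as the arithmetic mean of its
#' three replicate increment counts when every count lies within 10% of the
#' median count (inclusive: `|c - median| / median <= tol`). Otherwise the
#' fish is rejected and the offending counts reported.
#'
#' @param counts integer vector of exactly three positive replicate counts.
#' @param tol relative tolerance about the median (default 0.10).
#' @return a list with `accepted` (logical), `mean_age` (mean of the three
#'   counts if accepted, `NA` otherwise) and `offending` (the counts that
#'   violated the rule).
#' @export
#' @examples
#' qc_counts(c(99, 100, 101))   # accepted, mean 100
#' qc_counts(c(100, 100, 111))  # rejected: 111 deviates 11% from the median
qc_counts <- function(counts, tol = 0.10) {
  stopifnot(length(counts) == 3L, all(!is.na(counts)), all(counts > 0))
  med <- stats::median(counts)
  dev <- abs(counts - med) / med
  bad <- dev > tol
  if (any(bad)) {
    list(accepted = FALSE, mean_age = NA_real_, offending = counts[bad])
  } else {
    list(accepted = TRUE, mean_age = mean(counts), offending = numeric(0))
  }
}

#' Apply count QC across a fish table
#'
#' Rows with all three replicate counts present are run through
#' [qc_counts()]; accepted fish get `post_settlement_age_days` (the count
#' mean) and `aged = TRUE`. Fish with fewer than three counts are flagged
#' un-ageable, not errored.
#'
#' @param fish a fish-record data.frame with columns `count1..count3`.
#' @param tol passed to [qc_counts()].
#' @return the table with `post_settlement_age_days`, `aged` and
#'   `qc_rejected` columns filled in; attribute `qc_rejects` holds the
#'   rejected fish ids.
#' @export
age_fish <- function(fish, tol = 0.10) {
  cnt <- as.matrix(fish[, c("count1", "count2", "count3")])
  have3 <- rowSums(!is.na(cnt)) == 3L
  fish$post_settlement_age_days <- NA_real_
  fish$qc_rejected <- FALSE
  for (i in which(have3)) {
    q <- qc_counts(cnt[i, ], tol = tol)
    if (q$accepted) {
      fish$post_settlement_age_days[i] <- q$mean_age
    } else {
      fish$qc_rejected[i] <- TRUE
    }
  }
  fish$aged <- !is.na(fish$post_settlement_age_days)
  attr(fish, "qc_rejects") <- fish$fish_id[fish$qc_rejected]
  fish
}

#' Estimate pelagic larval duration from pre-settlement counts
#'
#' The PLD of a fish is the number of daily increments from the otolith
#' primordium to the settlement mark. The population estimate is the sample
#' mean and standard deviation over all fish whose core was read.
#'
#' @param fish a fish-record data.frame with a `pre_settlement_count`
#'   column, or a bare numeric vector of pre-settlement counts.
#' @return list with `mean_days`, `sd_days`, `n`.
#' @export
estimate_pld <- function(fish) {
  counts <- if (is.data.frame(fish)) fish$pre_settlement_count else fish
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2L) {
    stop("need at least 2 pre-settlement counts to estimate PLD (got ",
         length(counts), ")")
  }
  list(mean_days = mean(counts), sd_days = stats::sd(counts),
       n = length(counts))
}

#' Back-calculate settlement and hatch dates
#'
#' Settlement date is the collection date minus the post-settlement age;
#' hatch date is the settlement date minus the mean PLD. Ages and the mean
#' PLD are rounded half-up to whole days before date subtraction (calendar
#' dates are integral). Embryonic duration (under a day) is deliberately
#' not subtracted.
#'
#' @param fish fish-record data.frame with `collection_date` and
#'   `post_settlement_age_days` columns (measured or model-predicted).
#' @param mean_pld_days positive mean PLD in days.
#' @return the table with `pld_days`, `settlement_date` and `hatch_date`
#'   columns filled for rows that have an age.
#' @export
#' @examples
#' rec <- data.frame(fish_id = "F1",
#'                   collection_date = as.Date("2021-11-30"),
#'                   post_settlement_age_days = 60)
#' back_calculate(rec, mean_pld_days = 28)
back_calculate <- function(fish, mean_pld_days) {
  stopifnot(mean_pld_days > 0)
  has_age <- !is.na(fish$post_settlement_age_days)
  age_d <- round_half_up(fish$post_settlement_age_days[has_age])
  pld_d <- round_half_up(mean_pld_days)
  fish$pld_days <- ifelse(has_age, pld_d, NA_real_)
  fish$settlement_date <- as.Date(NA)
  fish$hatch_date <- as.Date(NA)
  fish$settlement_date[has_age] <- fish$collection_date[has_age] - age_d
  fish$hatch_date[has_age] <- fish$settlement_date[has_age] - pld_d
  bad <- which(has_age)[fish$hatch_date[has_age] > fish$collection_date[has_age]]
  if (length(bad) > 0) {
    stop("back-calculated hatch date after collection date for fish ",
         paste(fish$fish_id[bad], collapse = ", "), " (corrupt age)")
  }
  fish
}
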