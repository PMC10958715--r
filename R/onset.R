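# Time to onset: days from first target-drug therapy start to the event
# date, summarized as median/IQR and 30-day bins.

onset_bin <- function(days) {
  ifelse(days > 360, ">360", as.character(pmax(1L, ceiling(days / 30))))
}

onset_bin_levels <- function() c(as.character(1:12), ">360")

#' Compute time to onset for a primary-suspect cohort
#'
#' Onset is the day count from the earliest therapy start among the matched
#' target-drug sequence numbers to the case's event date. A case is excluded
#' (not errored) when either date is missing or has less than day precision,
#' or when the difference is negative.
#'
#' @param cohort a `faers_cases` cohort from [filter_primary_suspect()] (its
#'   `target_seq` attribute identifies the target-drug sequences)
#' @param target_seq optional tibble of (caseid, drug_seq) overriding the
#'   cohort attribute
#' @return a tibble of onset records with columns `caseid`, `onset_days`
#'   (non-negative integer) and `bin` ("1".."12" for successive 30-day
#'   windows, ">360" beyond; day 0 falls in bin 1). The attribute
#'   `n_excluded` counts cohort cases without a usable onset.
#' @export
compute_onset <- function(cohort, target_seq = NULL) {
  stopifnot(inherits(cohort, "faers_cases"))
  tseq <- target_seq %||% attr(cohort, "target_seq")
  ther <- cohort$ther
  if (!is.null(tseq) && nrow(tseq) > 0) {
    ther <- ther %>%
      inner_join(tseq, by = c(caseid = "caseid", dsg_drug_seq = "drug_seq"))
  }
  starts <- ther %>%
    mutate(parse_faers_date(.data$start_dt)) %>%
    filter(.data$precision == "day") %>%
    group_by(.data$caseid) %>%
    summarise(start = min(.data$date), .groups = "drop")
  events <- cohort$demo %>%
    mutate(parse_faers_date(.data$event_dt)) %>%
    filter(.data$precision == "day") %>%
    dplyr::select("caseid", event = "date")
  rec <- inner_join(starts, events, by = "caseid") %>%
    mutate(onset_days = as.integer(.data$event - .data$start)) %>%
    filter(.data$onset_days >= 0) %>%
    transmute(.data$caseid, .data$onset_days,
              bin = onset_bin(.data$onset_days)) %>%
    arrange(.data$caseid)
  attr(rec, "n_excluded") <- nrow(cohort$demo) - nrow(rec)
  rec
}

#' Summarize onset records
#'
#' Median and quartiles use linear interpolation between order statistics
#' (quantile position `1 + (n-1)p`, R's default type 7). Bin percents are
#' over the number of onset records, rounded half-up to two decimals.
#'
#' @param records onset records from [compute_onset()]
#' @return a list with `n`, `median`, `q1`, `q3` and `bins`, a tibble of
#'   (bin, count, percent) over the thirteen 30-day windows. Empty input
#'   yields `n = 0`, `NA` quantiles and zero counts.
#' @export
summarize_onset <- function(records) {
  n <- nrow(records)
  lv <- onset_bin_levels()
  if (n == 0) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                bins = tibble(bin = lv, count = 0L, percent = NA_real_)))
  }
  q <- unname(quantile(records$onset_days, c(0.25, 0.5, 0.75), type = 7))
  counts <- table(factor(records$bin, levels = lv))
  bins <- tibble(bin = lv, count = as.integer(counts)) %>%
    mutate(percent = percent_of(.data$count, n))
  list(n = n, median = q[2], q1 = q[1], q3 = q[3], bins = bins)
}
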