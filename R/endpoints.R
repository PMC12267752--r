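# Clinical endpoints per stay and follow-up summaries of failed attempts.

union_intervals <- function(ints) {
  ints <- ints[order(ints$start), , drop = FALSE]
  if (nrow(ints) < 2) return(ints)
  out <- ints[1, , drop = FALSE]
  overlapped <- FALSE
  for (i in 2:nrow(ints)) {
    k <- nrow(out)
    if (ints$start[i] <= out$end[k]) {
      if (ints$start[i] < out$end[k]) overlapped <- TRUE
      out$end[k] <- max(out$end[k], ints$end[i])
    } else out <- rbind(out, ints[i, ])
  }
  if (overlapped) warning("overlapping invasive intervals normalized by union")
  out
}

#' Compute endpoints for one ICU stay
#'
#' 28-day mortality is anchored at ICU admission (t = 0). Ventilator-free
#' days by day 28 follow the standard convention: 0 when the patient dies
#' before day 28, otherwise 28 minus the invasive-ventilation days accrued
#' up to day 28, floored at 0.
#'
#' @param stay One-row data.frame with `discharge_time` (hours).
#' @param invasive_intervals data.frame (`start`, `end`) in hours;
#'   overlapping intervals are normalized by union with a warning.
#' @param death_time Hours since admission, or `NA`.
#' @return list with `mort28`, `vfd28`, `mv_days`, `icu_los_days`.
#' @export
compute_endpoints <- function(stay, invasive_intervals, death_time = NA) {
  inv <- union_intervals(invasive_intervals)
  mv_hours <- sum(inv$end - inv$start)
  mort28 <- !is.na(death_time) && death_time <= 28 * 24
  mv28 <- sum(pmin(inv$end, 28 * 24) - pmin(inv$start, 28 * 24)) / 24
  vfd28 <- if (mort28) 0 else max(0, 28 - mv28)
  list(mort28 = mort28, vfd28 = vfd28, mv_days = mv_hours / 24,
       icu_los_days = (stay$discharge_time - stay$admission_time) / 24)
}

#' Cohort endpoint table
#'
#' @param stays Stay table (`stay_id`, `admission_time`, `discharge_time`,
#'   `death_time`).
#' @param timelines Named list of `vs_timeline` keyed by stay id (supplies
#'   the invasive intervals).
#' @return data.frame with one row per stay.
#' @export
compute_endpoints_cohort <- function(stays, timelines) {
  rows <- lapply(seq_len(nrow(stays)), function(i) {
    s <- stays[i, ]
    tl <- timelines[[as.character(s$stay_id)]]
    ep <- compute_endpoints(s, tl$invasive, s$death_time)
    data.frame(stay_id = s$stay_id, mort28 = ep$mort28, vfd28 = ep$vfd28,
               mv_days = ep$mv_days, icu_los_days = ep$icu_los_days)
  })
  as.data.frame(data.table::rbindlist(rows))
}

#' Fraction still in assisted mode after a failed switch attempt
#'
#' Step function of follow-up time: starts at 1 and drops at each observed
#' time to failure; the median read-off equals the median time to failure.
#'
#' @param failure_times Numeric vector of times to failure (hours) of failed
#'   first attempts.
#' @return data.frame (`time`, `fraction`), non-increasing in `fraction`,
#'   with the median time to failure in `attr(, "median")`.
#' @export
assisted_survival_curve <- function(failure_times) {
  if (!length(failure_times)) stop("no failed attempts supplied")
  tt <- sort(failure_times)
  u <- unique(tt)
  frac <- 1 - cumsum(tabulate(match(tt, u))) / length(tt)
  out <- data.frame(time = c(0, u), fraction = c(1, frac))
  attr(out, "median") <- stats::median(failure_times)
  out
}

#' Split failed attempts at the median time to failure
#'
#' Early failures have time to failure at or below the cohort median; late
#' failures above it.
#'
#' @param time_to_failure Numeric vector (hours).
#' @return list with `median`, logical `early`, and the two index vectors.
#' @export
split_early_late <- function(time_to_failure) {
  med <- stats::median(time_to_failure)
  early <- time_to_failure <= med
  list(median = med, early = early,
       early_idx = which(early), late_idx = which(!early))
}

#' Cohort-flow counts and percentages
#'
#' @param eligibility Eligibility data.frame from [phenotype_cohort()].
#' @param attempts Labeled attempt data.frame (first attempts).
#' @return list of counts and the percentages of [flow_percentages()];
#'   warns if the partition identities (eligible = attempted + no-switch,
#'   attempted = success + failure) are violated.
#' @export
flow_counts <- function(eligibility, attempts) {
  elig_ids <- eligibility$stay_id[eligibility$eligible]
  first <- attempts[attempts$attempt_index == 1 &
                      attempts$stay_id %in% elig_ids, ]
  n_eligible <- length(elig_ids)
  n_attempted <- nrow(first)
  n_success <- sum(first$outcome == "SUCCESS")
  n_failure <- sum(first$outcome == "FAILURE")
  n_no_switch <- n_eligible - n_attempted
  n_mode_change <- sum(first$attempt_type == "mode_change")
  if (n_attempted != n_success + n_failure)
    warning("attempted != success + failure")
  c(list(n_eligible = n_eligible, n_attempted = n_attempted,
         n_success = n_success, n_failure = n_failure,
         n_no_switch = n_no_switch, n_mode_change = n_mode_change),
    as.list(flow_percentages(n_eligible, n_attempted, n_success, n_failure,
                             n_no_switch, n_mode_change)))
}

#' Cohort-flow percentages from counts
#'
#' @param eligible,attempted,success,failure,no_switch,mode_change Counts.
#' @return Named numeric vector: `pct_attempted` and `pct_no_switch` (of
#'   eligible patients), `pct_success`, `pct_failure` and `pct_mode_change`
#'   (of attempted patients), in percent.
#' @export
flow_percentages <- function(eligible, attempted, success, failure,
                             no_switch, mode_change) {
  c(pct_attempted = 100 * attempted / eligible,
    pct_success = 100 * success / attempted,
    pct_failure = 100 * failure / attempted,
    pct_no_switch = 100 * no_switch / eligible,
    pct_mode_change = 100 * mode_change / attempted)
}
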