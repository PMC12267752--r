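# Eligibility screening, switch-attempt detection on clean timelines, and
# 72-hour outcome labeling of the first attempt.

#' Check cohort eligibility for one stay
#'
#' A stay is eligible when (1) at least one PaO2/FiO2 below 300 mmHg was
#' measured within the first 48 h of intubation (hypoxemic respiratory
#' failure), (2) invasive mechanical ventilation lasted at least 48 h in
#' total, (3) the first invasive mode category is CONTROLLED, and (4) it is
#' the first ICU stay of the hospitalization.
#'
#' @param stay One-row data.frame with at least `stay_id` and `first_stay`.
#' @param timeline The stay's harmonized `vs_timeline`.
#' @param pf_series data.frame (`time`, `value`) of derived PaO2/FiO2 points
#'   (see [derive_pf()]).
#' @param pf_threshold Hypoxemia threshold in mmHg (default 300).
#' @param mv_min_hours Minimum total invasive ventilation (default 48).
#' @param window_hours Hypoxemia lookback from intubation (default 48).
#' @return A list with `stay_id`, `eligible` flag and character vector
#'   `reasons` (empty iff eligible).
#' @export
check_eligibility <- function(stay, timeline, pf_series, pf_threshold = 300,
                              mv_min_hours = 48, window_hours = 48) {
  inv <- timeline$invasive
  if (!nrow(inv)) stop("missing intubation time for stay ", stay$stay_id)
  t_int <- min(inv$start)
  reasons <- character(0)

  in_window <- pf_series$time >= t_int & pf_series$time <= t_int + window_hours
  if (!any(in_window) || min(pf_series$value[in_window]) >= pf_threshold)
    reasons <- c(reasons, "no_hypoxemia_48h")

  if (sum(inv$end - inv$start) < mv_min_hours)
    reasons <- c(reasons, "mv_under_48h")

  seg <- timeline$segments
  first_inv <- seg[seg$start >= t_int - 1e-9 &
                     seg$category != "NONINVASIVE_OR_NONE", , drop = FALSE]
  if (!nrow(first_inv) || first_inv$category[1] != "CONTROLLED")
    reasons <- c(reasons, "not_starting_controlled")

  if (!isTRUE(stay$first_stay))
    reasons <- c(reasons, "not_first_stay")

  list(stay_id = stay$stay_id, eligible = length(reasons) == 0L,
       reasons = reasons)
}

#' Detect switch attempts on a persistence-filtered timeline
#'
#' A switch attempt is a CONTROLLED to ASSISTED boundary within invasive
#' ventilation. Attempts whose assisted side exists only because of
#' combined-mode reassignment are typed `rr_change` (a respiratory-rate
#' change during a combined mode); all others are `mode_change`.
#'
#' @param timeline A persistence-filtered `vs_timeline`.
#' @return data.frame with `stay_id`, `attempt_index`, `time`,
#'   `attempt_type`; zero rows when the timeline never leaves controlled
#'   ventilation (the "no switch" group).
#' @export
detect_attempts <- function(timeline) {
  seg <- timeline$segments
  n <- nrow(seg)
  if (n < 2) {
    return(data.frame(stay_id = integer(0), attempt_index = integer(0),
                      time = numeric(0), attempt_type = character(0)))
  }
  contiguous <- seg$start[-1] == seg$end[-n]
  is_attempt <- seg$category[-n] == "CONTROLLED" &
    seg$category[-1] == "ASSISTED" & contiguous
  idx <- which(is_attempt) + 1L
  data.frame(
    stay_id = rep(timeline$stay_id, length(idx)),
    attempt_index = seq_along(idx),
    time = seg$start[idx],
    attempt_type = ifelse(seg$provenance[idx] == "combined_reassigned",
                          "rr_change", "mode_change"),
    stringsAsFactors = FALSE)
}

#' Label a switch attempt under the 72-hour outcome definition
#'
#' An attempt fails if the patient returns to controlled ventilation (a
#' CONTROLLED segment surviving the persistence filter begins) within the
#' horizon, or dies within the horizon without an earlier return; otherwise
#' it succeeds. Liberation from the ventilator (extubation alive, no return)
#' counts as success, as does discharge alive before the horizon elapses.
#' Events at exactly `time + horizon` are inside the window.
#'
#' @param attempt One-row data.frame from [detect_attempts()].
#' @param timeline The same `vs_timeline` the attempt was detected on.
#' @param death_time Death time in hours, or `NA`.
#' @param horizon Follow-up horizon in hours (default 72).
#' @return The attempt row with `outcome` (`"SUCCESS"`/`"FAILURE"`),
#'   `failure_cause` (`"return_to_controlled"`, `"death"`, `"none"`),
#'   `failure_time` and `time_to_failure` appended.
#' @export
label_attempt <- function(attempt, timeline, death_time = NA, horizon = 72) {
  t0 <- attempt$time
  if (!is.na(death_time) && death_time <= t0)
    stop("death_time at or before attempt time for stay ", attempt$stay_id)
  seg <- timeline$segments
  returns <- seg$start[seg$category == "CONTROLLED" & seg$start > t0 &
                         seg$start <= t0 + horizon]
  ret <- if (length(returns)) min(returns) else NA_real_
  dth <- if (!is.na(death_time) && death_time > t0 &&
             death_time <= t0 + horizon) death_time else NA_real_

  if (!is.na(ret) && (is.na(dth) || ret <= dth)) {
    outcome <- "FAILURE"; cause <- "return_to_controlled"; ft <- ret
  } else if (!is.na(dth)) {
    outcome <- "FAILURE"; cause <- "death"; ft <- dth
  } else {
    outcome <- "SUCCESS"; cause <- "none"; ft <- NA_real_
  }
  attempt$outcome <- outcome
  attempt$failure_cause <- cause
  attempt$failure_time <- ft
  attempt$time_to_failure <- ft - t0
  attempt
}

#' Summarize a stay's attempts
#'
#' @param attempts data.frame of one stay's attempts (from
#'   [detect_attempts()]), ordered by `attempt_index`.
#' @return list with `time_to_first_attempt_days` (first attempt time / 24)
#'   and `n_secondary_attempts`.
#' @export
summarize_attempts <- function(attempts) {
  if (!nrow(attempts))
    return(list(time_to_first_attempt_days = NA_real_,
                n_secondary_attempts = 0L))
  list(time_to_first_attempt_days = min(attempts$time) / 24,
       n_secondary_attempts = nrow(attempts) - 1L)
}

#' Harmonize and phenotype a whole cohort
#'
#' Runs the full event-log phenotyping for every stay: timeline construction
#' from the raw mode log, combined-mode reassignment by spontaneous
#' respiratory rate, CPAP reassignment, persistence filtering, eligibility
#' screening, attempt detection, and labeling of the first attempt.
#'
#' @param cohort A `vs_cohort` (or any list with `stays`, `mode_events`,
#'   `airway_events`, `measurements` in the documented schemas).
#' @param dialects Named list of dialects keyed by center.
#' @param persistence_hours,horizon_hours,rr_threshold,tolerance_hours
#'   Phenotyping thresholds (defaults 1 h, 72 h, 10 breaths/min, 1 h).
#' @param strict Passed to [map_raw_mode()].
#' @return list with `timelines` (named list of `vs_timeline`),
#'   `eligibility` (data.frame `stay_id`, `eligible`, `reasons`), and
#'   `attempts` (all detected attempts; first attempts labeled).
#' @export
phenotype_cohort <- function(cohort, dialects = default_dialects(),
                             persistence_hours = 1, horizon_hours = 72,
                             rr_threshold = 10, tolerance_hours = 1,
                             strict = FALSE) {
  stays <- cohort$stays
  me <- split(cohort$mode_events, cohort$mode_events$stay_id)
  ae <- split(cohort$airway_events, cohort$airway_events$stay_id)
  meas <- cohort$measurements
  rr <- meas[meas$variable == "spont_rr", c("stay_id", "time", "value")]
  rr_by <- split(rr[c("time", "value")], rr$stay_id)
  pf_all <- derive_pf_cohort(meas, tolerance = tolerance_hours)
  pf_by <- split(pf_all[c("time", "value")], pf_all$stay_id)
  empty <- data.frame(time = numeric(0), value = numeric(0))

  timelines <- vector("list", nrow(stays))
  elig <- vector("list", nrow(stays))
  att <- vector("list", nrow(stays))
  for (i in seq_len(nrow(stays))) {
    s <- stays[i, ]
    id <- as.character(s$stay_id)
    stay_end <- if (!is.na(s$death_time))
      min(s$discharge_time, s$death_time) else s$discharge_time
    tl <- build_timeline(me[[id]], ae[[id]], dialects[[s$center]],
                         stay_end = stay_end, stay_id = s$stay_id,
                         strict = strict)
    tl <- reassign_combined(tl, if (!is.null(rr_by[[id]])) rr_by[[id]] else empty,
                            rr_threshold = rr_threshold,
                            tolerance = tolerance_hours)
    tl <- reassign_cpap(tl)
    tl <- persistence_filter(tl, min_duration = persistence_hours)
    timelines[[i]] <- tl

    el <- check_eligibility(s, tl, if (!is.null(pf_by[[id]])) pf_by[[id]] else empty)
    elig[[i]] <- data.frame(stay_id = s$stay_id, eligible = el$eligible,
                            reasons = paste(el$reasons, collapse = ";"),
                            stringsAsFactors = FALSE)
    a <- detect_attempts(tl)
    if (nrow(a)) {
      first <- label_attempt(a[1, ], tl, death_time = s$death_time,
                             horizon = horizon_hours)
      if (nrow(a) > 1) {
        rest <- a[-1, ]
        rest$outcome <- NA_character_
        rest$failure_cause <- NA_character_
        rest$failure_time <- NA_real_
        rest$time_to_failure <- NA_real_
        a <- rbind(first, rest)
      } else a <- first
    } else {
      a <- data.frame(stay_id = integer(0), attempt_index = integer(0),
                      time = numeric(0), attempt_type = character(0),
                      outcome = character(0), failure_cause = character(0),
                      failure_time = numeric(0), time_to_failure = numeric(0))
    }
    att[[i]] <- a
  }
  names(timelines) <- as.character(stays$stay_id)
  list(timelines = timelines,
       eligibility = as.data.frame(data.table::rbindlist(elig)),
       attempts = as.data.frame(data.table::rbindlist(att)))
}
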