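# Derived respiratory parameters and windowed feature extraction around the
# switch attempt. Series are data.frames with columns `time` (hours) and
# `value`, sorted by time.

# latest partner value at or before each primary time, within tolerance;
# "nearest prior" includes a simultaneous timestamp
nearest_prior <- function(primary_time, partner_time, partner_value,
                          tolerance) {
  if (!length(partner_time))
    return(rep(NA_real_, length(primary_time)))
  o <- order(partner_time)
  pt <- partner_time[o]; pv <- partner_value[o]
  i <- findInterval(primary_time, pt)
  out <- rep(NA_real_, length(primary_time))
  ok <- i >= 1L
  ok[ok] <- primary_time[ok] - pt[i[ok]] <= tolerance + 1e-9
  out[ok] <- pv[i[ok]]
  out
}

#' Derive PaO2/FiO2 from arterial PaO2 and the nearest prior FiO2
#'
#' One P/F point is emitted per PaO2 point that has an FiO2 at or before it
#' within `tolerance` hours; no extrapolation beyond the tolerance. FiO2 is
#' in percent; values of 0 or less are skipped with a warning.
#'
#' @param pao2,fio2 Series data.frames (`time`, `value`).
#' @param tolerance Nearest-measurement tolerance in hours (default 1).
#' @return Series data.frame of P/F in mmHg.
#' @export
#' @examples
#' derive_pf(data.frame(time = 2, value = 100),
#'           data.frame(time = 1.5, value = 40))
derive_pf <- function(pao2, fio2, tolerance = 1) {
  f <- nearest_prior(pao2$time, fio2$time, fio2$value, tolerance)
  bad <- !is.na(f) & f <= 0
  if (any(bad)) {
    warning("skipping ", sum(bad), " P/F point(s) with FiO2 <= 0")
    f[bad] <- NA_real_
  }
  ok <- !is.na(f)
  data.frame(time = pao2$time[ok], value = pao2$value[ok] / (f[ok] / 100))
}

#' Derive driving pressure from plateau pressure and nearest prior PEEP
#'
#' @param pplat,peep Series data.frames (`time`, `value`), cmH2O.
#' @inheritParams derive_pf
#' @return Series data.frame of driving pressure (Pplat - PEEP) in cmH2O;
#'   negative values are skipped with a warning.
#' @export
derive_dp <- function(pplat, peep, tolerance = 1) {
  p <- nearest_prior(pplat$time, peep$time, peep$value, tolerance)
  dp <- pplat$value - p
  bad <- !is.na(dp) & dp < 0
  if (any(bad)) {
    warning("skipping ", sum(bad), " driving-pressure point(s) < 0")
    dp[bad] <- NA_real_
  }
  ok <- !is.na(dp)
  data.frame(time = pplat$time[ok], value = dp[ok])
}

#' Derive respiratory system compliance from driving pressure and tidal volume
#'
#' @param dp_series Driving-pressure series (see [derive_dp()]).
#' @param tv Tidal-volume series, mL.
#' @inheritParams derive_pf
#' @return Series data.frame of C_RS = TV / driving pressure, mL/cmH2O;
#'   points with driving pressure of 0 or less are skipped with a warning.
#' @export
derive_crs <- function(dp_series, tv, tolerance = 1) {
  v <- nearest_prior(dp_series$time, tv$time, tv$value, tolerance)
  bad <- dp_series$value <= 0 & !is.na(v)
  if (any(bad)) warning("skipping ", sum(bad), " C_RS point(s) with dP <= 0")
  ok <- !is.na(v) & dp_series$value > 0
  data.frame(time = dp_series$time[ok], value = v[ok] / dp_series$value[ok])
}

# cohort-level derivation helpers over the long measurement table ----------

series_of <- function(meas, var) {
  s <- meas[meas$variable == var, c("stay_id", "time", "value")]
  s[order(s$stay_id, s$time), ]
}

derive_cohort_pair <- function(meas, primary_var, partner_var, fun,
                               tolerance = 1) {
  p <- series_of(meas, primary_var)
  q <- series_of(meas, partner_var)
  qs <- split(q[c("time", "value")], q$stay_id)
  parts <- lapply(split(p, p$stay_id), function(d) {
    id <- as.character(d$stay_id[1])
    partner <- qs[[id]]
    if (is.null(partner)) return(NULL)
    out <- fun(d[c("time", "value")], partner, tolerance)
    if (nrow(out)) cbind(stay_id = d$stay_id[1], out) else NULL
  })
  out <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1))])
  if (!nrow(out))
    return(data.frame(stay_id = integer(0), time = numeric(0),
                      value = numeric(0)))
  as.data.frame(out)
}

#' Cohort-level derived-parameter tables
#'
#' Apply [derive_pf()], [derive_dp()] and [derive_crs()] per stay over a
#' long measurement table (`stay_id`, `time`, `variable`, `value`).
#'
#' @param meas Long measurement table.
#' @param tolerance Nearest-measurement tolerance in hours.
#' @return Long table of the derived variable.
#' @export
derive_pf_cohort <- function(meas, tolerance = 1) {
  derive_cohort_pair(meas, "pao2", "fio2", derive_pf, tolerance)
}

#' @rdname derive_pf_cohort
#' @export
derive_dp_cohort <- function(meas, tolerance = 1) {
  derive_cohort_pair(meas, "pplat", "peep", derive_dp, tolerance)
}

#' @rdname derive_pf_cohort
#' @export
derive_crs_cohort <- function(meas, tolerance = 1) {
  dp <- derive_dp_cohort(meas, tolerance)
  dp$variable <- "driving_pressure"
  m2 <- rbind(meas[meas$variable == "tidal_volume",
                   c("stay_id", "time", "variable", "value")],
              dp[, c("stay_id", "time", "variable", "value")])
  derive_cohort_pair(m2, "driving_pressure", "tidal_volume", derive_crs,
                     tolerance)
}

#' Append derived parameters to a measurement table
#'
#' Adds `pf`, `driving_pressure` and `crs` rows derived from PaO2/FiO2,
#' Pplat/PEEP and driving pressure/tidal volume.
#'
#' @inheritParams derive_pf_cohort
#' @return The measurement table with derived rows appended.
#' @export
derive_parameters <- function(meas, tolerance = 1) {
  add <- list(pf = derive_pf_cohort(meas, tolerance),
              driving_pressure = derive_dp_cohort(meas, tolerance),
              crs = derive_crs_cohort(meas, tolerance))
  for (v in names(add)) if (nrow(add[[v]])) add[[v]]$variable <- v
  out <- rbind(meas[, c("stay_id", "time", "variable", "value")],
               do.call(rbind, lapply(add, function(d)
                 d[, c("stay_id", "time", "variable", "value")])))
  out <- out[order(out$stay_id, out$time, out$variable), ]
  rownames(out) <- NULL
  out
}

# windowed sampling ---------------------------------------------------------

#' Windowed last-observation-carried-forward sample
#'
#' Returns the most recent point of a series within the closed window
#' `[anchor - window, anchor]`; the anchor measurement itself counts as
#' pre-switch.
#'
#' @param series Series data.frame (`time`, `value`).
#' @param anchor Anchor time in hours (e.g. the switch attempt).
#' @param window Lookback in hours (default 12).
#' @return list(`value`, `time`) or `NULL` when no point falls in the
#'   window.
#' @export
locf_sample <- function(series, anchor, window = 12) {
  ok <- series$time >= anchor - window - 1e-9 & series$time <= anchor + 1e-9
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.max(series$time[ok])]
  list(value = series$value[i], time = series$time[i])
}

#' Change in a variable over a post-switch horizon
#'
#' Delta = most recent value in `(anchor, anchor + horizon]` minus the
#' windowed-LOCF pre value; positive means an increase after the switch.
#' Missing when either side is unavailable.
#'
#' @inheritParams locf_sample
#' @param horizon Post-switch horizon in hours (default 3).
#' @return Numeric delta, or `NA` when either side is missing.
#' @export
delta_sample <- function(series, anchor, horizon = 3, window = 12) {
  pre <- locf_sample(series, anchor, window)
  if (is.null(pre)) return(NA_real_)
  ok <- series$time > anchor + 1e-9 & series$time <= anchor + horizon + 1e-9
  if (!any(ok)) return(NA_real_)
  i <- which(ok)[which.max(series$time[ok])]
  series$value[i] - pre$value
}

#' Pre-switch feature matrix by windowed LOCF
#'
#' One row per anchor (stay), one column per variable, plus
#' `<variable>_time` columns recording the measurement times.
#'
#' @param meas Long measurement table (`stay_id`, `time`, `variable`,
#'   `value`), typically after [derive_parameters()].
#' @param anchors data.frame (`stay_id`, `time`) of anchor times.
#' @param variables Character vector of variables to extract (default: all
#'   in `meas`).
#' @param window Lookback in hours (default 12).
#' @return data.frame of features (NA = missing).
#' @export
extract_features <- function(meas, anchors, variables = NULL, window = 12) {
  if (is.null(variables)) variables <- sort(unique(meas$variable))
  dt <- data.table::as.data.table(meas)
  dt <- dt[dt$variable %in% variables & dt$time >= 0]
  q <- data.table::data.table(stay_id = anchors$stay_id,
                              time = anchors$time + 1e-9)
  out <- data.frame(stay_id = anchors$stay_id, anchor_time = anchors$time)
  for (v in variables) {
    dv <- dt[dt$variable == v]
    dv$mtime <- dv$time
    data.table::setkey(dv, stay_id, time)
    hit <- dv[q, on = c("stay_id", "time"), roll = window + 2e-9]
    out[[v]] <- hit$value
    out[[paste0(v, "_time")]] <- hit$mtime
  }
  out
}

#' Post-switch delta matrix
#'
#' Delta-horizon changes per variable: latest value in
#' `(anchor, anchor + horizon]` minus the windowed-LOCF pre value.
#'
#' @inheritParams extract_features
#' @param horizon Post-switch horizon in hours (default 3).
#' @return data.frame, one `delta_<variable>` column per variable.
#' @export
extract_deltas <- function(meas, anchors, variables = NULL, horizon = 3,
                           window = 12) {
  if (is.null(variables)) variables <- sort(unique(meas$variable))
  pre <- extract_features(meas, anchors, variables, window)
  dt <- data.table::as.data.table(meas)
  dt <- dt[dt$variable %in% variables]
  out <- data.frame(stay_id = anchors$stay_id, anchor_time = anchors$time,
                    horizon = horizon)
  # roll backwards from anchor+horizon, then reject hits at or before anchor
  q <- data.table::data.table(stay_id = anchors$stay_id,
                              time = anchors$time + horizon + 1e-9)
  for (v in variables) {
    dv <- dt[dt$variable == v]
    dv$mtime <- dv$time
    data.table::setkey(dv, stay_id, time)
    hit <- dv[q, on = c("stay_id", "time"), roll = horizon]
    post <- hit$value
    post[!is.na(post) & hit$mtime <= anchors$time + 1e-9] <- NA
    out[[paste0("delta_", v)]] <- post - pre[[v]]
  }
  out
}

#' Variable inclusion by availability
#'
#' Before-switch stage: keep variables observed in more than one-third of
#' patients (i.e. missing for fewer than two-thirds). After-switch stage:
#' keep variables whose delta is available for at least one-third of
#' patients (inclusive).
#'
#' @param availability Logical matrix or data.frame, one row per patient,
#'   one column per variable; `TRUE` = observed.
#' @param stage `"before"` or `"after"`.
#' @param threshold Fraction threshold (default 2/3 missing for before,
#'   1/3 available for after).
#' @return Character vector of retained variable names.
#' @export
select_variables <- function(availability, stage = c("before", "after"),
                             threshold = NULL) {
  stage <- match.arg(stage)
  av <- as.matrix(as.data.frame(availability))
  frac_obs <- colMeans(av)
  if (stage == "before") {
    thr <- if (is.null(threshold)) 2 / 3 else threshold
    names(frac_obs)[1 - frac_obs < thr - 1e-12]
  } else {
    thr <- if (is.null(threshold)) 1 / 3 else threshold
    names(frac_obs)[frac_obs >= thr - 1e-12]
  }
}

#' Per-variable missingness by outcome group
#'
#' @param features Feature (or delta) data.frame, one row per stay.
#' @param outcome Vector of outcome labels aligned with `features` rows.
#' @param variables Variables to report on.
#' @return data.frame (`variable`, `pct_missing_success`,
#'   `pct_missing_failure`), percentages in 0-100.
#' @export
missingness_report <- function(features, outcome, variables) {
  succ <- outcome == "SUCCESS"
  data.frame(
    variable = variables,
    pct_missing_success = vapply(variables, function(v)
      100 * mean(is.na(features[[v]][succ])), numeric(1)),
    pct_missing_failure = vapply(variables, function(v)
      100 * mean(is.na(features[[v]][!succ])), numeric(1)),
    row.names = NULL)
}

#' Stays retained for a delta-horizon analysis
#'
#' Patients who failed the switch or were liberated from mechanical
#' ventilation within the horizon are excluded: a stay is retained only if
#' it is still in assisted mode at `attempt + horizon`.
#'
#' @param attempts Labeled first-attempt data.frame (one row per stay, with
#'   `time`, `outcome`, `failure_time`).
#' @param extubation_time Named or aligned vector of invasive-ventilation
#'   end times (hours) for the attempts' stays.
#' @param horizon Post-switch horizon in hours (default 3).
#' @return Logical vector: retained rows of `attempts`.
#' @export
exclusion_for_delta <- function(attempts, extubation_time, horizon = 3) {
  not_failed_yet <- attempts$outcome == "SUCCESS" |
    (!is.na(attempts$failure_time) &
       attempts$failure_time > attempts$time + horizon)
  still_ventilated <- extubation_time > attempts$time + horizon
  not_failed_yet & still_ventilated
}
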