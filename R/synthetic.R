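# Synthetic multi-center ICU event-log generator with known ground truth.
# Emulates three centers with different mode-label dialects and logging
# frequencies, per-variable missingness, a latent switch-readiness process,
# a logistic failure mechanism on true pre-switch features, and a lognormal
# time-to-failure. All times are hours since ICU admission; intervals are
# half-open [start, end).

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# variable -> logging group
vs_variable_groups <- function() {
  c(pao2 = "blood_gas", paco2 = "blood_gas", ph = "blood_gas",
    base_excess = "blood_gas", lactate = "blood_gas", hco3 = "blood_gas",
    fio2 = "vent", peep = "vent", pplat = "vent", tidal_volume = "vent",
    resp_rate = "vent", spont_rr = "vent", minute_volume = "vent",
    ppeak = "vent",
    spo2 = "vitals", heart_rate = "vitals", map = "vitals",
    temperature = "vitals",
    wbc = "labs")
}

default_logging_intervals <- function() {
  list(
    center_1 = c(blood_gas = 4, vent = 1, vitals = 1, labs = 24, mode = 4),
    center_2 = c(blood_gas = 6, vent = 2, vitals = 1, labs = 24, mode = 6),
    center_3 = c(blood_gas = 4, vent = 2, vitals = 2, labs = 24, mode = 8)
  )
}

default_missingness <- function() {
  c(pao2 = 0.09, paco2 = 0.09, ph = 0.20, base_excess = 0.09,
    lactate = 0.34, hco3 = 0.17, fio2 = 0, peep = 0.02, pplat = 0.50,
    tidal_volume = 0.30, resp_rate = 0, spont_rr = 0.10,
    minute_volume = 0.11, ppeak = 0, spo2 = 0, heart_rate = 0.11,
    map = 0.23, temperature = 0.23, wbc = 0.28)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the analyses assume: a first switch
#' attempt at a lognormal readiness time (median about 1.45 days), a
#' logistic failure mechanism acting on true (noise-free) pre-switch
#' PaO2/FiO2, PEEP, base excess, lactate and driving pressure with a
#' marginal failure rate near two-thirds, a lognormal time-to-failure with
#' median 8 h (IQR about 4-19 h) truncated to [1, 72] h, and 28-day
#' mortality near 16% after success and 27% after failure.
#'
#' @param n_patients Number of ICU stays to generate.
#' @param n_centers Number of centers (default 3; must not exceed the number
#'   of supplied dialects).
#' @param mode_dialects Named list of dialect data.frames, one per center.
#' @param logging_interval_hours Named list per center of positive logging
#'   intervals (hours) for groups `blood_gas`, `vent`, `vitals`, `labs`,
#'   `mode`.
#' @param missingness_rates Named per-variable probabilities in `[0, 1]` of
#'   dropping each scheduled measurement.
#' @param readiness_dist `c(meanlog, sdlog)` of the lognormal
#'   switch-readiness time in days.
#' @param premature_attempt_prob Probability that the attempt is made before
#'   readiness (at a uniform fraction 0.3-0.7 of the readiness time).
#' @param no_attempt_prob Probability that a stay never attempts a switch.
#' @param failure_coefficients Named coefficients (`intercept`, `pf`,
#'   `peep`, `base_excess`, `lactate`, `dp`) of the logistic failure
#'   mechanism on standardized true pre-switch features.
#' @param ttf_dist `c(meanlog, sdlog)` of the lognormal time-to-failure in
#'   hours, truncated to `[1, 72]`.
#' @param mortality_model List with `base_logit` (28-day death log-odds
#'   after a successful switch), `failure_shift` and `no_switch_shift`
#'   (log-odds shifts for failed attempts and the no-switch group).
#' @param generate_measurements If `FALSE`, skip the measurement table
#'   (mode/airway/ground-truth generation is unchanged); useful when only
#'   attempt timing and outcomes are needed.
#' @param seed Integer seed; identical configs give byte-identical cohorts.
#' @return A list of class `vs_config`.
#' @export
cohort_config <- function(n_patients,
                          n_centers = 3,
                          mode_dialects = default_dialects(),
                          logging_interval_hours = default_logging_intervals(),
                          missingness_rates = default_missingness(),
                          readiness_dist = c(meanlog = log(1.45), sdlog = 0.75),
                          premature_attempt_prob = 0.10,
                          no_attempt_prob = 0.08,
                          failure_coefficients = c(intercept = 1.30,
                                                   pf = -0.25, peep = 0.15,
                                                   base_excess = -0.20,
                                                   lactate = 0.30, dp = 0.20),
                          ttf_dist = c(meanlog = log(8), sdlog = 1.15),
                          mortality_model = list(
                            base_logit = stats::qlogis(0.16),
                            failure_shift = stats::qlogis(0.27) - stats::qlogis(0.16),
                            no_switch_shift = stats::qlogis(0.82) - stats::qlogis(0.16)),
                          generate_measurements = TRUE,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, n_centers = n_centers,
              mode_dialects = mode_dialects,
              logging_interval_hours = logging_interval_hours,
              missingness_rates = missingness_rates,
              readiness_dist = readiness_dist,
              premature_attempt_prob = premature_attempt_prob,
              no_attempt_prob = no_attempt_prob,
              failure_coefficients = failure_coefficients,
              ttf_dist = ttf_dist, mortality_model = mortality_model,
              generate_measurements = generate_measurements,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "vs_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$missingness_rates, cfg$premature_attempt_prob,
             cfg$no_attempt_prob)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$n_patients < 0)
    stop("configuration error: n_patients must be >= 0")
  if (cfg$n_centers < 1 || cfg$n_centers > length(cfg$mode_dialects))
    stop("configuration error: n_centers must be in 1..length(mode_dialects)")
  ints <- unlist(cfg$logging_interval_hours)
  if (any(ints <= 0))
    stop("configuration error: logging intervals must be positive")
  lapply(cfg$mode_dialects, validate_dialect)
  invisible(cfg)
}

# fixed standardization constants of the failure mechanism
feature_z <- function(pf, peep, be, lactate, dp) {
  cbind(pf = (pf - 210) / 55,
        peep = (peep - 8) / 2.5,
        base_excess = be / 3,
        lactate = (log(lactate) - log(1.7)) / 0.4,
        dp = (dp - 12) / 3)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

sample_labels <- function(dialect, category, n) {
  pool <- dialect$raw_label[dialect$category == category]
  pool[sample.int(length(pool), n, replace = TRUE)]
}

empty_cohort <- function() {
  list(
    stays = data.frame(stay_id = integer(), center = character(),
                       admission_time = numeric(), discharge_time = numeric(),
                       death_time = numeric(), first_stay = logical(),
                       age_group = character(), sex = character(),
                       apache2 = numeric(), saps2 = numeric()),
    mode_events = data.frame(stay_id = integer(), time = numeric(),
                             raw_label = character()),
    airway_events = data.frame(stay_id = integer(), time = numeric(),
                               event = character()),
    measurements = data.frame(stay_id = integer(), time = numeric(),
                              variable = character(), value = numeric()),
    ground_truth = data.frame(stay_id = integer(), center = character(),
                              true_attempt_time = numeric(),
                              true_outcome = character(),
                              true_failure_time = numeric(),
                              true_failure_cause = character(),
                              true_failure_probability = numeric(),
                              pf_true = numeric(), peep_true = numeric(),
                              base_excess_true = numeric(),
                              lactate_true = numeric(), dp_true = numeric()),
    truth_segments = data.frame(stay_id = integer(), start = numeric(),
                                end = numeric(), category = character())
  )
}

#' Generate a synthetic multi-center ICU cohort
#'
#' Each stay is intubated at t = 0 in a controlled-category raw mode of its
#' center's dialect. A latent severity improves over the stay; the true
#' pre-switch features are evaluated at the attempt time, the attempt's
#' outcome is drawn from the logistic failure mechanism on those features,
#' and failures return to controlled ventilation (or die) after a truncated
#' lognormal delay within 72 h. Measurements are sampled on each center's
#' logging grid, centered on the patient trajectory, and thinned by
#' per-variable missingness. Mode changes are always logged at the change
#' time and re-logged on the center's mode-logging grid.
#'
#' @param config A `vs_config` from [cohort_config()].
#' @return A list of class `vs_cohort` with data.frames `stays`,
#'   `mode_events`, `airway_events`, `measurements`, `ground_truth`, and the
#'   internal `truth_segments` (the generator's true category timeline,
#'   kept for validation).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' coh$ground_truth
generate_cohort <- function(config) {
  validate_config(config)
  n <- config$n_patients
  if (n == 0) return(structure(empty_cohort(), class = c("vs_cohort", "list")))
  set.seed(config$seed)

  centers <- names(config$mode_dialects)[seq_len(config$n_centers)]
  center <- sample(centers, n, replace = TRUE)
  sev0 <- stats::rnorm(n)
  recov <- 0.35  # severity decline per day

  no_attempt <- stats::runif(n) < config$no_attempt_prob
  readiness_d <- stats::rlnorm(n, config$readiness_dist[["meanlog"]],
                               config$readiness_dist[["sdlog"]])
  premature <- stats::runif(n) < config$premature_attempt_prob
  attempt_d <- readiness_d * ifelse(premature, stats::runif(n, 0.3, 0.7), 1)
  attempt_h <- pmax(1.5, attempt_d * 24)
  sev_att <- sev0 - recov * attempt_h / 24 + stats::rnorm(n, 0, 0.3)

  # true pre-switch features (noise-free w.r.t. measurement error)
  pf <- clamp(200 * exp(-0.20 * sev_att + stats::rnorm(n, 0, 0.22)), 60, 520)
  fio2 <- clamp(40 * exp(0.12 * sev_att + stats::rnorm(n, 0, 0.12)), 25, 90)
  peep <- clamp(round(8 + 2.0 * sev_att + stats::rnorm(n, 0, 1.8)), 4, 18)
  be <- 0.5 - 1.8 * sev_att + stats::rnorm(n, 0, 1.6)
  lactate <- clamp(exp(log(1.7) + 0.28 * sev_att + stats::rnorm(n, 0, 0.30)),
                   0.4, 15)
  dp <- clamp(12 * exp(0.10 * sev_att + stats::rnorm(n, 0, 0.13)), 5, 28)

  fc <- config$failure_coefficients
  z <- feature_z(pf, peep, be, lactate, dp)
  logit_fail <- fc[["intercept"]] +
    z %*% fc[c("pf", "peep", "base_excess", "lactate", "dp")]
  p_fail <- as.vector(stats::plogis(logit_fail))
  fail <- stats::runif(n) < p_fail
  fail[no_attempt] <- NA

  ttf <- rlnorm_trunc(n, config$ttf_dist[["meanlog"]],
                      config$ttf_dist[["sdlog"]], 1, 72)

  mm <- config$mortality_model
  logit_death <- mm$base_logit +
    ifelse(!no_attempt & !is.na(fail) & fail, mm$failure_shift, 0) +
    ifelse(no_attempt, mm$no_switch_shift, 0)
  mort28 <- stats::runif(n) < stats::plogis(logit_death)
  fail_by_death <- !no_attempt & !is.na(fail) & fail & mort28 &
    stats::runif(n) < 0.35

  # per-stay true mode schedule: times/categories of category changes,
  # extubation and death
  sid <- seq_len(n)
  sched <- vector("list", n)
  extub <- numeric(n)
  death <- rep(NA_real_, n)
  n_sec <- ifelse(!no_attempt & !is.na(fail) & fail & !fail_by_death,
                  pmin(stats::rpois(n, 2.3), 5L), 0L)
  for (i in sid) {
    if (no_attempt[i]) {
      extub[i] <- pmax(50, stats::rlnorm(1, log(120), 0.5))
      sched[[i]] <- list(time = 0, category = "CONTROLLED")
      next
    }
    a <- attempt_h[i]
    tms <- c(0, a); cats <- c("CONTROLLED", "ASSISTED")
    if (!fail[i]) {
      extub[i] <- a + pmax(2, stats::rlnorm(1, log(40), 0.6))
    } else if (fail_by_death[i]) {
      death[i] <- a + ttf[i]
      extub[i] <- death[i]
    } else {
      f1 <- a + ttf[i]
      tms <- c(tms, f1); cats <- c(cats, "CONTROLLED")
      t <- f1
      k <- n_sec[i]
      if (k == 0L) {
        extub[i] <- f1 + pmax(2, stats::rlnorm(1, log(72), 0.6))
      } else {
        for (j in seq_len(k)) {
          t <- t + pmax(1.5, stats::rlnorm(1, log(12), 0.8))
          tms <- c(tms, t); cats <- c(cats, "ASSISTED")
          if (j < k) {
            t <- t + pmax(1.5, stats::rlnorm(1, log(10), 0.9))
            tms <- c(tms, t); cats <- c(cats, "CONTROLLED")
          } else {
            extub[i] <- t + pmax(2, stats::rlnorm(1, log(48), 0.6))
          }
        }
      }
    }
    sched[[i]] <- list(time = tms, category = cats)
  }

  # deaths for the remaining 28-day deaths, placed so they cannot relabel
  # the first attempt (success deaths after attempt + 72 h)
  for (i in sid) {
    if (!mort28[i] || !is.na(death[i])) next
    if (no_attempt[i]) {
      death[i] <- stats::runif(1, 24, min(extub[i] + 48, 671))
    } else if (!fail[i]) {
      lo <- min(max(attempt_h[i] + 72.5, extub[i]), 660)
      death[i] <- stats::runif(1, lo, 672)
    } else {
      lo <- min(attempt_h[i] + ttf[i] + 1, 660)
      death[i] <- stats::runif(1, lo, 672)
    }
  }

  # truncate schedules at death; close stays
  extub_actual <- ifelse(!is.na(death), pmin(extub, death), extub)
  discharge <- extub_actual + pmax(4, stats::rlnorm(n, log(36), 0.6))
  discharge <- ifelse(!is.na(death) & death <= discharge, death, discharge)

  truth_list <- vector("list", n)
  mode_list <- vector("list", n)
  for (i in sid) {
    keep <- sched[[i]]$time < extub_actual[i]
    tms <- sched[[i]]$time[keep]; cats <- sched[[i]]$category[keep]
    truth_list[[i]] <- list(stay_id = rep(i, length(tms)), start = tms,
                            end = c(tms[-1], extub_actual[i]),
                            category = cats)
    # mode log: change events plus grid re-logs of the active category
    mint <- config$logging_interval_hours[[center[i]]][["mode"]]
    grid <- if (extub_actual[i] >= mint)
      seq(mint, extub_actual[i], by = mint) else numeric(0)
    gcat <- cats[findInterval(grid, tms)]
    mode_list[[i]] <- list(stay_id = rep(i, length(tms) + length(grid)),
                           time = c(tms, grid), category = c(cats, gcat))
  }
  truth_segments <- as.data.frame(data.table::rbindlist(truth_list))
  mode_events <- as.data.frame(data.table::rbindlist(mode_list))
  mode_events <- mode_events[order(mode_events$stay_id, mode_events$time), ]
  # raw labels drawn from each center's dialect within the true category
  mode_events$raw_label <- NA_character_
  for (ct in centers) {
    dlt <- config$mode_dialects[[ct]]
    for (cat in c("CONTROLLED", "ASSISTED")) {
      sel <- mode_events$stay_id %in% sid[center == ct] &
        mode_events$category == cat
      if (any(sel)) mode_events$raw_label[sel] <- sample_labels(dlt, cat, sum(sel))
    }
  }
  mode_events$category <- NULL
  rownames(mode_events) <- NULL

  # patients who die while ventilated get no extubation event
  died_on_vent <- !is.na(death) & death <= extub
  airway_events <- rbind(
    data.frame(stay_id = sid, time = 0, event = "intubation"),
    data.frame(stay_id = sid[!died_on_vent], time = extub_actual[!died_on_vent],
               event = "extubation"))
  airway_events <- airway_events[order(airway_events$stay_id,
                                       airway_events$time), ]
  rownames(airway_events) <- NULL

  age_groups <- c("18-39", "40-49", "50-59", "60-69", "70-79", "80+")
  stays <- data.frame(
    stay_id = sid, center = center, admission_time = 0,
    discharge_time = discharge, death_time = death, first_stay = TRUE,
    age_group = sample(age_groups, n, TRUE,
                       prob = c(.09, .09, .17, .21, .21, .12)),
    sex = sample(c("F", "M"), n, TRUE, prob = c(0.37, 0.63)),
    apache2 = clamp(round(stats::rnorm(n, 26, 8)), 2, 60),
    saps2 = clamp(round(stats::rnorm(n, 45, 13)), 5, 110),
    stringsAsFactors = FALSE)

  ground_truth <- data.frame(
    stay_id = sid, center = center,
    true_attempt_time = ifelse(no_attempt, NA_real_, attempt_h),
    true_outcome = ifelse(no_attempt, NA_character_,
                          ifelse(fail, "failure", "success")),
    true_failure_time = ifelse(!no_attempt & !is.na(fail) & fail,
                               attempt_h + ttf, NA_real_),
    true_failure_cause = ifelse(!no_attempt & !is.na(fail) & fail,
                                ifelse(fail_by_death, "death",
                                       "return_to_controlled"),
                                NA_character_),
    true_failure_probability = ifelse(no_attempt, NA_real_, p_fail),
    pf_true = pf, peep_true = peep, base_excess_true = be,
    lactate_true = lactate, dp_true = dp, stringsAsFactors = FALSE)

  measurements <- if (config$generate_measurements) {
    generate_measurements(config, center, sev0, sev_att, attempt_h,
                          no_attempt, fail, extub_actual, discharge,
                          truth_segments,
                          list(pf = pf, fio2 = fio2, peep = peep, be = be,
                               lactate = lactate, dp = dp))
  } else empty_cohort()$measurements

  out <- list(stays = stays, mode_events = mode_events,
              airway_events = airway_events, measurements = measurements,
              ground_truth = ground_truth, truth_segments = truth_segments)
  structure(out, class = c("vs_cohort", "list"))
}

#' @export
print.vs_cohort <- function(x, ...) {
  cat("<vs_cohort>", nrow(x$stays), "stays,", nrow(x$mode_events),
      "mode events,", nrow(x$measurements), "measurements\n")
  invisible(x)
}

# trajectory parameters: value(t) interpolates patient baseline -> true
# pre-switch value, then takes an outcome-dependent post-switch step.
# columns: baseline center, severity loading (multiplicative vars use a
# log-scale loading), measurement noise sd, post-switch step (success, fail)
traj_table <- function() {
  rbind(
    pao2 = c(NA, NA, 0.04, -6.1, -8.5),       # from pf * fio2, mult noise
    paco2 = c(40, 0.05, 0.03, 0.2, 0.8),      # multiplicative
    ph = c(7.37, -0.025, 0.012, -0.001, -0.006),  # additive
    base_excess = c(0.5, -1.8, 0.9, 0.1, -0.1),   # additive
    lactate = c(1.7, 0.28, 0.10, 0.0, 0.1),   # multiplicative
    hco3 = c(23, -1.5, 1.2, 0.0, -0.2),       # additive
    fio2 = c(40, 0.12, 0.05, -1, -1),         # multiplicative
    peep = c(8, 2.0, 0.6, -0.4, -0.2),        # additive, rounded
    pplat = c(NA, NA, 0.8, -2.5, -2.0),       # peep + dp, additive noise
    tidal_volume = c(440, 0, 0.08, 48, 34),   # multiplicative
    resp_rate = c(19, 2.0, 1.8, -1, -1),      # additive, rounded
    minute_volume = c(8.8, 0.05, 0.10, -0.2, -0.5),  # multiplicative
    ppeak = c(NA, NA, 1.2, -3.2, -2.7),       # pplat + 4, additive noise
    spo2 = c(97, -1.0, 1.0, 0, -1),           # additive, rounded
    heart_rate = c(85, 5, 8, 3, 3),           # additive, rounded
    temperature = c(37, 0.15, 0.3, 0.1, 0.1), # additive
    map = c(77, -2, 6, 0, 0),                 # additive, rounded
    wbc = c(12, 0.10, 0.12, 0, 0.05)          # multiplicative
  )
}

generate_measurements <- function(config, center, sev0, sev_att, attempt_h,
                                  no_attempt, fail, extub, stay_end,
                                  truth_segments, feat) {
  n <- length(center)
  groups <- vs_variable_groups()
  mult_vars <- c("paco2", "lactate", "fio2", "minute_volume", "wbc",
                 "tidal_volume")
  int_vars <- c("peep", "resp_rate", "spo2", "heart_rate", "map")
  tt <- traj_table()
  miss <- config$missingness_rates

  res <- vector("list", length(groups))
  idx <- 0L
  for (v in names(groups)) {
    grp <- groups[[v]]
    iv <- vapply(config$logging_interval_hours[center],
                 function(x) x[[grp]], numeric(1))
    horizon <- if (grp == "vent") extub else stay_end
    npts <- pmax(0L, floor(horizon / iv) + 1L)
    stay <- rep(seq_len(n), npts)
    tm <- unlist(lapply(seq_len(n), function(i)
      if (npts[i] > 0) seq(0, by = iv[i], length.out = npts[i]) else numeric(0)))
    if (!length(stay)) next
    frac <- pmin(tm / (attempt_h[stay] * (1 + no_attempt[stay])), 1)
    post <- !no_attempt[stay] & tm > attempt_h[stay]

    if (v == "spont_rr") {
      # spontaneous RR reflects the true current category
      assisted <- truth_category_at(truth_segments, stay, tm) == "ASSISTED"
      val <- stats::runif(length(tm), 0, 6)
      val[assisted] <- stats::runif(sum(assisted), 12, 28)
      val <- round(val)
      keep <- stats::runif(length(tm)) >= miss[["spont_rr"]]
      idx <- idx + 1L
      res[[idx]] <- list(stay_id = stay[keep], time = tm[keep],
                         variable = rep(v, sum(keep)), value = val[keep])
      next
    }
    failed <- !is.na(fail[stay]) & fail[stay]
    step <- numeric(length(tm))
    step[post & failed] <- tt[v, 5]
    step[post & !failed] <- tt[v, 4]
    noise_sd <- tt[v, 3]

    if (v == "pao2") {
      pf_t <- traj_interp(200 * exp(-0.20 * sev0[stay]), feat$pf[stay], frac)
      fio2_t <- traj_interp(40 * exp(0.12 * sev0[stay]), feat$fio2[stay], frac)
      val <- (pf_t + ifelse(post, step, 0) * 2.2) * fio2_t / 100 *
        exp(stats::rnorm(length(tm), 0, noise_sd))
    } else if (v == "pplat") {
      dp_t <- traj_interp(12 * exp(0.10 * sev0[stay]), feat$dp[stay], frac)
      peep_t <- traj_interp(8 + 2.0 * sev0[stay], feat$peep[stay], frac)
      val <- peep_t + dp_t + step + stats::rnorm(length(tm), 0, noise_sd)
    } else if (v == "ppeak") {
      dp_t <- traj_interp(12 * exp(0.10 * sev0[stay]), feat$dp[stay], frac)
      peep_t <- traj_interp(8 + 2.0 * sev0[stay], feat$peep[stay], frac)
      val <- peep_t + dp_t + 4 + step + stats::rnorm(length(tm), 0, noise_sd)
    } else {
      base <- tt[v, 1]; load <- tt[v, 2]
      if (v %in% mult_vars) {
        v0 <- base * exp(load * sev0[stay])
        vatt <- base * exp(load * sev_att[stay])
        # failure-mechanism features hit their exactly-generated values
        if (v == "lactate") vatt <- feat$lactate[stay]
        if (v == "fio2") vatt <- feat$fio2[stay]
        val <- traj_interp(v0, vatt, frac) + step
        val <- pmax(0.05 * base, val * exp(stats::rnorm(length(tm), 0, noise_sd)))
      } else {
        v0 <- base + load * sev0[stay]
        vatt <- base + load * sev_att[stay]
        if (v == "peep") vatt <- feat$peep[stay]
        if (v == "base_excess") vatt <- feat$be[stay]
        val <- traj_interp(v0, vatt, frac) + step +
          stats::rnorm(length(tm), 0, noise_sd)
      }
    }
    if (v %in% int_vars) val <- round(val)
    if (v == "fio2") val <- clamp(val, 21, 100)
    if (v == "spo2") val <- clamp(val, 70, 100)

    keep <- stats::runif(length(tm)) >= (if (v %in% names(miss)) miss[[v]] else 0)
    idx <- idx + 1L
    res[[idx]] <- list(stay_id = stay[keep], time = tm[keep],
                       variable = rep(v, sum(keep)), value = val[keep])
  }
  out <- data.table::rbindlist(res[seq_len(idx)])
  data.table::setorder(out, stay_id, time, variable)
  as.data.frame(out)
}

traj_interp <- function(v0, v1, frac) v0 + (v1 - v0) * frac

# category of the true timeline at (stay, time) pairs
truth_category_at <- function(truth_segments, stay, time) {
  dt <- data.table::as.data.table(truth_segments)
  q <- data.table::data.table(stay_id = stay, start = time,
                              ord = seq_along(stay))
  data.table::setkey(dt, stay_id, start)
  res <- dt[q, on = c("stay_id", "start"), roll = Inf]
  res$category[order(res$ord)]
}

#' Replace logged modes with combined-category labels
#'
#' Replaces a fraction of the controlled/assisted mode records of a cohort
#' with combined-category labels from the same center's dialect, emitting a
#' spontaneous-respiratory-rate measurement at each injected record that is
#' consistent with the ground-truth category (spontaneous RR > 10 where the
#' truth is assisted, <= 10 where controlled). Downstream combined-mode
#' reassignment can then recover the original categories.
#'
#' @param cohort A `vs_cohort`.
#' @param fraction Fraction in `[0, 1]` of mode records to replace.
#' @param config The `vs_config` the cohort was generated with (supplies the
#'   dialects).
#' @param seed Integer seed for the record selection.
#' @return The modified `vs_cohort`.
#' @export
inject_combined_modes <- function(cohort, fraction, config, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be a probability in [0, 1]")
  if (fraction == 0) return(cohort)
  set.seed(seed)
  me <- cohort$mode_events
  ctr <- cohort$stays$center[match(me$stay_id, cohort$stays$stay_id)]
  pick <- stats::runif(nrow(me)) < fraction
  if (!any(pick)) return(cohort)
  truth <- truth_category_at(cohort$truth_segments, me$stay_id[pick],
                             me$time[pick])
  for (ct in unique(ctr[pick])) {
    sel <- pick & ctr == ct
    me$raw_label[sel] <- sample_labels(config$mode_dialects[[ct]],
                                       "COMBINED", sum(sel))
  }
  rr <- ifelse(truth == "ASSISTED",
               round(stats::runif(sum(pick), 12, 28)),
               round(stats::runif(sum(pick), 0, 6)))
  add <- data.frame(stay_id = me$stay_id[pick], time = me$time[pick],
                    variable = "spont_rr", value = rr,
                    stringsAsFactors = FALSE)
  meas <- rbind(cohort$measurements, add)
  meas <- meas[order(meas$stay_id, meas$time, meas$variable), ]
  rownames(meas) <- NULL
  cohort$mode_events <- me
  cohort$measurements <- meas
  cohort
}

#' Simulate a cohort for PEEP-interaction testing
#'
#' Draws per-patient PEEP (defining the strata), a standardized continuous
#' variable, a center with a random intercept, and a Bernoulli switch-success
#' outcome from a logistic model with optional stratum-specific slopes.
#' Used to calibrate [interaction_test()] under the null (all `interaction`
#' terms zero) and to measure its power against planted effects.
#'
#' @param n Number of patients.
#' @param beta_value Common slope of the variable.
#' @param interaction Length-2 numeric: additional slope in the 6-10 and
#'   > 10 cmH2O PEEP strata (zero = no effect modification).
#' @param stratum_props Sampling proportions of the three PEEP strata.
#' @param stratum_effects Additive stratum log-odds (first stratum is
#'   reference).
#' @param n_centers,center_sd Number of centers and SD of the center random
#'   intercept.
#' @param base_logit Intercept (log-odds of success in the reference
#'   stratum).
#' @param seed Integer seed.
#' @return data.frame with `success`, `value`, `peep`, `center`.
#' @export
simulate_interaction_cohort <- function(n, beta_value = 0.2,
                                        interaction = c(0, 0),
                                        stratum_props = c(0.3, 0.5, 0.2),
                                        stratum_effects = c(0, 0.1, 0.2),
                                        n_centers = 3, center_sd = 0.3,
                                        base_logit = -0.7, seed = 1L) {
  set.seed(seed)
  stratum <- sample.int(3, n, replace = TRUE, prob = stratum_props)
  peep <- c(3, 6, 11)[stratum] +
    stats::rbinom(n, size = c(2, 4, 5)[stratum], prob = 0.5)
  value <- stats::rnorm(n)
  center <- sample.int(n_centers, n, replace = TRUE)
  ceff <- stats::rnorm(n_centers, 0, center_sd)[center]
  slope <- beta_value + c(0, interaction)[stratum]
  p <- stats::plogis(base_logit + stratum_effects[stratum] +
                       slope * value + ceff)
  data.frame(success = stats::rbinom(n, 1, p), value = value, peep = peep,
             center = paste0("center_", center))
}
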