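# End-to-end orchestration: synthetic or user-supplied event tables ->
# harmonize -> detect/label -> features -> endpoints -> group comparisons ->
# prediction, with CSV/JSON outputs and a plain-text log.

#' Pipeline run configuration
#'
#' All thresholds of the analysis are defaults here, never hard-coded
#' downstream, so sensitivity to each is testable.
#'
#' @param input_dir Directory of input CSVs (see [read_cohort()]); mutually
#'   exclusive with `synthetic` and `cohort`.
#' @param synthetic A `vs_config` for [generate_cohort()].
#' @param cohort An already-built `vs_cohort` (e.g. after
#'   [inject_combined_modes()]).
#' @param dialects Named list of mode dialects keyed by center.
#' @param persistence_hours Minimum persistence of a mode transition (1).
#' @param horizon_hours Outcome follow-up horizon (72).
#' @param locf_window_hours Pre-switch LOCF window (12).
#' @param delta_horizons Post-switch delta horizon(s), ascending (3).
#' @param rr_threshold Spontaneous-RR threshold for combined-mode
#'   reassignment (10 breaths/min).
#' @param before_missing_exclude Exclude a before-switch variable when
#'   missing for at least this fraction of patients (2/3).
#' @param after_include_min Include a delta variable when available for at
#'   least this fraction of patients (1/3).
#' @param peep_breaks Inner PEEP cut points for stratification (5, 10).
#' @param analyses Named logical toggles: `baseline`, `before`, `after`,
#'   `predict`.
#' @param folds Outer/inner CV folds for prediction (5).
#' @param seed Integer seed.
#' @return list of class `vs_run_config`.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL,
                       cohort = NULL,
                       dialects = default_dialects(),
                       persistence_hours = 1, horizon_hours = 72,
                       locf_window_hours = 12, delta_horizons = 3,
                       rr_threshold = 10, before_missing_exclude = 2 / 3,
                       after_include_min = 1 / 3, peep_breaks = c(5, 10),
                       analyses = c(baseline = TRUE, before = TRUE,
                                    after = TRUE, predict = TRUE),
                       folds = 5, seed = 1L) {
  thr <- c(persistence_hours, horizon_hours, locf_window_hours,
           delta_horizons, rr_threshold)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (is.unsorted(delta_horizons))
    stop("delta_horizons must be sorted ascending")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 cohort = cohort,
                 dialects = dialects, persistence_hours = persistence_hours,
                 horizon_hours = horizon_hours,
                 locf_window_hours = locf_window_hours,
                 delta_horizons = delta_horizons,
                 rr_threshold = rr_threshold,
                 before_missing_exclude = before_missing_exclude,
                 after_include_min = after_include_min,
                 peep_breaks = peep_breaks, analyses = analyses,
                 folds = folds, seed = as.integer(seed)),
            class = "vs_run_config")
}

#' Read / write cohort event tables as CSV
#'
#' The on-disk contract is five CSVs: `stays.csv`, `mode_events.csv`,
#' `airway_events.csv`, `measurements.csv` and (for synthetic cohorts)
#' `ground_truth.csv`. FiO2 values of 1.0 or less are treated as fractions
#' and converted to percent on ingest, with a warning.
#'
#' @param dir Directory.
#' @return `read_cohort()` returns a `vs_cohort` list.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  need <- c("stays.csv", "mode_events.csv", "airway_events.csv",
            "measurements.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) stop("missing input file: ", f)
  }
  coh <- list(stays = rd("stays.csv"), mode_events = rd("mode_events.csv"),
              airway_events = rd("airway_events.csv"),
              measurements = rd("measurements.csv"))
  validate_cohort_tables(coh)
  fi <- coh$measurements$variable == "fio2"
  frac <- fi & coh$measurements$value <= 1
  if (any(frac)) {
    warning(sum(frac), " FiO2 value(s) <= 1 treated as fractions, rescaled",
            " to percent")
    coh$measurements$value[frac] <- coh$measurements$value[frac] * 100
  }
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) coh$ground_truth <- utils::read.csv(gt)
  structure(coh, class = c("vs_cohort", "list"))
}

validate_cohort_tables <- function(coh) {
  schema <- list(
    stays = c("stay_id", "center", "admission_time", "discharge_time",
              "death_time", "first_stay"),
    mode_events = c("stay_id", "time", "raw_label"),
    airway_events = c("stay_id", "time", "event"),
    measurements = c("stay_id", "time", "variable", "value"))
  for (tb in names(schema)) {
    missing_cols <- setdiff(schema[[tb]], names(coh[[tb]]))
    if (length(missing_cols))
      stop(tb, ": missing column(s) ", paste(missing_cols, collapse = ", "))
    if (tb != "stays" && nrow(coh[[tb]]) && any(coh[[tb]]$time < 0))
      stop(tb, ": negative time at row ", which(coh[[tb]]$time < 0)[1])
  }
  invisible(coh)
}

#' @rdname read_cohort
#' @param cohort A `vs_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("stays", "mode_events", "airway_events", "measurements",
              "ground_truth")
  for (tb in intersect(tables, names(cohort)))
    utils::write.csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Read / write a generator configuration as YAML
#'
#' @param config A `vs_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg$mode_dialects <- lapply(cfg$mode_dialects, function(d)
    as.list(stats::setNames(d$category, d$raw_label)))
  cfg$logging_interval_hours <- lapply(cfg$logging_interval_hours, as.list)
  # named numeric vectors serialize as YAML maps
  for (f in c("missingness_rates", "readiness_dist",
              "failure_coefficients", "ttf_dist"))
    cfg[[f]] <- as.list(cfg[[f]])
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$mode_dialects <- lapply(cfg$mode_dialects, function(d)
    data.frame(raw_label = names(d), category = unlist(d, use.names = FALSE),
               stringsAsFactors = FALSE))
  cfg$logging_interval_hours <- lapply(cfg$logging_interval_hours,
                                       function(x) unlist(x))
  cfg$missingness_rates <- unlist(cfg$missingness_rates)
  cfg$readiness_dist <- unlist(cfg$readiness_dist)
  cfg$failure_coefficients <- unlist(cfg$failure_coefficients)
  cfg$ttf_dist <- unlist(cfg$ttf_dist)
  do.call(cohort_config, cfg)
}

# variable groups used for reporting and group contributions
vs_report_groups <- function() {
  list(gas_exchange = c("pf", "pao2", "paco2", "ph", "base_excess",
                        "lactate", "hco3", "fio2", "spo2"),
       ventilatory = c("peep", "pplat", "driving_pressure", "crs",
                       "resp_rate", "minute_volume", "ppeak",
                       "tidal_volume"),
       inflammatory = "wbc",
       other = c("heart_rate", "temperature", "map"))
}

comparison_row <- function(variable, values, group, type = "continuous",
                           continuous_test = "wilcoxon",
                           levels = c("SUCCESS", "FAILURE")) {
  cg <- compare_groups(values, group, type, continuous_test)
  s <- cg$summaries
  lv <- intersect(levels, s$group)
  if (length(lv) != 2) lv <- s$group[1:2]
  out <- data.frame(variable = variable,
                    a = s$summary[s$group == lv[1]],
                    b = s$summary[s$group == lv[2]],
                    n_a = s$n[s$group == lv[1]],
                    n_b = s$n[s$group == lv[2]],
                    test = cg$test, p_value = cg$p_value,
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- c(tolower(lv), paste0("n_", tolower(lv)))
  out
}

baseline_feature_means <- function(meas, variables, window = 24) {
  dt <- data.table::as.data.table(meas)
  dt <- dt[dt$variable %in% variables & dt$time <= window]
  agg <- dt[, list(value = mean(value)), by = c("stay_id", "variable")]
  wide <- data.table::dcast(agg, stay_id ~ variable, value.var = "value")
  as.data.frame(wide)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a cohort, harmonizes the mode logs, detects and
#' labels switch attempts, computes endpoints and cohort-flow counts, and
#' runs the toggled analyses: baseline group comparison, before-switch
#' windowed-LOCF comparison with PEEP-interaction tests, after-switch delta
#' comparison, and LASSO failure prediction. All outputs are CSV/JSON files
#' under `out_dir` plus a plain-text log recording every threshold and the
#' seed; re-running with the same configuration reproduces all outputs.
#'
#' @param config A `vs_run_config` from [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the cohort, phenotyping results, analysis
#'   tables and fitted models.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "vs_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path,
                            append = TRUE, sep = "")
  cat("", file = log_path)
  logf("seed: %d", config$seed)
  for (f in c("persistence_hours", "horizon_hours", "locf_window_hours",
              "rr_threshold", "before_missing_exclude", "after_include_min",
              "folds"))
    logf("%s: %s", f, paste(signif(config[[f]], 6), collapse = ","))
  logf("delta_horizons: %s", paste(config$delta_horizons, collapse = ","))
  logf("peep_breaks: %s", paste(config$peep_breaks, collapse = ","))

  cohort <- if (!is.null(config$cohort)) {
    config$cohort
  } else if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else if (!is.null(config$synthetic)) {
    generate_cohort(config$synthetic)
  } else stop("run_config needs input_dir, synthetic or cohort")

  phen <- phenotype_cohort(cohort, dialects = config$dialects,
                           persistence_hours = config$persistence_hours,
                           horizon_hours = config$horizon_hours,
                           rr_threshold = config$rr_threshold)
  elig_ids <- phen$eligibility$stay_id[phen$eligibility$eligible]
  first <- phen$attempts[phen$attempts$attempt_index == 1 &
                           phen$attempts$stay_id %in% elig_ids, ]
  flow <- flow_counts(phen$eligibility, phen$attempts)
  utils::write.csv(as.data.frame(flow), file.path(out_dir, "cohort_flow.csv"),
                   row.names = FALSE)
  logf("flow: eligible=%d attempted=%d success=%d failure=%d no_switch=%d",
       flow$n_eligible, flow$n_attempted, flow$n_success, flow$n_failure,
       flow$n_no_switch)

  res <- list(cohort = cohort, phenotypes = phen, first_attempts = first,
              flow = flow, config = config)
  if (!nrow(first) || !any(config$analyses)) {
    return(invisible(res))
  }
  group <- first$outcome
  stays <- cohort$stays[match(first$stay_id, cohort$stays$stay_id), ]
  meas <- derive_parameters(
    cohort$measurements[cohort$measurements$stay_id %in% first$stay_id, ])
  endpoints <- compute_endpoints_cohort(stays, phen$timelines)
  res$endpoints <- endpoints

  if (isTRUE(config$analyses[["baseline"]])) {
    base_feat <- baseline_feature_means(
      meas, c("pf", "pao2", "paco2", "ph", "driving_pressure", "crs", "map",
              "lactate"))
    bf <- base_feat[match(first$stay_id, base_feat$stay_id), , drop = FALSE]
    rows <- list(
      comparison_row("female_sex", stays$sex == "F", group, "categorical"),
      comparison_row("apache2", stays$apache2, group),
      comparison_row("saps2", stays$saps2, group),
      comparison_row("mort28", endpoints$mort28, group, "categorical"),
      comparison_row("vfd28", endpoints$vfd28, group),
      comparison_row("mv_days", endpoints$mv_days, group),
      comparison_row("icu_los_days", endpoints$icu_los_days, group),
      comparison_row("time_to_attempt_days", first$time / 24, group))
    for (v in setdiff(names(bf), "stay_id"))
      rows[[length(rows) + 1L]] <- comparison_row(paste0("baseline_", v),
                                                  bf[[v]], group)
    baseline_table <- do.call(rbind, rows)
    utils::write.csv(baseline_table,
                     file.path(out_dir, "baseline_table.csv"),
                     row.names = FALSE)
    res$baseline_table <- baseline_table

    failed <- first[first$outcome == "FAILURE", ]
    curve <- assisted_survival_curve(failed$time_to_failure)
    utils::write.csv(curve, file.path(out_dir, "assisted_fraction_curve.csv"),
                     row.names = FALSE)
    res$curve <- curve
    logf("median time to failure (h): %.2f", attr(curve, "median"))
  }

  anchors <- data.frame(stay_id = first$stay_id, time = first$time)
  all_vars <- setdiff(sort(unique(meas$variable)), "spont_rr")
  features <- extract_features(meas, anchors, all_vars,
                               window = config$locf_window_hours)
  res$features <- features

  if (isTRUE(config$analyses[["before"]])) {
    avail <- !is.na(features[all_vars])
    keep_vars <- select_variables(avail, "before",
                                  threshold = config$before_missing_exclude)
    res$before_variables <- keep_vars
    miss <- missingness_report(features, group, keep_vars)
    rows <- lapply(keep_vars, function(v)
      comparison_row(v, features[[v]], group))
    before_table <- do.call(rbind, rows)
    before_table <- merge(before_table, miss, by = "variable", sort = FALSE)
    utils::write.csv(before_table, file.path(out_dir, "before_table.csv"),
                     row.names = FALSE)
    res$before_table <- before_table

    # PEEP-stratified P/F and compliance with interaction tests; each
    # measurement is paired with its nearest prior PEEP
    peep_series <- series_of(meas, "peep")
    inter <- list()
    for (v in intersect(c("pf", "crs"), keep_vars)) {
      vt <- features[[paste0(v, "_time")]]
      paired_peep <- rep(NA_real_, nrow(features))
      ok <- !is.na(vt)
      sp <- split(seq_len(nrow(features))[ok], features$stay_id[ok])
      for (id in names(sp)) {
        ps <- peep_series[peep_series$stay_id == as.integer(id), ]
        paired_peep[sp[[id]]] <- nearest_prior(vt[sp[[id]]], ps$time,
                                               ps$value, 1)
      }
      it <- try(interaction_test(group == "FAILURE", features[[v]],
                                 paired_peep, stays$center,
                                 breaks = config$peep_breaks), silent = TRUE)
      if (!inherits(it, "try-error")) {
        inter[[v]] <- it
        logf("interaction p (%s by PEEP): %.4f", v, it$p_interaction)
        utils::write.csv(it$strata,
                         file.path(out_dir, paste0("strata_", v, ".csv")),
                         row.names = FALSE)
      }
    }
    res$interactions <- inter
  }

  # extubation time of the invasive interval containing each attempt
  extub <- vapply(seq_len(nrow(first)), function(i) {
    inv <- phen$timelines[[as.character(first$stay_id[i])]]$invasive
    hit <- inv$start <= first$time[i] & inv$end > first$time[i]
    if (any(hit)) inv$end[which(hit)[1]] else max(inv$end)
  }, numeric(1))

  if (isTRUE(config$analyses[["after"]])) {
    h <- config$delta_horizons[1]
    retained <- exclusion_for_delta(first, extub, horizon = h)
    deltas <- extract_deltas(meas, anchors[retained, ], all_vars,
                             horizon = h, window = config$locf_window_hours)
    dcols <- paste0("delta_", all_vars)
    avail <- !is.na(deltas[dcols])
    keep_d <- select_variables(avail, "after",
                               threshold = config$after_include_min)
    res$after_variables <- keep_d
    g2 <- group[retained]
    rows <- lapply(keep_d, function(v)
      comparison_row(v, deltas[[v]], g2, continuous_test = "t"))
    after_table <- do.call(rbind, rows)
    after_table <- merge(after_table, missingness_report(deltas, g2, keep_d),
                         by = "variable", sort = FALSE)
    utils::write.csv(after_table, file.path(out_dir, "after_table.csv"),
                     row.names = FALSE)
    res$after_table <- after_table
    res$deltas <- deltas
    res$delta_retained <- retained
  }

  if (isTRUE(config$analyses[["predict"]])) {
    keep_vars <- if (!is.null(res$before_variables)) res$before_variables
      else all_vars
    y <- group == "FAILURE"
    d1 <- build_design(features[keep_vars], y)
    m1 <- fit_lasso_cv(d1$x, d1$y, folds = config$folds, seed = config$seed)
    pred <- list(model1 = list(auc = m1$auc, auc_se = m1$auc_se,
                               auc_folds = m1$auc_folds))
    res$model1 <- m1
    if (!is.null(res$deltas)) {
      keep_d <- res$after_variables
      d2 <- build_design(cbind(features[res$delta_retained, keep_vars,
                                        drop = FALSE],
                               res$deltas[keep_d]),
                         y[res$delta_retained])
      m2 <- fit_lasso_cv(d2$x, d2$y, folds = config$folds, seed = config$seed)
      pred$model2 <- list(auc = m2$auc, auc_se = m2$auc_se,
                          auc_folds = m2$auc_folds)
      res$model2 <- m2
    }
    groups <- lapply(vs_report_groups(), intersect, x = colnames(d1$x))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    gc <- group_contribution(d1$x, d1$y, groups, folds = config$folds,
                             seed = config$seed)
    pred$group_contribution_model1 <- gc
    res$group_contribution <- gc
    jsonlite::write_json(pred, file.path(out_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    logf("model 1 AUC: %.3f", m1$auc)
    if (!is.null(res$model2)) logf("model 2 AUC: %.3f", res$model2$auc)
  }
  invisible(res)
}

#' Sensitivity analyses over a pipeline run
#'
#' Reruns key comparisons under the study's sensitivity scenarios:
#' restriction to patients surviving at least 72 h after the first attempt,
#' per-center stratification, attempt-type stratification (mode change vs
#' respiratory-rate change), early vs late failure split at the median time
#' to failure, and a delta-horizon sweep from 1 to 8 h.
#'
#' @param res The list returned by [run_pipeline()].
#' @param out_dir Output directory.
#' @param sweep_horizons Delta horizons for the sweep (default 1:8 hours).
#' @return Invisibly, a list of the produced tables.
#' @export
sensitivity_suite <- function(res, out_dir, sweep_horizons = 1:8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  first <- res$first_attempts
  stays <- res$cohort$stays[match(first$stay_id, res$cohort$stays$stay_id), ]
  endpoints <- res$endpoints
  out <- list()

  mk_baseline <- function(idx) {
    if (length(unique(first$outcome[idx])) < 2) return(NULL)
    do.call(rbind, list(
      comparison_row("mort28", endpoints$mort28[idx], first$outcome[idx],
                     "categorical"),
      comparison_row("vfd28", endpoints$vfd28[idx], first$outcome[idx]),
      comparison_row("mv_days", endpoints$mv_days[idx], first$outcome[idx]),
      comparison_row("time_to_attempt_days", first$time[idx] / 24,
                     first$outcome[idx])))
  }

  surv <- is.na(stays$death_time) | stays$death_time > first$time + 72
  out$survivor_baseline <- mk_baseline(which(surv))
  if (!is.null(out$survivor_baseline))
    utils::write.csv(out$survivor_baseline,
                     file.path(out_dir, "survivor_baseline.csv"),
                     row.names = FALSE)

  for (ct in unique(stays$center)) {
    tb <- mk_baseline(which(stays$center == ct))
    if (is.null(tb)) {
      warning("skipping empty or one-class stratum: center ", ct)
      next
    }
    out[[paste0("center_", ct)]] <- tb
    utils::write.csv(tb, file.path(out_dir, paste0("baseline_", ct, ".csv")),
                     row.names = FALSE)
  }

  for (ty in unique(first$attempt_type)) {
    tb <- mk_baseline(which(first$attempt_type == ty))
    if (is.null(tb)) {
      warning("skipping empty or one-class stratum: type ", ty)
      next
    }
    out[[paste0("type_", ty)]] <- tb
    utils::write.csv(tb, file.path(out_dir, paste0("baseline_", ty, ".csv")),
                     row.names = FALSE)
  }

  failed <- which(first$outcome == "FAILURE")
  if (length(failed) >= 2) {
    sp <- split_early_late(first$time_to_failure[failed])
    el <- rep(NA_character_, nrow(first))
    el[failed[sp$early_idx]] <- "early"
    el[failed[sp$late_idx]] <- "late"
    if (length(sp$late_idx)) {
      tb <- do.call(rbind, list(
        comparison_row("mort28", endpoints$mort28[!is.na(el)],
                       el[!is.na(el)], "categorical"),
        comparison_row("vfd28", endpoints$vfd28[!is.na(el)], el[!is.na(el)])))
      out$early_late <- tb
      utils::write.csv(tb, file.path(out_dir, "early_late.csv"),
                       row.names = FALSE)
    }
  }

  # delta-horizon sweep: retained n is non-increasing in the horizon
  meas <- derive_parameters(
    res$cohort$measurements[res$cohort$measurements$stay_id %in%
                              first$stay_id, ])
  anchors <- data.frame(stay_id = first$stay_id, time = first$time)
  extub <- vapply(seq_len(nrow(first)), function(i) {
    inv <- res$phenotypes$timelines[[as.character(first$stay_id[i])]]$invasive
    hit <- inv$start <= first$time[i] & inv$end > first$time[i]
    if (any(hit)) inv$end[which(hit)[1]] else max(inv$end)
  }, numeric(1))
  sweep <- lapply(sweep_horizons, function(h) {
    retained <- exclusion_for_delta(first, extub, horizon = h)
    data.frame(horizon = h, n_retained = sum(retained))
  })
  out$delta_sweep <- do.call(rbind, sweep)
  utils::write.csv(out$delta_sweep, file.path(out_dir, "delta_sweep.csv"),
                   row.names = FALSE)
  invisible(out)
}
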