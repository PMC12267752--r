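# Shared fixtures and independent oracles, all built in code.

# a vs_timeline from parallel vectors; invasive defaults to the full span
mk_timeline <- function(start, end, category,
                        provenance = rep("logged", length(start)),
                        invasive = NULL, stay_id = 1L) {
  if (is.null(invasive))
    invasive <- data.frame(start = min(start), end = max(end))
  ventswitch:::new_timeline(
    stay_id,
    data.frame(start = start, end = end, category = category,
               provenance = provenance, stringsAsFactors = FALSE),
    invasive)
}

mk_series <- function(time, value) data.frame(time = time, value = value)

# brute-force enumeration of the persistence merge rule, working on an
# rle-style (duration, category) representation rebuilt from scratch at
# every iteration: repeatedly flip the leftmost maximal run after the first
# that is shorter than the minimum, then recompute the runs
oracle_persistence <- function(durations, categories, min_duration = 1) {
  repeat {
    r <- rle(categories)
    run_id <- rep(seq_along(r$lengths), r$lengths)
    run_dur <- tapply(durations, run_id, sum)
    short <- which(run_dur < min_duration - 1e-9 &
                     seq_along(run_dur) > 1L)
    if (!length(short)) break
    i <- short[1]
    categories[run_id == i] <- r$values[i - 1]
  }
  r <- rle(categories)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  data.frame(duration = as.numeric(tapply(durations, run_id, sum)),
             category = r$values, stringsAsFactors = FALSE)
}

# independent type-7 quantile from the order-statistics definition
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# a small dense-logging, fully observed generator configuration
dense_config <- function(n, seed = 1L, ...) {
  li <- lapply(default_logging_intervals(), function(x) {
    x[] <- c(1, 0.5, 0.5, 24, 1)
    x
  })
  cohort_config(n_patients = n, logging_interval_hours = li,
                missingness_rates = default_missingness() * 0,
                seed = seed, ...)
}

# match detected first attempts against generator ground truth; returns
# fraction of ground-truth attempts detected at the exact time with the
# correct 72-h label
fidelity <- function(cohort, phen) {
  gt <- cohort$ground_truth
  first <- phen$attempts[phen$attempts$attempt_index == 1, ]
  m <- merge(gt[!is.na(gt$true_attempt_time), ], first, by = "stay_id",
             all.x = TRUE)
  ok <- !is.na(m$time) & abs(m$time - m$true_attempt_time) < 1e-6 &
    m$outcome == toupper(m$true_outcome)
  mean(ok)
}
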