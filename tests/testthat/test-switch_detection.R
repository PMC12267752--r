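# Eligibility, attempt detection, and the 72-hour outcome labeling.

simple_stay <- function(first_stay = TRUE) {
  data.frame(stay_id = 1L, first_stay = first_stay)
}

test_that("eligibility requires hypoxemia, 48 h of MV, controlled start", {
  tl <- mk_timeline(c(0, 40), c(40, 72), c("CONTROLLED", "ASSISTED"))
  ok <- check_eligibility(simple_stay(), tl, mk_series(12, 250))
  expect_true(ok$eligible)
  expect_length(ok$reasons, 0)

  no_hyp <- check_eligibility(simple_stay(), tl, mk_series(c(12, 30),
                                                           c(320, 310)))
  expect_false(no_hyp$eligible)
  expect_equal(no_hyp$reasons, "no_hypoxemia_48h")

  tl_a <- mk_timeline(c(0, 40), c(40, 72), c("ASSISTED", "CONTROLLED"))
  wrong_start <- check_eligibility(simple_stay(), tl_a, mk_series(12, 250))
  expect_true("not_starting_controlled" %in% wrong_start$reasons)

  tl_short <- mk_timeline(0, 30, "CONTROLLED",
                          invasive = data.frame(start = 0, end = 30))
  short <- check_eligibility(simple_stay(), tl_short, mk_series(12, 250))
  expect_true("mv_under_48h" %in% short$reasons)

  later <- check_eligibility(simple_stay(first_stay = FALSE), tl,
                             mk_series(12, 250))
  expect_true("not_first_stay" %in% later$reasons)
})

test_that("attempts are controlled-to-assisted boundaries, in order", {
  tl <- mk_timeline(c(0, 30, 45, 96), c(30, 45, 96, 120),
                    c("CONTROLLED", "ASSISTED", "CONTROLLED", "ASSISTED"))
  a <- detect_attempts(tl)
  expect_equal(a$time, c(30, 96))
  expect_equal(a$attempt_index, 1:2)
  expect_equal(a$attempt_type, c("mode_change", "mode_change"))

  all_ctrl <- mk_timeline(0, 100, "CONTROLLED")
  expect_equal(nrow(detect_attempts(all_ctrl)), 0)

  reassigned <- mk_timeline(c(0, 30), c(30, 60),
                            c("CONTROLLED", "ASSISTED"),
                            provenance = c("logged", "combined_reassigned"))
  expect_equal(detect_attempts(reassigned)$attempt_type, "rr_change")
})

test_that("labeling implements the 72-hour while-alive definition", {
  tl_fail <- mk_timeline(c(0, 30, 38), c(30, 38, 120),
                         c("CONTROLLED", "ASSISTED", "CONTROLLED"))
  a <- detect_attempts(tl_fail)[1, ]
  lab <- label_attempt(a, tl_fail, death_time = NA)
  expect_equal(lab$outcome, "FAILURE")
  expect_equal(lab$failure_cause, "return_to_controlled")
  expect_equal(lab$time_to_failure, 8)

  # liberation alive, no return: success
  tl_succ <- mk_timeline(c(0, 30), c(30, 40), c("CONTROLLED", "ASSISTED"),
                         invasive = data.frame(start = 0, end = 40))
  a <- detect_attempts(tl_succ)[1, ]
  expect_equal(label_attempt(a, tl_succ, death_time = NA)$outcome, "SUCCESS")

  # death on assisted mode within the horizon: failure by death
  lab <- label_attempt(a, tl_succ, death_time = 54)
  expect_equal(lab$outcome, "FAILURE")
  expect_equal(lab$failure_cause, "death")
  expect_equal(lab$time_to_failure, 24)

  # return outside the horizon: success
  tl_late <- mk_timeline(c(0, 30, 110), c(30, 110, 150),
                         c("CONTROLLED", "ASSISTED", "CONTROLLED"))
  a <- detect_attempts(tl_late)[1, ]
  expect_equal(label_attempt(a, tl_late, death_time = NA)$outcome, "SUCCESS")
  # the horizon's right end is closed: a return at exactly +72 h fails
  tl_edge <- mk_timeline(c(0, 30, 102), c(30, 102, 150),
                         c("CONTROLLED", "ASSISTED", "CONTROLLED"))
  a <- detect_attempts(tl_edge)[1, ]
  expect_equal(label_attempt(a, tl_edge, death_time = NA)$outcome, "FAILURE")

  expect_error(label_attempt(a, tl_edge, death_time = 10), "death_time")
})

test_that("extending the horizon can only turn successes into failures", {
  set.seed(55)
  for (rep in 1:40) {
    n <- sample(3:9, 1)
    dur <- runif(n, 1.5, 40)
    cats <- rep(c("CONTROLLED", "ASSISTED"), length.out = n)
    tl <- mk_timeline(cumsum(c(0, dur[-n])), cumsum(dur), cats)
    a <- detect_attempts(tl)
    if (!nrow(a)) next
    death <- if (runif(1) < 0.3) sum(dur) * runif(1, 0.8, 1.2) else NA
    if (!is.na(death) && death <= a$time[1]) death <- NA
    prev <- NULL
    for (h in c(24, 48, 72, 96)) {
      lab <- label_attempt(a[1, ], tl, death_time = death, horizon = h)
      if (!is.null(prev) && prev == "FAILURE")
        expect_equal(lab$outcome, "FAILURE")
      prev <- lab$outcome
    }
  }
})

test_that("attempt summaries use days and count secondary attempts", {
  a <- data.frame(stay_id = 1, attempt_index = 1:3, time = c(43.2, 50, 90))
  s <- summarize_attempts(a)
  expect_equal(s$time_to_first_attempt_days, 1.8)
  expect_equal(s$n_secondary_attempts, 2L)
  expect_equal(summarize_attempts(a[1, ])$n_secondary_attempts, 0L)
  expect_equal(summarize_attempts(a[0, ])$n_secondary_attempts, 0L)
})

test_that("phenotyping matches ground truth on a small dense cohort", {
  coh <- generate_cohort(dense_config(120, seed = 14))
  phen <- phenotype_cohort(coh)
  expect_equal(fidelity(coh, phen), 1)
  # no attempts detected for no-switch stays
  gt <- coh$ground_truth
  none <- gt$stay_id[is.na(gt$true_attempt_time)]
  expect_false(any(phen$attempts$stay_id %in% none))
})
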