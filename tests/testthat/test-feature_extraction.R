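# Derived parameters, windowed LOCF, delta horizons, variable inclusion.

test_that("P/F pairs each PaO2 with the nearest prior FiO2 within 1 h", {
  out <- derive_pf(mk_series(2, 100), mk_series(1.5, 40))
  expect_equal(out$value, 250)
  # nearest prior beyond tolerance: no point
  expect_equal(nrow(derive_pf(mk_series(2, 100), mk_series(0, 40))), 0)
  # "prior" includes a simultaneous timestamp
  expect_equal(derive_pf(mk_series(2, 90), mk_series(2, 30))$value, 300)
  # later FiO2 never pairs backwards
  expect_equal(nrow(derive_pf(mk_series(2, 90), mk_series(2.5, 30))), 0)
  expect_warning(out <- derive_pf(mk_series(2, 90), mk_series(2, 0)),
                 "FiO2")
  expect_equal(nrow(out), 0)
})

test_that("driving pressure and compliance follow their derivation rules", {
  expect_equal(derive_dp(mk_series(2, 20), mk_series(2 - 1 / 6, 10))$value, 10)
  expect_equal(nrow(derive_dp(mk_series(2, 19), mk_series(0.5, 10))), 0)
  expect_equal(derive_dp(mk_series(2, 11.7), mk_series(2, 0))$value, 11.7)
  expect_warning(out <- derive_dp(mk_series(2, 8), mk_series(2, 10)),
                 "driving-pressure")
  expect_equal(nrow(out), 0)

  expect_equal(derive_crs(mk_series(2, 10), mk_series(1.5, 400))$value, 40)
  expect_warning(out <- derive_crs(mk_series(2, 0), mk_series(1.9, 400)),
                 "dP")
  expect_equal(nrow(out), 0)
  # tidal volume 70 min before: outside tolerance
  expect_equal(nrow(derive_crs(mk_series(2, 10),
                               mk_series(2 - 70 / 60, 400))), 0)
})

test_that("windowed LOCF takes the latest point in the closed window", {
  s <- mk_series(c(-13, -2) + 100, c(5, 7))
  expect_equal(locf_sample(s, 100)$value, 7)
  expect_null(locf_sample(mk_series(87, 5), 100))
  expect_equal(locf_sample(mk_series(88, 5), 100)$value, 5)  # exactly -12 h
  expect_equal(locf_sample(mk_series(100, 9), 100)$value, 9)  # anchor itself
})

test_that("delta is post minus pre, requiring both sides", {
  s <- mk_series(c(99, 102.5), c(40, 42))
  expect_equal(delta_sample(s, 100), 2)
  expect_equal(delta_sample(mk_series(99, 40), 100), NA_real_)
  expect_equal(delta_sample(mk_series(102, 42), 100), NA_real_)
  # post window is anchor-exclusive, horizon-inclusive
  expect_equal(delta_sample(mk_series(c(100, 103), c(40, 44)), 100), 4)
  expect_true(is.na(delta_sample(mk_series(c(99, 103.5), c(40, 44)), 100)))
})

test_that("swapping pre and post values negates the delta", {
  set.seed(3)
  for (rep in 1:30) {
    pre <- runif(1, 10, 50)
    post <- runif(1, 10, 50)
    fwd <- delta_sample(mk_series(c(99, 101), c(pre, post)), 100)
    rev <- delta_sample(mk_series(c(99, 101), c(post, pre)), 100)
    expect_equal(fwd, -rev)
  }
})

test_that("variable inclusion thresholds sit where the rules state", {
  av <- cbind(a = c(rep(TRUE, 40), rep(FALSE, 60)),
              b = c(rep(TRUE, 20), rep(FALSE, 80)),
              c = c(rep(TRUE, 34), rep(FALSE, 66)))
  # before: observed in > 1/3 of patients survives (40% yes, 20% no)
  kept <- select_variables(av[, c("a", "b")], "before")
  expect_equal(kept, "a")
  # after: "at least one-third" is inclusive
  av3 <- cbind(x = c(rep(TRUE, 33), rep(FALSE, 66)),
               y = c(rep(TRUE, 32), rep(FALSE, 67)))
  expect_equal(select_variables(av3, "after"), "x")
  expect_equal(select_variables(av[, "b", drop = FALSE], "after"),
               character(0))
})

test_that("missingness report reproduces injected missingness", {
  f <- data.frame(v_full = rnorm(100), v_miss = rnorm(100))
  out <- missingness_report(f, rep(c("SUCCESS", "FAILURE"), 50), "v_full")
  expect_equal(out$pct_missing_success, 0)
  expect_equal(out$pct_missing_failure, 0)

  set.seed(10)
  n <- 1000
  g <- rep(c("SUCCESS", "FAILURE"), each = n / 2)
  x <- rnorm(n)
  x[runif(n) < 0.3] <- NA  # MCAR at 30% in both groups
  rep30 <- missingness_report(data.frame(v = x), g, "v")
  expect_true(rep30$pct_missing_success >= 25 &
                rep30$pct_missing_success <= 35)
  expect_true(rep30$pct_missing_failure >= 25 &
                rep30$pct_missing_failure <= 35)

  # group-dependent injection shows up as the injected gap
  y <- rnorm(n)
  y[g == "SUCCESS" & runif(n) < 0.1] <- NA
  y[g == "FAILURE" & runif(n) < 0.5] <- NA
  repg <- missingness_report(data.frame(v = y), g, "v")
  expect_equal(repg$pct_missing_success, 10, tolerance = 0.5)
  expect_equal(repg$pct_missing_failure, 50, tolerance = 0.12)
})

test_that("delta-stage exclusion keeps only stays still assisted", {
  att <- data.frame(
    stay_id = 1:3, time = c(10, 10, 10),
    outcome = c("FAILURE", "SUCCESS", "FAILURE"),
    failure_time = c(12, NA, 18))
  extub <- c(100, 12.5, 100)
  keep <- exclusion_for_delta(att, extub, horizon = 3)
  expect_equal(keep, c(FALSE, FALSE, TRUE))
})

test_that("retained sets shrink monotonically with the delta horizon", {
  set.seed(21)
  n <- 200
  att <- data.frame(
    stay_id = 1:n, time = runif(n, 10, 50),
    outcome = sample(c("SUCCESS", "FAILURE"), n, TRUE))
  att$failure_time <- ifelse(att$outcome == "FAILURE",
                             att$time + runif(n, 0.5, 72), NA)
  extub <- att$time + runif(n, 0.5, 120)
  prev <- rep(TRUE, n)
  for (h in 1:8) {
    cur <- exclusion_for_delta(att, extub, horizon = h)
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("cohort-level extraction matches the per-series primitives", {
  meas <- data.frame(
    stay_id = c(1, 1, 1, 1, 2, 2),
    time = c(5, 11, 13, 14.5, 8, 12.2),
    variable = c("pao2", "pao2", "pao2", "pao2", "lactate", "lactate"),
    value = c(70, 80, 90, 95, 1.5, 2.5))
  anchors <- data.frame(stay_id = c(1, 2), time = c(12, 12))
  f <- extract_features(meas, anchors, c("pao2", "lactate"))
  expect_equal(f$pao2, c(80, NA))
  expect_equal(f$pao2_time[1], 11)
  expect_equal(f$lactate, c(NA, 1.5))
  d <- extract_deltas(meas, anchors, c("pao2", "lactate"), horizon = 3)
  expect_equal(d$delta_pao2, c(95 - 80, NA))
  expect_equal(d$delta_lactate, c(NA, 1))
})
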