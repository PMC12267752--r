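# Harmonization of raw mode logs: label mapping, carry-forward timelines,
# combined/CPAP reassignment, persistence filtering.

test_that("raw labels map to their dialect categories", {
  d <- default_dialects()$center_1
  expect_equal(map_raw_mode("VC-CMV", d), "CONTROLLED")
  expect_equal(map_raw_mode("SPN-CPAP", d), "CPAP")
  expect_equal(map_raw_mode(c("PS", "PC-BIPAP"), d),
               c("ASSISTED", "COMBINED"))
  expect_error(map_raw_mode("nonsense", d, strict = TRUE),
               class = "vs_unknown_mode_label")
  expect_warning(out <- map_raw_mode("nonsense", d, strict = FALSE),
                 "NONINVASIVE_OR_NONE")
  expect_equal(out, "NONINVASIVE_OR_NONE")
})

test_that("every default dialect is total and covers all five categories", {
  for (d in default_dialects()) {
    expect_gte(nrow(d), 10)
    expect_setequal(unique(d$category), vs_categories())
    expect_equal(anyDuplicated(d$raw_label), 0)
  }
})

test_that("logged categories carry forward to the next log or extubation", {
  d <- default_dialects()$center_1
  airway <- data.frame(time = c(0, 45), event = c("intubation", "extubation"))
  rec <- data.frame(time = c(0, 30), raw_label = c("VC-CMV", "PS"))
  tl <- build_timeline(rec, airway, d, stay_end = 50)
  inv <- tl$segments[tl$segments$category != "NONINVASIVE_OR_NONE", ]
  expect_equal(inv$start, c(0, 30))
  expect_equal(inv$end, c(30, 45))
  expect_equal(inv$category, c("CONTROLLED", "ASSISTED"))
  # trailing post-extubation gap is non-invasive
  tail_seg <- tl$segments[nrow(tl$segments), ]
  expect_equal(tail_seg$category, "NONINVASIVE_OR_NONE")

  one <- build_timeline(data.frame(time = 0, raw_label = "VC-CMV"),
                        data.frame(time = c(0, 48),
                                   event = c("intubation", "extubation")),
                        d, stay_end = 48)
  expect_equal(nrow(one$segments), 1)
  expect_equal(one$segments$end - one$segments$start, 48)

  expect_error(build_timeline(data.frame(time = numeric(0),
                                         raw_label = character(0)),
                              airway, d, stay_end = 50),
               class = "vs_missing_mode_data")
})

test_that("combined segments resolve by the nearest spontaneous RR", {
  tl <- mk_timeline(c(0, 10, 15), c(10, 15, 20),
                    c("CONTROLLED", "COMBINED", "CONTROLLED"))
  # RR 14 > 10 -> assisted
  out <- reassign_combined(tl, mk_series(10.2, 14))
  expect_equal(out$segments$category[2], "ASSISTED")
  expect_equal(out$segments$provenance[2], "combined_reassigned")
  # rule is strictly "higher than ten": RR exactly 10 -> controlled
  out <- reassign_combined(tl, mk_series(10.2, 10))
  expect_equal(out$segments$category[2], "CONTROLLED")
  # no RR within the +/- 1 h tolerance -> conservative fallback
  out <- reassign_combined(tl, mk_series(13, 25))
  expect_equal(out$segments$category[2], "CONTROLLED")
  # boundaries never move
  expect_equal(out$segments$start, tl$segments$start)
  expect_equal(out$segments$end, tl$segments$end)
})

test_that("CPAP is assisted inside invasive ventilation, otherwise none", {
  inv <- data.frame(start = 0, end = 48)
  tl <- mk_timeline(c(0, 20, 25), c(20, 25, 48),
                    c("CONTROLLED", "CPAP", "CONTROLLED"), invasive = inv)
  out <- reassign_cpap(tl)
  expect_equal(out$segments$category[2], "ASSISTED")

  tl <- mk_timeline(c(0, 50), c(48, 60), c("CONTROLLED", "CPAP"),
                    invasive = inv)
  out <- reassign_cpap(tl)
  expect_equal(out$segments$category[out$segments$start == 50],
               "NONINVASIVE_OR_NONE")

  # straddling the extubation boundary: split, each side per its rule
  tl <- mk_timeline(c(0, 46), c(46, 52), c("CONTROLLED", "CPAP"),
                    invasive = inv)
  out <- reassign_cpap(tl)
  cp <- out$segments[out$segments$provenance == "cpap_reassigned", ]
  expect_equal(cp$start, c(46, 48))
  expect_equal(cp$end, c(48, 52))
  expect_equal(cp$category, c("ASSISTED", "NONINVASIVE_OR_NONE"))
})

test_that("sub-threshold mode blips are merged away, 1.0 h runs survive", {
  tl <- mk_timeline(c(0, 10, 10.5), c(10, 10.5, 20),
                    c("CONTROLLED", "ASSISTED", "CONTROLLED"))
  out <- persistence_filter(tl)
  expect_equal(nrow(out$segments), 1)
  expect_equal(out$segments$category, "CONTROLLED")
  expect_equal(out$segments$end - out$segments$start, 20)

  # "at least 1 h" is inclusive
  tl <- mk_timeline(c(0, 10, 11), c(10, 11, 20),
                    c("CONTROLLED", "ASSISTED", "CONTROLLED"))
  out <- persistence_filter(tl)
  expect_equal(out$segments$category, c("CONTROLLED", "ASSISTED",
                                        "CONTROLLED"))
})

test_that("persistence filtering matches the brute-force merge oracle", {
  set.seed(404)
  for (rep in 1:1000) {
    n <- sample(2:12, 1)
    cats <- character(n)
    cats[1] <- sample(c("CONTROLLED", "ASSISTED"), 1)
    for (i in seq_len(n - 1))
      cats[i + 1] <- if (runif(1) < 0.8)
        setdiff(c("CONTROLLED", "ASSISTED"), cats[i]) else cats[i]
    dur <- round(runif(n, 0.1, 2.5), 2)
    tl <- mk_timeline(cumsum(c(0, dur[-n])), cumsum(dur), cats)
    got <- persistence_filter(tl)$segments
    want <- oracle_persistence(dur, cats)
    expect_equal(got$category, want$category,
                 info = paste("case", rep))
    expect_equal(got$end - got$start, want$duration, tolerance = 1e-9,
                 info = paste("case", rep))
  }
})

test_that("persistence filtering is idempotent and conserves covered time", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    cats <- sample(c("CONTROLLED", "ASSISTED"), n, replace = TRUE)
    dur <- runif(n, 0.2, 3)
    tl <- mk_timeline(cumsum(c(0, dur[-n])), cumsum(dur), cats)
    once <- persistence_filter(tl)
    twice <- persistence_filter(once)
    expect_equal(once$segments, twice$segments)
    expect_equal(sum(once$segments$end - once$segments$start), sum(dur),
                 tolerance = 1e-9)
  }
})
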