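# Group comparisons, PEEP-stratified summaries, interaction testing.

test_that("proportions use chi-squared, small tables switch to Fisher", {
  # 28-day mortality contrast at the published cohort sizes
  died <- c(rep(TRUE, 367), rep(FALSE, 2191 - 367),
            rep(TRUE, 1259), rep(FALSE, 4524 - 1259))
  grp <- c(rep("SUCCESS", 2191), rep("FAILURE", 4524))
  cmp <- compare_groups(died, grp, type = "categorical")
  expect_equal(cmp$test, "chi2")
  expect_lt(cmp$p_value, 0.001)

  # identical proportions: chi-squared statistic 0, p = 1
  same <- compare_groups(rep(c(TRUE, FALSE), 50),
                         rep(c("A", "B"), each = 50), type = "categorical")
  expect_equal(same$p_value, 1)

  # an expected cell below 5 switches to Fisher, matching the exact
  # hypergeometric enumeration
  x <- c(rep(TRUE, 3), rep(FALSE, 9), rep(TRUE, 1), rep(FALSE, 11))
  g <- rep(c("A", "B"), each = 12)
  cmp <- compare_groups(x, g, type = "categorical")
  expect_equal(cmp$test, "fisher")
  # enumeration: P(table at least as extreme) under fixed margins
  m <- 4; n_ <- 20; k <- 12  # 4 positives, 20 negatives, 12 in group A
  probs <- dhyper(0:4, m, n_, k)
  obs <- dhyper(3, m, n_, k)
  expect_equal(cmp$p_value, sum(probs[probs <= obs + 1e-12]))
})

test_that("continuous comparisons use Wilcoxon by default, t on request", {
  set.seed(6)
  x <- c(rnorm(60), rnorm(60, 1))
  g <- rep(c("A", "B"), each = 60)
  w <- compare_groups(x, g)
  expect_equal(w$test, "wilcoxon")
  expect_equal(w$p_value, wilcox.test(x ~ g, exact = FALSE)$p.value)
  tt <- compare_groups(x, g, continuous_test = "t")
  expect_equal(tt$test, "t")
  expect_equal(tt$p_value, t.test(x ~ g)$p.value)
  expect_error(compare_groups(x[1:60], g[1:60]), "two non-empty groups")
})

test_that("comparison p-values are roughly uniform under the null", {
  set.seed(123)
  p <- replicate(300, {
    x <- rnorm(40)
    g <- sample(rep(c("A", "B"), 20))
    compare_groups(x, g)$p_value
  })
  # rank-test p-values are discrete, so ties are expected; the KS check is
  # on the aggregate shape
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("stratified summaries match order-statistics quantiles", {
  vals <- 1:9
  s <- stratified_summary(vals, rep(4, 9), rep("success", 9))
  row <- s[s$stratum == "<=5" & s$outcome == "success", ]
  expect_equal(row$median, 5)
  expect_equal(row$q1, 3)
  expect_equal(row$q3, 7)
  # empty cells are NA markers, not errors
  expect_true(is.na(s$median[s$stratum == ">10"]))

  set.seed(9)
  x <- rlnorm(101, log(200), 0.4)
  peep <- sample(c(4, 8, 12), 101, TRUE)
  out <- sample(c("success", "failure"), 101, TRUE)
  s <- stratified_summary(x, peep, out)
  for (i in seq_len(nrow(s))) {
    cell <- x[peep_stratum(peep) == s$stratum[i] & out == s$outcome[i]]
    if (!length(cell)) next
    expect_equal(s$median[i], oracle_quantile7(cell, 0.5))
    expect_equal(s$q1[i], oracle_quantile7(cell, 0.25))
    expect_equal(s$q3[i], oracle_quantile7(cell, 0.75))
  }
})

test_that("chi-squared on a 2x2 table is invariant to label swaps", {
  x <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 55), rep(FALSE, 45))
  g <- rep(c("A", "B"), each = 100)
  p1 <- compare_groups(x, g, type = "categorical")$p_value
  p2 <- compare_groups(!x, g, type = "categorical")$p_value
  p3 <- compare_groups(x, rev(g), type = "categorical")$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("single-center interaction test equals the plain logistic LRT", {
  d <- simulate_interaction_cohort(800, beta_value = 0.3,
                                   interaction = c(0.2, 0.4),
                                   n_centers = 1, center_sd = 0, seed = 17)
  got <- interaction_test(d$success, d$value, d$peep, d$center)
  expect_equal(got$model, "fixed")
  dd <- data.frame(y = d$success, x = as.numeric(scale(d$value)),
                   stratum = peep_stratum(d$peep))
  full <- glm(y ~ x * stratum, data = dd, family = binomial())
  red <- glm(y ~ x + stratum, data = dd, family = binomial())
  p_ref <- anova(red, full, test = "LRT")$`Pr(>Chi)`[2]
  expect_equal(got$p_interaction, p_ref, tolerance = 1e-8)
})

test_that("one-class strata are dropped with a warning", {
  d <- simulate_interaction_cohort(300, seed = 19, n_centers = 1)
  d$success[peep_stratum(d$peep) == ">10"] <- 1L
  expect_warning(out <- interaction_test(d$success, d$value, d$peep,
                                         d$center),
                 "single outcome class")
  expect_true(out$p_interaction >= 0 && out$p_interaction <= 1)
})

test_that("the mixed model detects a strong planted PEEP interaction", {
  d <- simulate_interaction_cohort(3000, beta_value = 0,
                                   interaction = c(0, 0.8), seed = 23)
  out <- suppressMessages(
    interaction_test(d$success, d$value, d$peep, d$center))
  expect_equal(out$model, "mixed")
  expect_lt(out$p_interaction, 0.01)
})
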