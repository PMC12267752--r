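# Descriptive group comparisons and the PEEP-stratified interaction test.

#' Compare a variable between outcome groups
#'
#' Proportions are compared with the chi-squared test, switching to Fisher's
#' exact test when any expected cell count is below 5. Continuous variables
#' use the Wilcoxon rank-sum test by default, or Welch's t test on request.
#' All tests are two-sided. Summaries are median (IQR) for Wilcoxon-tested
#' variables, mean (SD) for t-tested ones, and count (%) for categorical
#' ones.
#'
#' @param values Vector of values (numeric, or factor/character/logical for
#'   categorical variables). `NA`s are dropped (complete-case).
#' @param group Two-level vector aligned with `values`.
#' @param type `"continuous"` or `"categorical"`.
#' @param continuous_test `"wilcoxon"` (default) or `"t"`.
#' @return list with `test` (one of `"chi2"`, `"fisher"`, `"wilcoxon"`,
#'   `"t"`), `p_value`, and a `summaries` data.frame (one row per group).
#' @export
compare_groups <- function(values, group,
                           type = c("continuous", "categorical"),
                           continuous_test = c("wilcoxon", "t")) {
  type <- match.arg(type)
  continuous_test <- match.arg(continuous_test)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- factor(group[ok])
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("compare_groups needs two non-empty groups")

  if (type == "categorical") {
    tab <- table(values, group)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test <- "fisher"
      p <- stats::fisher.test(tab)$p.value
    } else {
      test <- "chi2"
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
    }
    # count (%) of the "positive" level (last level of a factor, TRUE for
    # logicals)
    pos <- if (is.logical(values)) TRUE else utils::tail(levels(factor(values)), 1)
    summaries <- do.call(rbind, lapply(levels(group), function(g) {
      x <- values[group == g]
      k <- sum(x == pos)
      data.frame(group = g, n = length(x),
                 summary = sprintf("%d (%.0f)", k, 100 * k / length(x)),
                 stringsAsFactors = FALSE)
    }))
  } else if (continuous_test == "t") {
    test <- "t"
    p <- stats::t.test(values ~ group)$p.value
    summaries <- do.call(rbind, lapply(levels(group), function(g) {
      x <- values[group == g]
      data.frame(group = g, n = length(x),
                 summary = sprintf("%.1f (%.1f)", mean(x), stats::sd(x)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    test <- "wilcoxon"
    p <- stats::wilcox.test(values ~ group, exact = FALSE)$p.value
    summaries <- do.call(rbind, lapply(levels(group), function(g) {
      x <- values[group == g]
      q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7)
      data.frame(group = g, n = length(x),
                 summary = sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(test = test, p_value = p, summaries = summaries)
}

#' PEEP stratum assignment
#'
#' Strata follow the reporting convention: at or below 5, 6 to 10, and above
#' 10 cmH2O. Assignment uses the PEEP paired to the specific measurement
#' (the nearest prior PEEP), not a daily mean.
#'
#' @param peep Numeric PEEP values (cmH2O).
#' @param breaks Two inner cut points (default 5 and 10).
#' @return Ordered factor with levels `"<=5"`, `"6-10"`, `">10"`.
#' @export
peep_stratum <- function(peep, breaks = c(5, 10)) {
  cut(peep, breaks = c(-Inf, breaks, Inf),
      labels = c(paste0("<=", breaks[1]),
                 paste0(breaks[1] + 1, "-", breaks[2]),
                 paste0(">", breaks[2])),
      ordered_result = TRUE)
}

#' Per-stratum medians and IQRs by outcome
#'
#' @param values Numeric measurements (e.g. P/F or compliance).
#' @param peep PEEP paired to each measurement.
#' @param outcome Outcome label per measurement.
#' @param breaks Passed to [peep_stratum()].
#' @return data.frame (`stratum`, `outcome`, `n`, `median`, `q1`, `q3`);
#'   empty cells yield `NA` rows, not errors. Quartiles use linear
#'   interpolation (type 7).
#' @export
stratified_summary <- function(values, peep, outcome, breaks = c(5, 10)) {
  ok <- !is.na(values) & !is.na(peep) & !is.na(outcome)
  values <- values[ok]; outcome <- outcome[ok]
  st <- peep_stratum(peep[ok], breaks)
  grid <- expand.grid(stratum = levels(st),
                      outcome = sort(unique(outcome)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- values[st == grid$stratum[i] & outcome == grid$outcome[i]]
    if (!length(x))
      return(data.frame(grid[i, ], n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_))
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7)
    data.frame(grid[i, ], n = length(x), median = q[[1]], q1 = q[[2]],
               q3 = q[[3]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test whether PEEP modifies a variable's association with switch success
#'
#' Fits a mixed-effects logistic regression of switch success on the
#' (standardized) variable, the PEEP stratum, and their interaction, with a
#' random intercept per center, and compares it against the
#' no-interaction model with a likelihood-ratio test. With a single center
#' the model reduces to a plain fixed-effects logistic regression. Strata
#' containing only one outcome class are dropped with a warning.
#'
#' @param success Logical (or 0/1) switch-success outcome per patient.
#' @param values Numeric variable values (measured at the switch attempt).
#' @param peep PEEP paired to each value.
#' @param center Center identifier per patient.
#' @param breaks Passed to [peep_stratum()].
#' @return list with `p_interaction`, `strata` (the per-stratum medians by
#'   outcome from [stratified_summary()]), `n`, and `model`
#'   (`"mixed"` or `"fixed"`).
#' @export
interaction_test <- function(success, values, peep, center,
                             breaks = c(5, 10)) {
  ok <- !is.na(success) & !is.na(values) & !is.na(peep) & !is.na(center)
  d <- data.frame(y = as.integer(success[ok]), x = as.numeric(values[ok]),
                  stratum = peep_stratum(peep[ok], breaks),
                  center = factor(center[ok]))
  strata_summary <- stratified_summary(values[ok], peep[ok],
                                       ifelse(d$y == 1, "success", "failure"),
                                       breaks)
  cls <- tapply(d$y, d$stratum, function(y) length(unique(y)))
  bad <- names(cls)[!is.na(cls) & cls < 2]
  if (length(bad)) {
    warning("dropping stratum with a single outcome class: ",
            paste(bad, collapse = ", "))
    d <- d[!(d$stratum %in% bad), ]
  }
  d$stratum <- droplevels(d$stratum)
  if (nlevels(d$stratum) < 2)
    stop("interaction test needs at least two populated PEEP strata")
  d$x <- as.numeric(scale(d$x))
  df_int <- nlevels(d$stratum) - 1L

  if (nlevels(d$center) > 1) {
    full <- lme4::glmer(y ~ x * stratum + (1 | center), data = d,
                        family = stats::binomial())
    red <- lme4::glmer(y ~ x + stratum + (1 | center), data = d,
                       family = stats::binomial())
    model <- "mixed"
  } else {
    full <- stats::glm(y ~ x * stratum, data = d, family = stats::binomial())
    red <- stats::glm(y ~ x + stratum, data = d, family = stats::binomial())
    model <- "fixed"
  }
  lrt <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(red)))
  p <- stats::pchisq(max(lrt, 0), df = df_int, lower.tail = FALSE)
  list(p_interaction = p, strata = strata_summary, n = nrow(d), model = model)
}
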