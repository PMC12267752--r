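# Switch-failure prediction: design-matrix construction, L1-penalized
# logistic regression with nested cross-validation, and variable-group
# contributions to the held-out AUC.

#' Rank-based AUC (Mann-Whitney)
#'
#' @param scores Numeric predictions.
#' @param labels Logical or 0/1 outcomes (1 = event).
#' @return AUC in `[0, 1]`; ties handled by midranks.
#' @export
auc_mw <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), any(y), any(!y))
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a prediction design matrix
#'
#' Continuous features are median-imputed with a paired missingness-indicator
#' column for every feature with any missing value; zero-variance columns
#' are dropped. Model 1 uses pre-switch features only; model 2 appends
#' delta-horizon columns and restricts rows to attempts still in assisted
#' mode at the delta horizon (pass `retained`).
#'
#' @param features data.frame of pre-switch features (one row per attempt;
#'   value columns only, no `_time` columns).
#' @param outcome Logical or 0/1 failure flag aligned with rows.
#' @param deltas Optional data.frame of delta columns (model 2).
#' @param retained Optional logical vector: rows to keep (model 2's
#'   still-assisted restriction, see [exclusion_for_delta()]).
#' @return list with `x` (numeric matrix), `y` (0/1), `value_cols` (columns
#'   holding feature values, named by source feature).
#' @export
build_design <- function(features, outcome, deltas = NULL, retained = NULL) {
  x <- as.data.frame(features)
  if (!is.null(deltas)) x <- cbind(x, as.data.frame(deltas))
  y <- as.integer(as.logical(outcome))
  if (!is.null(retained)) {
    x <- x[retained, , drop = FALSE]
    y <- y[retained]
  }
  if (length(unique(y)) < 2) stop("outcome is constant")

  cols <- list()
  value_cols <- character(0)
  for (v in names(x)) {
    col <- as.numeric(x[[v]])
    miss <- is.na(col)
    if (all(miss)) next
    if (any(miss)) {
      col[miss] <- stats::median(col[!miss])
      if (stats::sd(miss) > 0) cols[[paste0(v, "_missing")]] <- as.numeric(miss)
    }
    if (stats::sd(col) > 0) {
      cols[[v]] <- col
      value_cols <- c(value_cols, v)
    }
  }
  if (!length(cols)) stop("design matrix is degenerate: no usable columns")
  list(x = do.call(cbind, cols), y = y, value_cols = value_cols)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Nested cross-validated LASSO logistic regression
#'
#' Outer folds (stratified by outcome) provide held-out predictions; within
#' each outer training set the L1 penalty is chosen by inner
#' cross-validation (`glmnet::cv.glmnet`, lambda at the minimum deviance).
#' The reported AUC is computed only on held-out predictions, pooled over
#' the outer folds. Standardization is learned inside each training fit.
#'
#' @param x Numeric matrix (see [build_design()]).
#' @param y 0/1 outcome vector.
#' @param folds Number of outer folds (default 5).
#' @param inner_folds Inner folds for penalty selection (default 5).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return list of class `vs_cv`: `auc` (pooled held-out), `auc_folds`,
#'   `auc_se`, `fold` (outer assignments), `predictions` (held-out
#'   probabilities), `coefficients` (per-fold matrix at the selected
#'   penalty).
#' @export
fit_lasso_cv <- function(x, y, folds = 5, inner_folds = 5, seed = 1L) {
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("need both outcome classes")
  if (nrow(x) <= folds) stop("need more rows than folds")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  pred <- numeric(length(y))
  coefs <- matrix(NA_real_, ncol(x) + 1, folds,
                  dimnames = list(c("(Intercept)", colnames(x)), NULL))
  for (k in seq_len(folds)) {
    tr <- fold != k
    inner <- stratified_folds(y[tr], inner_folds)
    cv <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 1, foldid = inner,
                            standardize = TRUE)
    pred[!tr] <- as.numeric(predict(cv, x[!tr, , drop = FALSE],
                                    s = "lambda.min", type = "response"))
    coefs[, k] <- as.numeric(stats::coef(cv, s = "lambda.min"))
  }
  auc_folds <- vapply(seq_len(folds), function(k) {
    if (length(unique(y[fold == k])) < 2) return(NA_real_)
    auc_mw(pred[fold == k], y[fold == k])
  }, numeric(1))
  structure(list(auc = auc_mw(pred, y), auc_folds = auc_folds,
                 auc_se = stats::sd(auc_folds, na.rm = TRUE) /
                   sqrt(sum(!is.na(auc_folds))),
                 fold = fold, predictions = pred, coefficients = coefs),
            class = "vs_cv")
}

#' @export
print.vs_cv <- function(x, ...) {
  cat(sprintf("<vs_cv> held-out AUC %.3f (SE %.3f), %d folds\n",
              x$auc, x$auc_se, length(x$auc_folds)))
  invisible(x)
}

#' Variable-group contributions to cross-validated AUC
#'
#' For each group of columns, refits the nested cross-validation without the
#' group (using the same seed, hence the same fold structure) and reports
#' the AUC drop relative to the full model.
#'
#' @param x,y As in [fit_lasso_cv()].
#' @param groups Named list of character vectors of column names; together
#'   they must cover columns of `x` and each must name at least one column.
#'   A feature's missingness-indicator column travels with its group
#'   automatically when named `<feature>_missing`.
#' @param folds,inner_folds,seed As in [fit_lasso_cv()].
#' @return data.frame (`group`, `auc_without`, `delta_auc`), plus the full
#'   AUC in `attr(, "auc_full")`.
#' @export
group_contribution <- function(x, y, groups, folds = 5, inner_folds = 5,
                               seed = 1L) {
  if (!length(groups)) stop("no variable groups supplied")
  all_named <- unique(unlist(groups))
  unknown <- setdiff(all_named, colnames(x))
  if (length(unknown))
    stop("unknown column(s) in groups: ", paste(unknown, collapse = ", "))
  full <- fit_lasso_cv(x, y, folds, inner_folds, seed)
  rows <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    if (!length(cols)) stop("group ", g, " covers no columns")
    cols <- unique(c(cols, paste0(cols, "_missing")))
    keep <- setdiff(colnames(x), cols)
    if (!length(keep)) stop("group ", g, " covers every column")
    fit <- fit_lasso_cv(x[, keep, drop = FALSE], y, folds, inner_folds, seed)
    data.frame(group = g, auc_without = fit$auc,
               delta_auc = full$auc - fit$auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "auc_full") <- full$auc
  out
}
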