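# ROC/AUC evaluation of the relative-risk model: rank-based (Mann-Whitney)
# AUC with a DeLong-type asymptotic confidence interval, Youden-optimal
# cutoff, and 10-fold / leave-one-out cross-validation with pooled
# out-of-fold scores.

#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a random case scores above a
#' random control, ties counted one half. The confidence interval uses the
#' asymptotic paired-placement (DeLong-type) variance
#' `var(V10)/n1 + var(V01)/n0`. The optimal cutoff maximizes Youden's J
#' (sensitivity + specificity - 1); ties resolve to the lower threshold.
#'
#' @param scores Numeric risk scores, higher = more case-like.
#' @param labels Case/control labels: logical (`TRUE` = case), 0/1, or a
#'   factor/character with value `"case"` for cases.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `roc_curve`: `auc`, `auc_se`, `ci` (low, high),
#'   `points` (threshold, sensitivity, fpr), `optimal` (threshold,
#'   sensitivity, specificity, youden), `n_cases`, `n_controls`.
#' @export
#' @examples
#' roc_auc(c(.9, .8, .1, .2), c(TRUE, TRUE, FALSE, FALSE))$auc
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- to_case_indicator(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  cs <- scores[y == 1]
  ct <- scores[y == 0]
  # Placements via sorted control / case score vectors.
  sc <- sort(ct)
  v10 <- (findInterval(cs, sc, left.open = TRUE) +
            findInterval(cs, sc)) / (2 * n0)
  ss <- sort(cs)
  v01 <- 1 - (findInterval(ct, ss, left.open = TRUE) +
                findInterval(ct, ss)) / (2 * n1)
  auc <- mean(v10)
  var_auc <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
    (if (n0 > 1) stats::var(v01) / n0 else 0)
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(low = max(0, auc - z * se), high = min(1, auc + z * se))

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(cs >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(ct >= t), numeric(1))
  j <- sens - fpr
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]  # ties -> lower threshold
  structure(
    list(auc = auc, auc_se = se, ci = ci, conf_level = conf_level,
         points = data.frame(threshold = thr, sensitivity = sens,
                             fpr = fpr),
         optimal = list(threshold = thr[best], sensitivity = sens[best],
                        specificity = 1 - fpr[best], youden = j[best]),
         n_cases = n1, n_controls = n0),
    class = "roc_curve"
  )
}

to_case_indicator <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == "case")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      100 * x$conf_level, "% CI ", format(x$ci[["low"]], digits = 4), "-",
      format(x$ci[["high"]], digits = 4), "); optimal cutoff ",
      format(x$optimal$threshold, digits = 4), " (sens ",
      format(x$optimal$sensitivity, digits = 3), ", spec ",
      format(x$optimal$specificity, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Cross-validated AUC of the logistic relative-risk model
#'
#' Records are partitioned into outcome-stratified folds (seeded); each
#' fold is scored by a model fitted on the remaining folds, and all
#' out-of-fold predicted probabilities are pooled into a single ROC,
#' matching the convention of reporting one cross-validated AUC with CI.
#'
#' @param data Case-control data frame.
#' @param variables Model variables (selection is frozen; it is not re-run
#'   inside folds).
#' @param k Number of folds (2..n), or `"loo"` for leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @param status_col Outcome column name.
#' @param conf_level Confidence level for the pooled AUC.
#' @return Object of class `cv_result`: `scheme`, `seed`, `scores`,
#'   `labels`, `folds` and the pooled `roc` ([roc_auc()] object).
#' @export
cv_auc <- function(data, variables, k = 10, seed = 1L,
                   status_col = "status", conf_level = 0.95) {
  n <- nrow(data)
  y <- to_case_indicator(data[[status_col]])
  loo <- identical(k, "loo") || (is.numeric(k) && k == n)
  if (loo) {
    folds <- seq_len(n)
    k <- n
  } else {
    if (!is.numeric(k) || k < 2 || k > n) stop("k must be in 2..n or 'loo'")
    folds <- integer(n)
    with_seed(seed, {
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    })
  }
  scores <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    train <- data[!test, , drop = FALSE]
    if (length(unique(to_case_indicator(train[[status_col]]))) < 2) {
      stop("fold ", f, " leaves a single-class training set; ",
           "use fewer folds")
    }
    fit <- fit_logistic(train, variables, status_col)
    scores[test] <- predict(fit, data[test, , drop = FALSE])
  }
  structure(
    list(scheme = if (loo) "leave-one-out" else paste0(k, "-fold"),
         seed = if (loo) NA_integer_ else as.integer(seed),
         scores = scores, labels = y, folds = folds,
         roc = roc_auc(scores, y, conf_level = conf_level)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, " cross-validation, pooled ", sep = "")
  print(x$roc)
  invisible(x)
}

#' Write ROC points and summary as delimited text
#'
#' @param x A `roc_curve` or `cv_result`.
#' @param path File path for the points; a `<path>.summary.csv` companion
#'   holds AUC, CI and the optimal cutoff.
#' @export
write_roc <- function(x, path) {
  roc <- if (inherits(x, "cv_result")) x$roc else x
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(roc$points, path, row.names = FALSE, quote = FALSE)
  smry <- data.frame(
    auc = roc$auc, ci_low = roc$ci[["low"]], ci_high = roc$ci[["high"]],
    conf_level = roc$conf_level,
    optimal_threshold = roc$optimal$threshold,
    optimal_sensitivity = roc$optimal$sensitivity,
    optimal_specificity = roc$optimal$specificity
  )
  utils::write.csv(smry, paste0(path, ".summary.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
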