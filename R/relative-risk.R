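# Relative-risk (odds-ratio) modelling: crude 2x2 odds ratios, unconditional
# logistic regression by Newton-Raphson, the two-phase forward selection used
# to build the ESCC model, interaction screening, and profile scoring.

#' Crude odds ratio from a 2x2 exposure-by-status table
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c Exposed controls.
#' @param d Unexposed controls.
#' @param conf_level Confidence level for the Wald interval on the log-OR
#'   scale (default 0.95).
#' @param correction If `TRUE`, add 0.5 to every cell (Haldane-Anscombe);
#'   off by default so published cross-products are reproduced exactly.
#' @return Named numeric vector `c(or, ci_low, ci_high)`.
#' @export
#' @examples
#' crude_or(56, 188, 95, 1125)  # drinking vs ESCC
crude_or <- function(a, b, c, d, conf_level = 0.95, correction = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (a + b < 1 || c + d < 1) stop("need at least one case and one control")
  if (correction) {
    cells <- cells + 0.5
  } else if (any(cells == 0)) {
    stop("zero cell(s): ", paste(names(cells)[cells == 0], collapse = ", "),
         "; use correction = TRUE for a Haldane-Anscombe correction")
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- c(or, exp(log(or) - z * se), exp(log(or) + z * se))
  names(out) <- c("or", "ci_low", "ci_high")
  out
}

# Newton-Raphson MLE for logistic regression on a design matrix.
# Convergence: max |score| < 1e-8 or relative log-likelihood change < 1e-10;
# at most 100 iterations; |beta| > 15 during iteration is treated as
# separation. Covariance is the inverse observed information.
newton_logistic <- function(X, y, tol_score = 1e-8, tol_ll = 1e-10,
                            max_iter = 100) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    ll <- sum(y * eta - log1pexp(eta))
    score <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    if (max(abs(score)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) <
         tol_ll * (abs(ll_old) + tol_ll))) {
      converged <- TRUE
      break
    }
    beta <- beta + solve(info, score)
    if (any(abs(beta) > 15)) {
      stop("complete or quasi-separation suspected (|coefficient| > 15 ",
           "during iteration); check the data for empty or determining cells")
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov = solve(info), loglik = ll, converged = converged,
       iterations = iter, score_norm = max(abs(score)))
}

# Build outcome vector and design matrix for given variables (treatment
# contrasts, reference = first factor level), optionally plus interaction
# pairs given as list(c("v1","v2"), ...).
build_design <- function(data, variables, status_col = "status",
                         interactions = NULL) {
  y <- as.integer(data[[status_col]] == "case")
  if (length(unique(y)) < 2) stop("need both cases and controls")
  for (v in variables) {
    if (is.null(data[[v]])) stop("variable not found in data: ", v)
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])
    data[[v]] <- droplevels(data[[v]])
  }
  rhs <- if (length(variables)) paste(variables, collapse = " + ") else "1"
  if (!is.null(interactions)) {
    rhs <- paste(c(rhs, vapply(interactions, paste, character(1),
                               collapse = ":")),
                 collapse = " + ")
  }
  fml <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fml, data = data)
  xlevels <- lapply(stats::setNames(variables, variables),
                    function(v) levels(data[[v]]))
  list(X = X, y = y, xlevels = xlevels, formula = fml)
}

#' Fit an unconditional logistic regression model
#'
#' Maximum-likelihood fit by Newton iterations on the binomial
#' log-likelihood, with dummy (treatment) coding of categorical factors:
#' the reference is each factor's first level. The coefficient covariance
#' is the inverse observed information, so `exp(beta)` with Wald intervals
#' reproduces standard adjusted odds-ratio tables.
#'
#' @param data Data frame with a case/control `status` column and the
#'   model variables (factors; character columns are coerced).
#' @param variables Character vector of variable names to include.
#' @param status_col Name of the outcome column (factor or character with
#'   values `case`/`control`).
#' @return An object of class `logistic_fit` with elements `coefficients`,
#'   `vcov`, `loglik`, `converged`, `iterations`, `coding` (per-variable
#'   levels and reference) and `variables`.
#' @export
#' @examples
#' d <- generate_case_control(default_cohort_spec(n_cases = 200, seed = 3))
#' fit <- fit_logistic(d, c("smoking", "drinking"))
#' summary(fit)
fit_logistic <- function(data, variables, status_col = "status") {
  des <- build_design(data, variables, status_col)
  fit <- newton_logistic(des$X, des$y)
  structure(
    c(fit,
      list(variables = variables, xlevels = des$xlevels,
           coding = lapply(des$xlevels, function(l) {
             list(levels = l, reference = l[1])
           }),
           n = length(des$y), n_cases = sum(des$y))),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n, "(", x$n_cases, "cases ),",
      length(x$coefficients), "coefficients; logLik =",
      format(x$loglik, digits = 7),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Adjusted odds-ratio table from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param ... Unused.
#' @return Data frame with columns `term`, `estimate` (log-odds), `se`,
#'   `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
summary.logistic_fit <- function(object, conf_level = 0.95, ...) {
  beta <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * se),
    ci_high = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Predicted case probabilities for new records
#'
#' @param object A `logistic_fit`.
#' @param newdata Data frame containing the model variables.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  for (v in object$variables) {
    if (is.null(newdata[[v]])) stop("variable not found in newdata: ", v)
    lv <- object$xlevels[[v]]
    val <- as.character(newdata[[v]])
    bad <- setdiff(unique(val), lv)
    if (length(bad)) {
      stop("unknown level(s) for '", v, "': ", paste(bad, collapse = ", "))
    }
    newdata[[v]] <- factor(val, levels = lv)
  }
  rhs <- if (length(object$variables)) {
    paste(object$variables, collapse = " + ")
  } else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)),
                           data = newdata)
  stats::plogis(drop(X %*% object$coefficients[colnames(X)]))
}

# Likelihood-ratio test of nested fits; returns p-value and df.
lrt_p <- function(ll_full, ll_reduced, df) {
  stat <- max(0, 2 * (ll_full - ll_reduced))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

# Fit with an interaction block added; used by interaction_screen.
fit_logistic_interaction <- function(data, variables, pair,
                                     status_col = "status") {
  des <- build_design(data, variables, status_col,
                      interactions = list(pair))
  newton_logistic(des$X, des$y)
}

#' Two-phase forward selection with backward departure
#'
#' Starting from the forced-in model, each remaining candidate factor is
#' tested by a block likelihood-ratio test (all its dummy columns at once);
#' the candidate with the smallest p-value below `p_enter` enters (ties
#' break by candidate order). After every entry, non-forced variables whose
#' block LRT p-value exceeds `p_remove` are removed (largest first).
#' Selection stops when no candidate can enter.
#'
#' @param data Case-control data frame.
#' @param forced Variables entered a priori and never removed (the ESCC
#'   model forces age band, sex, smoking and drinking).
#' @param candidates Ordered character vector of candidate variables,
#'   disjoint from `forced`.
#' @param p_enter Entry cut-off (default 0.05).
#' @param p_remove Departure cut-off (default 0.10).
#' @param status_col Outcome column name.
#' @return An object of class `selection_trace`: data frame `steps`
#'   (action, variable, statistic df, p-value), `final_variables`, `forced`
#'   and the final `fit`.
#' @export
forward_select <- function(data, forced, candidates, p_enter = 0.05,
                           p_remove = 0.10, status_col = "status") {
  if (length(intersect(forced, candidates))) {
    stop("forced and candidates must be disjoint")
  }
  if (p_enter > p_remove) stop("p_enter must be <= p_remove")
  current <- forced
  remaining <- candidates
  steps <- list()
  fit_cache <- function(vars) {
    des <- build_design(data, vars, status_col)
    newton_logistic(des$X, des$y)
  }
  fit_cur <- fit_cache(current)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * (length(candidates) + 1L)) break  # cycling guard
    if (!length(remaining)) break
    trials <- lapply(remaining, function(v) {
      f1 <- fit_cache(c(current, v))
      df <- length(f1$coefficients) - length(fit_cur$coefficients)
      list(v = v, fit = f1, df = df,
           p = lrt_p(f1$loglik, fit_cur$loglik, df))
    })
    ps <- vapply(trials, `[[`, numeric(1), "p")
    if (!any(ps < p_enter)) {
      for (i in seq_along(trials)) {
        steps[[length(steps) + 1L]] <- data.frame(
          action = "reject", variable = trials[[i]]$v,
          df = trials[[i]]$df, p_value = ps[i],
          stringsAsFactors = FALSE)
      }
      break
    }
    best <- which.min(ps)  # ties break by candidate order
    current <- c(current, trials[[best]]$v)
    fit_cur <- trials[[best]]$fit
    steps[[length(steps) + 1L]] <- data.frame(
      action = "enter", variable = trials[[best]]$v,
      df = trials[[best]]$df, p_value = ps[best], stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, trials[[best]]$v)
    # departure phase
    repeat {
      removable <- setdiff(current, forced)
      if (!length(removable)) break
      drops <- lapply(removable, function(v) {
        f0 <- fit_cache(setdiff(current, v))
        df <- length(fit_cur$coefficients) - length(f0$coefficients)
        list(v = v, fit = f0, df = df,
             p = lrt_p(fit_cur$loglik, f0$loglik, df))
      })
      ps0 <- vapply(drops, `[[`, numeric(1), "p")
      if (max(ps0) <= p_remove) break
      worst <- which.max(ps0)
      current <- setdiff(current, drops[[worst]]$v)
      fit_cur <- drops[[worst]]$fit
      steps[[length(steps) + 1L]] <- data.frame(
        action = "remove", variable = drops[[worst]]$v,
        df = drops[[worst]]$df, p_value = ps0[worst],
        stringsAsFactors = FALSE)
      remaining <- union(remaining, drops[[worst]]$v)
    }
  }
  structure(
    list(steps = if (length(steps)) do.call(rbind, steps) else
           data.frame(action = character(), variable = character(),
                      df = integer(), p_value = numeric()),
         forced = forced, candidate_order = candidates,
         final_variables = current,
         fit = fit_logistic(data, current, status_col)),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> final model:",
      paste(x$final_variables, collapse = " + "), "\n")
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' Re-screen univariably non-significant variables against the full model
#'
#' Second phase of the two-phase selection: each variable excluded after
#' univariable screening is added to the multivariable base model and kept
#' if its block likelihood-ratio test significantly improves the fit.
#'
#' @param data Case-control data frame.
#' @param base_variables Variables of the current multivariable model.
#' @param excluded Variables to re-screen.
#' @param alpha Significance cut-off (default 0.05).
#' @param status_col Outcome column name.
#' @return Character vector of variables to add, with the per-variable
#'   p-values as attribute `p_values`.
#' @export
rescreen_nonsignificant <- function(data, base_variables, excluded,
                                    alpha = 0.05, status_col = "status") {
  if (!length(excluded)) {
    return(structure(character(0), p_values = numeric(0)))
  }
  des0 <- build_design(data, base_variables, status_col)
  f0 <- newton_logistic(des0$X, des0$y)
  p <- vapply(excluded, function(v) {
    des1 <- build_design(data, c(base_variables, v), status_col)
    f1 <- newton_logistic(des1$X, des1$y)
    lrt_p(f1$loglik, f0$loglik,
          length(f1$coefficients) - length(f0$coefficients))
  }, numeric(1))
  structure(excluded[p < alpha], p_values = p)
}

#' Screen pairwise interactions among model variables
#'
#' For each pair, the cross-product dummy block is added to the
#' main-effects model and tested by a block likelihood-ratio test. Pairs
#' whose augmented fit is degenerate (rank deficiency or separation from
#' empty or determining cross-cells, common for sparse factor pairs) get
#' `p_value = NA` and are never retained.
#'
#' @param data Case-control data frame.
#' @param fit_variables Main-effect variables of the model.
#' @param pairs List of length-2 character vectors, or `NULL` for all
#'   pairs of `fit_variables`.
#' @param alpha Significance cut-off (default 0.05).
#' @param status_col Outcome column name.
#' @return Data frame with columns `var1`, `var2`, `df`, `p_value`,
#'   `retained`.
#' @export
interaction_screen <- function(data, fit_variables, pairs = NULL,
                               alpha = 0.05, status_col = "status") {
  if (is.null(pairs)) {
    pairs <- utils::combn(fit_variables, 2, simplify = FALSE)
  }
  if (!length(pairs)) {
    return(data.frame(var1 = character(), var2 = character(),
                      df = integer(), p_value = numeric(),
                      retained = logical()))
  }
  des0 <- build_design(data, fit_variables, status_col)
  f0 <- newton_logistic(des0$X, des0$y)
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2, all(pr %in% fit_variables))
    f1 <- tryCatch(
      fit_logistic_interaction(data, fit_variables, pr, status_col),
      error = function(e) NULL)
    if (is.null(f1)) {
      return(data.frame(var1 = pr[1], var2 = pr[2], df = NA_integer_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    df <- length(f1$coefficients) - length(f0$coefficients)
    data.frame(var1 = pr[1], var2 = pr[2], df = df,
               p_value = lrt_p(f1$loglik, f0$loglik, df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$retained <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Relative risk of a risk-factor profile
#'
#' The profile's relative risk is the product of the fitted odds ratios of
#' its non-reference levels over the included variables (equivalently
#' `exp(sum(beta * x))`); an all-reference profile scores 1. Under the
#' rare-disease assumption these odds ratios approximate relative risks.
#'
#' @param fit A `logistic_fit`.
#' @param profile Named list or character vector mapping each included
#'   variable to one of its levels.
#' @param include Variables contributing to the product; defaults to all
#'   fitted variables.
#' @return Non-negative scalar relative risk.
#' @export
#' @examples
#' d <- generate_case_control(default_cohort_spec(n_cases = 200, seed = 3))
#' fit <- fit_logistic(d, c("smoking", "drinking"))
#' relative_risk(fit, c(smoking = "smoker", drinking = "non-drinker"))
relative_risk <- function(fit, profile, include = fit$variables) {
  stopifnot(inherits(fit, "logistic_fit"))
  bad <- setdiff(include, fit$variables)
  if (length(bad)) {
    stop("variable(s) absent from fit: ", paste(bad, collapse = ", "))
  }
  profile <- as.list(profile)
  lp <- 0
  for (v in include) {
    lev <- profile[[v]]
    if (is.null(lev)) stop("profile is missing a level for '", v, "'")
    lv <- fit$xlevels[[v]]
    if (!lev %in% lv) {
      stop("unknown level '", lev, "' for variable '", v, "'")
    }
    if (lev != lv[1]) {
      cf <- fit$coefficients[paste0(v, lev)]
      if (is.na(cf)) stop("coefficient not found for ", v, lev)
      lp <- lp + cf
    }
  }
  unname(exp(lp))
}
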