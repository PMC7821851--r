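# Bruzzi-type population attributable risk from the fitted model and the
# case covariate distribution, and deflation of composite registry incidence
# into a baseline (reference-profile) hazard.

#' Population attributable risk (Bruzzi case-based estimator)
#'
#' Estimates `PAR = 1 - mean over cases of 1 / rr(x_i)`, where `rr` is the
#' profile relative risk from the fitted model restricted to the included
#' factors. The equivalent stratum-sum form
#' `1 - sum_j rho_j / RR_j` (case fractions `rho_j` over covariate strata)
#' is available for cross-checking.
#'
#' By default the included factors are the fitted variables minus the
#' demographic ones (`age_band`, `sex`): the baseline hazard is already
#' age- and sex-specific, so including them would double count. Pass
#' `factors = fit$variables` for an all-factors PAR.
#'
#' With protective factors in the model (fitted OR < 1, e.g. frequent
#' fresh-fruit intake), the coding reference is not the lowest-risk
#' profile and a reference-anchored PAR can be negative. The default
#' anchor therefore re-expresses every relative risk against the
#' lowest-risk level of each included factor (the usual convention of
#' Gail-type absolute-risk tools), which guarantees `value` in \[0, 1) and
#' a baseline hazard no larger than the composite incidence. Projected
#' absolute risks are invariant to the anchor as long as [absolute_risk()]
#' uses the same one (both default to `"lowest_risk"`).
#'
#' @param fit A [fit_logistic()] result.
#' @param cases Data frame of case records (one row per case) with a level
#'   for every included factor; rows with `status` present are filtered to
#'   cases.
#' @param factors Included factor names; default drops `age_band`, `sex`.
#' @param method `"case_average"` (default) or `"stratum_sum"`.
#' @param anchor `"lowest_risk"` (default) anchors relative risks at the
#'   minimum-OR level of each included factor; `"reference"` uses the
#'   dummy-coding reference levels.
#' @return Object of class `par_estimate`: `value` in \[0, 1) under the
#'   default anchor, `n_cases`, `factors`, `mean_inv_rr`, `anchor_levels`.
#' @export
estimate_par <- function(fit, cases,
                         factors = setdiff(fit$variables,
                                           c("age_band", "sex")),
                         method = c("case_average", "stratum_sum"),
                         anchor = c("lowest_risk", "reference")) {
  method <- match.arg(method)
  anchor <- match.arg(anchor)
  stopifnot(inherits(fit, "logistic_fit"))
  if (!is.null(cases$status)) {
    cases <- cases[cases$status == "case", , drop = FALSE]
  }
  if (!nrow(cases)) stop("no case records supplied")
  rr_of_row <- function(row) {
    relative_risk(fit, lapply(row, as.character), include = factors)
  }
  anchor_levels <- anchor_profile(fit, factors, anchor)
  shift <- relative_risk(fit, anchor_levels, include = factors)
  if (method == "case_average") {
    rr <- vapply(seq_len(nrow(cases)), function(i) {
      rr_of_row(cases[i, factors, drop = FALSE])
    }, numeric(1)) / shift
    if (any(rr == 0)) stop("relative risk of 0 encountered for a case")
    mean_inv <- mean(1 / rr)
  } else {
    key <- interaction(lapply(cases[factors], as.character), drop = TRUE,
                       sep = "\r")
    tab <- table(key)
    rho <- as.numeric(tab) / nrow(cases)
    strata <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    rr <- vapply(seq_len(nrow(strata)), function(i) {
      rr_of_row(stats::setNames(as.list(strata[i, ]), factors))
    }, numeric(1)) / shift
    if (any(rr == 0)) stop("relative risk of 0 encountered for a stratum")
    mean_inv <- sum(rho / rr)
  }
  structure(
    list(value = 1 - mean_inv, n_cases = nrow(cases), factors = factors,
         mean_inv_rr = mean_inv, method = method, anchor = anchor,
         anchor_levels = anchor_levels),
    class = "par_estimate"
  )
}

# Lowest-risk (or coding-reference) level per included factor.
anchor_profile <- function(fit, factors, anchor = "lowest_risk") {
  out <- lapply(stats::setNames(factors, factors), function(v) {
    lv <- fit$xlevels[[v]]
    if (anchor == "reference") return(lv[1])
    beta <- c(0, fit$coefficients[paste0(v, lv[-1])])
    lv[which.min(beta)]
  })
  out
}

#' @export
print.par_estimate <- function(x, ...) {
  cat("<par_estimate> PAR =", format(x$value, digits = 4),
      "from", x$n_cases, "cases over",
      paste(x$factors, collapse = ", "),
      paste0("(", x$anchor, " anchor)"), "\n")
  invisible(x)
}

#' Baseline (reference-profile) hazard from composite incidence
#'
#' Deflates registry incidence by the attributable fraction:
#' `h1(age band, sex) = incidence_rate / 100000 * (1 - PAR)`, converting
#' per-100,000 person-year rates to per-person-year hazards.
#'
#' @param incidence A [rate_table()] of disease incidence (per 100,000
#'   person-years).
#' @param par A `par_estimate` or a bare PAR value in \[0, 1).
#' @return Data frame of class `baseline_hazard` with columns `sex`,
#'   `age_lo`, `age_hi`, `hazard` (per person-year).
#' @export
baseline_hazard <- function(incidence, par) {
  stopifnot(inherits(incidence, "rate_table"))
  p <- if (inherits(par, "par_estimate")) par$value else par
  if (p < 0 || p >= 1) stop("PAR must lie in [0, 1)")
  out <- data.frame(
    sex = incidence$sex, age_lo = incidence$age_lo,
    age_hi = incidence$age_hi,
    hazard = incidence$rate_per_100k / 1e5 * (1 - p),
    stringsAsFactors = FALSE
  )
  attr(out, "par") <- p
  attr(out, "band_width") <- attr(incidence, "band_width")
  class(out) <- c("baseline_hazard", "data.frame")
  out
}

#' Write / read a baseline hazard table as delimited text
#'
#' Comma-separated with header `sex,age_lo,age_hi,hazard` (per person-year).
#' @param x A `baseline_hazard`.
#' @param path File path.
#' @export
write_baseline_hazard <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("sex", "age_lo", "age_hi", "hazard")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_baseline_hazard
#' @export
read_baseline_hazard <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "hazard")
  if (!all(need %in% names(x))) {
    stop("baseline hazard file needs columns: ", paste(need, collapse = ", "))
  }
  x <- x[order(x$sex, x$age_lo), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "band_width") <- x$age_hi[1] - x$age_lo[1]
  class(x) <- c("baseline_hazard", "data.frame")
  x
}
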