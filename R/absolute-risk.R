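# Gail-type projection of an individual's absolute disease risk over a time
# horizon: piecewise-constant cause-specific hazards (profile relative risk
# times the baseline hazard) competing with non-disease mortality, plus the
# derived number needed to investigate and exhaustive risk grids.

# Extract per-band hazards for one sex, clipped to [age, age + tau).
band_slices <- function(tbl, value_col, sex, age, tau) {
  b <- tbl[tbl$sex == sex, , drop = FALSE]
  if (!nrow(b)) stop("no rate-table rows for sex '", sex, "'")
  b <- b[order(b$age_lo), , drop = FALSE]
  if (age < b$age_lo[1] || age + tau > b$age_hi[nrow(b)] + 1e-9) {
    stop("projection interval [", age, ", ", age + tau,
         ") is outside the rate-table support [", b$age_lo[1], ", ",
         b$age_hi[nrow(b)], ")")
  }
  keep <- b$age_hi > age & b$age_lo < age + tau
  b <- b[keep, , drop = FALSE]
  data.frame(
    age_lo = pmax(b$age_lo, age),
    age_hi = pmin(b$age_hi, age + tau),
    value = b[[value_col]]
  )
}

#' Absolute risk of disease over a time horizon
#'
#' Combines the profile's relative risk `r`, the baseline hazard `h1` and
#' the competing (non-disease) mortality `m` in a piecewise-constant
#' competing-risks construction. Over each age band `j` intersecting
#' `[age, age + tau)` with clipped width `Delta_j`, total hazard
#' `h_j + m_j` with `h_j = r * h1_j`:
#' \deqn{increment_j = \frac{h_j}{h_j + m_j} S_{j-1}
#'       (1 - e^{-(h_j + m_j)\Delta_j}),\quad
#'       S_j = S_{j-1} e^{-(h_j + m_j)\Delta_j},\ S_0 = 1}
#' and the absolute risk is the sum of the increments (0 where
#' `h_j + m_j = 0`).
#'
#' Age and sex enter through the rate tables only; by default the fitted
#' demographic odds ratios are excluded from `r` to avoid double counting
#' (set `include_demographics = TRUE` for sensitivity analyses). The
#' relative risk is anchored the same way as [estimate_par()] (default:
#' lowest-risk level of every included factor), so that `r * h1` is
#' invariant to the anchoring convention when the baseline hazard was
#' deflated with a matching PAR.
#'
#' @param fit A [fit_logistic()] result.
#' @param profile Named list with `age` (years), `sex`, and a level for
#'   every non-demographic model variable, e.g.
#'   `list(age = 60, sex = "male", smoking = "smoker", ...)`.
#' @param baseline A [baseline_hazard()] table (per person-year).
#' @param competing A [rate_table()] of non-disease mortality (per 100,000
#'   person-years).
#' @param tau Horizon in years (default 5).
#' @param include_demographics If `TRUE`, demographic variables (`age_band`,
#'   `sex`) present in the fit also contribute to `r`.
#' @param anchor Relative-risk anchoring, as in [estimate_par()];
#'   `"lowest_risk"` (default) or `"reference"`. Must match the anchor used
#'   for the PAR behind `baseline`.
#' @return Object of class `absolute_risk`: `risk`, `rr` (anchored), `tau`,
#'   and the per-band decomposition `bands` (clipped band, hazards,
#'   increment, survival at the band end).
#' @export
absolute_risk <- function(fit, profile, baseline, competing, tau = 5,
                          include_demographics = FALSE,
                          anchor = c("lowest_risk", "reference")) {
  anchor <- match.arg(anchor)
  if (tau <= 0) stop("tau must be positive")
  age <- profile$age
  sex <- profile$sex
  if (is.null(age) || is.null(sex)) stop("profile needs 'age' and 'sex'")
  include <- setdiff(fit$variables, if (include_demographics) character(0)
                     else c("age_band", "sex"))
  r <- relative_risk(fit, profile[setdiff(names(profile),
                                          c("age", "sex"))
                                  ][include], include = include) /
    relative_risk(fit, anchor_profile(fit, include, anchor),
                  include = include)
  hb <- band_slices(baseline, "hazard", sex, age, tau)
  mb <- band_slices(competing, "rate_per_100k", sex, age, tau)
  if (nrow(hb) != nrow(mb) || any(abs(hb$age_lo - mb$age_lo) > 1e-9)) {
    stop("baseline and competing tables have incompatible age bands")
  }
  h <- r * hb$value
  m <- mb$value / 1e5
  delta <- hb$age_hi - hb$age_lo
  total <- h + m
  decay <- exp(-total * delta)
  S_prev <- cumprod(c(1, decay))[seq_along(delta)]
  frac <- ifelse(total > 0, h / total, 0)
  inc <- frac * S_prev * (1 - decay)
  structure(
    list(risk = sum(inc), rr = r, tau = tau, age = age, sex = sex,
         bands = data.frame(age_lo = hb$age_lo, age_hi = hb$age_hi,
                            width = delta, hazard = h, competing = m,
                            increment = inc, survival = S_prev * decay)),
    class = "absolute_risk"
  )
}

#' @export
print.absolute_risk <- function(x, ...) {
  cat("<absolute_risk> ", x$sex, " aged ", x$age, ", rr = ",
      format(x$rr, digits = 4), ": ", x$tau, "-year risk = ",
      format(100 * x$risk, digits = 4), "%  (NNI ",
      nni(x$risk)$individuals, ")\n", sep = "")
  invisible(x)
}

#' Number needed to investigate to identify one case
#'
#' The smallest integer `n` such that `n * risk >= 1`, i.e.
#' `ceiling(1 / risk)`.
#'
#' @param risk Absolute risk, a probability in (0, 1\].
#' @return Object of class `nni_result` with `risk` and `individuals`.
#' @export
#' @examples
#' nni(0.197225)  # 6 individuals
nni <- function(risk) {
  if (inherits(risk, "absolute_risk")) risk <- risk$risk
  if (risk <= 0 || risk > 1) stop("risk must lie in (0, 1]")
  structure(list(risk = risk, individuals = as.integer(ceiling(1 / risk))),
            class = "nni_result")
}

#' @export
print.nni_result <- function(x, ...) {
  cat("<nni_result> risk ", format(100 * x$risk, digits = 6), "% -> ",
      x$individuals, " individuals to investigate per expected case\n",
      sep = "")
  invisible(x)
}

#' Enumerate absolute risks over ages, sexes and factor-level combinations
#'
#' @param fit A [fit_logistic()] result.
#' @param baseline,competing As in [absolute_risk()].
#' @param ages Numeric vector of starting ages (default: band starts of the
#'   baseline table whose full horizon is supported).
#' @param sexes Character vector (default both sexes in the tables).
#' @param levels Named list mapping each non-demographic model variable to
#'   the levels to enumerate (default: all its levels).
#' @param tau Horizon in years.
#' @param anchor Relative-risk anchoring passed to [absolute_risk()].
#' @return Data frame of class `risk_grid`, one row per (sex, age,
#'   combination), ordered by sex, age, then lexicographic levels, with
#'   columns `sex`, `age`, the factor levels, `rr`, `risk`, `risk_percent`
#'   and `nni`.
#' @export
risk_grid <- function(fit, baseline, competing, ages = NULL, sexes = NULL,
                      levels = NULL, tau = 5,
                      anchor = c("lowest_risk", "reference")) {
  anchor <- match.arg(anchor)
  vars <- setdiff(fit$variables, c("age_band", "sex"))
  if (is.null(sexes)) sexes <- sort(unique(baseline$sex))
  if (is.null(ages)) {
    lo <- sort(unique(baseline$age_lo))
    hi_max <- max(baseline$age_hi)
    ages <- lo[lo + tau <= hi_max + 1e-9]
  }
  if (is.null(levels)) {
    levels <- lapply(stats::setNames(vars, vars),
                     function(v) fit$xlevels[[v]])
  } else {
    stopifnot(all(vars %in% names(levels)))
    levels <- levels[vars]
  }
  combos <- expand.grid(rev(levels), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[rev(vars)]
  combos <- combos[do.call(order, combos), , drop = FALSE]
  grid <- expand.grid(seq_len(nrow(combos)), age = ages, sex = sexes,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cmb <- combos[grid[i, 1], , drop = FALSE]
    prof <- c(list(age = grid$age[i], sex = grid$sex[i]),
              as.list(cmb))
    ar <- absolute_risk(fit, prof, baseline, competing, tau = tau,
                        anchor = anchor)
    data.frame(sex = grid$sex[i], age = grid$age[i], cmb,
               rr = ar$rr, risk = ar$risk,
               risk_percent = round(100 * ar$risk, 4),
               nni = if (ar$risk > 0) nni(ar$risk)$individuals else
                 NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_grid", "data.frame")
  out
}

#' Write a risk grid as delimited text
#'
#' Comma-separated with columns sex, age, one per factor, rr, risk_percent
#' (4 decimal places), nni.
#' @param x A `risk_grid`.
#' @param path File path.
#' @export
write_risk_grid <- function(x, path) {
  out <- as.data.frame(x)
  out$rr <- signif(out$rr, 6)
  out$risk <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
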