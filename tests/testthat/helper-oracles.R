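# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the logistic oracle is a concave coordinate-wise grid
# search, the absolute-risk oracle a discrete-time integrator, the AUC
# oracle explicit pair counting.

# Log-likelihood of a logistic model (direct formula).
oracle_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

# Coordinate-wise grid maximization of the (concave) logistic
# log-likelihood: bracket each coefficient coarsely, then refine the grid
# down to step 1e-3. No derivatives, no Newton steps.
oracle_grid_logistic <- function(X, y) {
  beta <- numeric(ncol(X))
  for (step in c(0.5, 0.1, 0.02, 0.004, 1e-3)) {
    repeat {
      moved <- FALSE
      for (j in seq_along(beta)) {
        grid <- beta[j] + seq(-10, 10) * step
        ll <- vapply(grid, function(b) {
          bb <- beta
          bb[j] <- b
          oracle_loglik(bb, X, y)
        }, numeric(1))
        best <- grid[which.max(ll)]
        if (abs(best - beta[j]) > step / 2) moved <- TRUE
        beta[j] <- best
      }
      if (!moved) break
    }
  }
  beta
}

# Discrete-time integrator over the same piecewise-constant hazards as the
# banded projection: steps of `dt` years, per-step cause-specific event
# probability h/(h+m) * S * (1 - exp(-(h+m) dt)).
oracle_risk_integrator <- function(age, tau, band_lo, band_hi, h, m,
                                   dt = 1e-3) {
  end <- age + tau
  cuts <- sort(unique(c(seq(age, end, by = dt), end,
                        band_lo[band_lo > age & band_lo < end])))
  lookup <- function(t) max(which(band_lo <= t + 1e-12))
  S <- 1
  risk <- 0
  for (i in seq_len(length(cuts) - 1)) {
    w <- cuts[i + 1] - cuts[i]
    j <- lookup(cuts[i])
    tot <- h[j] + m[j]
    p_any <- 1 - exp(-tot * w)
    if (tot > 0) risk <- risk + h[j] / tot * S * p_any
    S <- S * exp(-tot * w)
  }
  risk
}

# AUC by explicit enumeration of all case-control pairs.
oracle_auc_pairs <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) {
    for (b in ct) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cs) * length(ct))
}

# Closed-form PAR of the generating multiplicative model, anchored at the
# lowest-risk level of each included factor:
# E_case[1/rr_f] = R_min,f / sum_j p_j R_j per factor, independent factors.
oracle_par_true <- function(spec, factors) {
  mean_inv <- 1
  for (f in spec$factors[factors]) {
    R <- exp(f$log_or)
    mean_inv <- mean_inv * min(R) / sum(f$control_probs * R)
  }
  1 - mean_inv
}

# Anchored true relative risk of a profile under the generating model.
oracle_rr_true <- function(spec, profile, factors) {
  rr <- 1
  for (v in factors) {
    f <- spec$factors[[v]]
    R <- exp(f$log_or)
    rr <- rr * R[match(profile[[v]], f$levels)] / min(R)
  }
  rr
}

# Minimal hand-built logistic_fit for tests that need exact known ORs.
# `ors` is a named list: variable -> named numeric of per-level odds
# ratios, first element the reference (OR 1).
make_fit <- function(ors, intercept = -4) {
  coefs <- c("(Intercept)" = intercept)
  xlevels <- list()
  for (v in names(ors)) {
    lv <- names(ors[[v]])
    stopifnot(ors[[v]][1] == 1)
    xlevels[[v]] <- lv
    coefs[paste0(v, lv[-1])] <- log(ors[[v]][-1])
  }
  structure(
    list(coefficients = coefs,
         vcov = diag(length(coefs)), loglik = NA_real_, converged = TRUE,
         iterations = 0L, variables = names(ors), xlevels = xlevels,
         coding = lapply(xlevels, function(l) list(levels = l,
                                                   reference = l[1])),
         n = 0L, n_cases = 0L),
    class = "logistic_fit"
  )
}

# Constant-rate tables over the default 40-75 support, for hand-checked
# projections.
flat_baseline <- function(hazard, band_width = 5) {
  lo <- seq(40, 75 - band_width, by = band_width)
  out <- data.frame(sex = rep(c("female", "male"), each = length(lo)),
                    age_lo = rep(lo, 2), age_hi = rep(lo + band_width, 2),
                    hazard = hazard)
  class(out) <- c("baseline_hazard", "data.frame")
  attr(out, "band_width") <- band_width
  out
}

flat_mortality <- function(rate_per_100k) {
  generate_rate_table(base_rate = rate_per_100k, age_slope = 0,
                      sex_ratio = 1)
}
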