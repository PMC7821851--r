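# Competing-risk-adjusted absolute-risk projection, NNI and risk grids.

fit2 <- make_fit(list(
  smoking = c("non-smoker" = 1, smoker = 1.27),
  drinking = c("non-drinker" = 1, drinker = 3.75)
))
prof_hi <- list(age = 60, sex = "male", smoking = "smoker",
                drinking = "drinker")
prof_lo <- list(age = 60, sex = "male", smoking = "non-smoker",
                drinking = "non-drinker")

test_that("zero baseline hazard gives zero risk; competing death reduces risk", {
  mort <- flat_mortality(1000)
  expect_equal(absolute_risk(fit2, prof_hi, flat_baseline(0), mort)$risk, 0)
  with_m <- absolute_risk(fit2, prof_hi, flat_baseline(2e-3), mort)
  no_m <- absolute_risk(fit2, prof_hi, flat_baseline(2e-3),
                        flat_mortality(0))
  expect_lt(with_m$risk, no_m$risk)
})

test_that("constant hazard and no competing mortality give 1 - exp(-r h tau)", {
  h1 <- 2e-3
  ar <- absolute_risk(fit2, prof_hi, flat_baseline(h1), flat_mortality(0),
                      tau = 5)
  r <- 1.27 * 3.75   # anchored rr: both references are the lowest risk
  expect_equal(ar$rr, r, tolerance = 1e-12)
  expect_equal(ar$risk, 1 - exp(-r * h1 * 5), tolerance = 1e-12)
  # reference profile: r = 1
  ar0 <- absolute_risk(fit2, prof_lo, flat_baseline(h1), flat_mortality(0))
  expect_equal(ar0$risk, 1 - exp(-h1 * 5), tolerance = 1e-12)
})

test_that("risk is monotone in rr and bounded by 1 - final survival", {
  base <- flat_baseline(1e-3)
  mort <- flat_mortality(800)
  a1 <- absolute_risk(fit2, prof_lo, base, mort)
  a2 <- absolute_risk(fit2, prof_hi, base, mort)
  expect_gt(a2$risk, a1$risk)
  for (a in list(a1, a2)) {
    expect_equal(a$risk, sum(a$bands$increment), tolerance = 1e-15)
    expect_true(all(a$bands$increment >= 0))
    expect_true(all(diff(c(1, a$bands$survival)) <= 1e-15))
    expect_lte(a$risk, 1 - a$bands$survival[nrow(a$bands)] + 1e-12)
  }
})

test_that("banded projection matches the fine-grid integrator (randomized)", {
  for (seed in 1:100) {
    set.seed(seed)
    bw <- sample(c(2, 5), 1)
    lo <- seq(40, 75 - bw, by = bw)
    h1 <- runif(length(lo), 0, 0.02)
    m <- runif(length(lo), 0, 0.05)
    r <- runif(1, 0.2, 30)
    age <- runif(1, 40, 70)
    tau <- runif(1, 0.5, min(5, 75 - age))
    base <- data.frame(sex = "male", age_lo = lo, age_hi = lo + bw,
                       hazard = h1)
    class(base) <- c("baseline_hazard", "data.frame")
    mort <- rate_table(data.frame(sex = "male", age_lo = lo,
                                  age_hi = lo + bw,
                                  rate_per_100k = m * 1e5))
    fit <- make_fit(list(x = c(lo = 1, hi = r)))
    # reference anchor so the projection uses exactly r (r < 1 allowed)
    ar <- absolute_risk(fit, list(age = age, sex = "male", x = "hi"),
                        base, mort, tau = tau, anchor = "reference")
    # the integrator sees the same clipped piecewise-constant hazards
    oracle <- oracle_risk_integrator(age, tau, lo, lo + bw, r * h1, m)
    expect_equal(ar$risk, oracle, tolerance = 1e-6)
  }
})

test_that("small-hazard limit is r * sum(h1 * width)", {
  base <- flat_baseline(1e-6)
  ar <- absolute_risk(fit2, prof_hi, base, flat_mortality(0), tau = 5)
  expect_equal(ar$risk, ar$rr * 1e-6 * 5, tolerance = 1e-3)
})

test_that("projection rejects unsupported ages and horizons", {
  base <- flat_baseline(1e-3)
  mort <- flat_mortality(100)
  expect_error(absolute_risk(fit2, list(age = 72, sex = "male",
                                        smoking = "smoker",
                                        drinking = "drinker"),
                             base, mort, tau = 5), "outside")
  expect_error(absolute_risk(fit2, prof_hi, base, mort, tau = 0),
               "positive")
})

test_that("NNI is the ceiling of the reciprocal risk", {
  expect_equal(nni(0.197225)$individuals, 6L)    # published: 6
  expect_equal(nni(0.045162)$individuals, 23L)   # published: 23
  expect_equal(nni(0.062386)$individuals, 17L)   # published: 17
  expect_equal(nni(0.071621)$individuals, 14L)   # published: 14
  expect_equal(nni(0.005128)$individuals, 196L)  # published: 196
  expect_equal(nni(0.038644)$individuals, 26L)   # published: 26
  expect_equal(nni(1)$individuals, 1L)
  expect_error(nni(0), "risk")
})

test_that("risk_grid enumerates deterministically and peaks where it should", {
  d <- generate_case_control(default_cohort_spec(n_cases = 500, seed = 13))
  fit <- fit_logistic(d, c("age_band", "sex", "smoking", "drinking",
                           "education", "hot_food", "pickled_food",
                           "fruit"))
  inc <- generate_rate_table(100, 0.08, 1.2)
  mort <- generate_rate_table(1000, 0.09, 1.3)
  baseline <- baseline_hazard(inc, estimate_par(fit, d))
  g <- risk_grid(fit, baseline, mort)
  # 6 binary lifestyle factors x 7 age-band starts x 2 sexes
  expect_equal(nrow(g), 2^6 * 7 * 2)
  g2 <- risk_grid(fit, baseline, mort)
  expect_identical(g, g2)
  expect_identical(order(g$sex, g$age), seq_len(nrow(g)))
  # maximum at the oldest supported age with the highest-rr combination
  top <- g[which.max(g$risk), ]
  expect_equal(top$age, 70)
  expect_equal(top$rr, max(g$rr))
  # within a fixed profile, risk non-decreasing in age on the default
  # increasing schedules
  key <- interaction(g[setdiff(names(g), c("age", "rr", "risk",
                                           "risk_percent", "nni"))])
  for (kk in unique(key)) {
    sub <- g[key == kk, ]
    expect_true(all(diff(sub$risk[order(sub$age)]) >= 0))
  }
  # export round-trips through text
  f <- tempfile(fileext = ".csv")
  write_risk_grid(g, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(g))
  expect_equal(back$risk_percent, g$risk_percent, tolerance = 1e-12)
})

test_that("fitted pipeline reproduces the generating model's true risks", {
  spec <- default_cohort_spec(n_cases = 2000, controls_per_case = 5,
                              seed = 41)
  d <- generate_case_control(spec)
  vars <- c("age_band", "sex", "smoking", "drinking", "education",
            "hot_food", "pickled_food", "fruit")
  lifestyle <- setdiff(vars, c("age_band", "sex"))
  fit <- fit_logistic(d, vars)
  inc <- generate_rate_table(100, 0.08, 1.2)
  mort <- generate_rate_table(1000, 0.09, 1.3)
  baseline <- baseline_hazard(inc, estimate_par(fit, d))
  baseline_true <- baseline_hazard(inc, oracle_par_true(spec, lifestyle))

  set.seed(7)
  rel_err <- replicate(40, {
    prof <- c(list(age = sample(seq(40, 70, 5), 1),
                   sex = sample(c("male", "female"), 1)),
              lapply(spec$factors[lifestyle],
                     function(f) sample(f$levels, 1)))
    est <- absolute_risk(fit, prof, baseline, mort)$risk
    hb <- baseline_true[baseline_true$sex == prof$sex, ]
    mb <- mort[mort$sex == prof$sex, ]
    truth <- oracle_risk_integrator(
      prof$age, 5, hb$age_lo, hb$age_hi,
      oracle_rr_true(spec, prof, lifestyle) * hb$hazard,
      mb$rate_per_100k / 1e5)
    if (truth > 1e-3) abs(est - truth) / truth else NA_real_
  })
  expect_lt(median(rel_err, na.rm = TRUE), 0.15)
})
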