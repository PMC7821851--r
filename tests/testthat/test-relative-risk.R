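# Crude odds ratios, the Newton logistic fitter, the two-phase selection and
# profile relative risks.

test_that("crude_or basics: symmetry, CI closure, zero cells", {
  expect_equal(unname(crude_or(10, 10, 10, 10)["or"]), 1)
  x <- crude_or(30, 70, 20, 80)
  expect_lt(x["ci_low"], x["or"])
  expect_gt(x["ci_high"], x["or"])
  wider <- crude_or(30, 70, 20, 80, conf_level = 0.99)
  expect_lt(wider["ci_low"], x["ci_low"])
  expect_gt(wider["ci_high"], x["ci_high"])
  expect_error(crude_or(0, 10, 5, 5), "zero cell.*a")
  corrected <- crude_or(0, 10, 5, 5, correction = TRUE)
  expect_equal(unname(corrected["or"]), (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("intercept-only and saturated logistic fits match closed forms", {
  d <- data.frame(status = factor(rep(c("case", "control"), c(30, 90)),
                                  levels = c("control", "case")),
                  x = factor(c(rep(c("no", "yes"), c(18, 12)),
                               rep(c("no", "yes"), c(72, 18)))))
  f0 <- fit_logistic(d, character(0))
  expect_equal(unname(f0$coefficients), log(30 / 90), tolerance = 1e-10)
  f1 <- fit_logistic(d, "x")
  or_2x2 <- crude_or(12, 18, 18, 72)["or"]
  expect_equal(exp(unname(f1$coefficients["xyes"])), unname(or_2x2),
               tolerance = 1e-8)
  expect_true(f1$converged)
  expect_lt(f1$score_norm, 1e-6)
  # covariance symmetric positive definite
  expect_equal(f1$vcov, t(f1$vcov))
  expect_true(all(eigen(f1$vcov, only.values = TRUE)$values > 0))
})

test_that("Newton MLE agrees with glm as an independent route", {
  d <- generate_case_control(default_cohort_spec(n_cases = 400, seed = 21))
  vars <- c("age_band", "sex", "smoking", "drinking", "fruit")
  fit <- fit_logistic(d, vars)
  ref <- glm(status == "case" ~ age_band + sex + smoking + drinking + fruit,
             family = binomial(), data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("Newton MLE matches the grid-search oracle on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(15:40, 1)
    p <- sample(1:3, 1)
    X <- cbind(1, matrix(rbinom(n * p, 1, 0.5), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
    beta_true <- runif(p + 1, -1, 1)
    y <- rbinom(n, 1, plogis(drop(X %*% beta_true)))
    if (length(unique(y)) < 2) next
    ours <- tryCatch(escrisk:::newton_logistic(X, y), error = function(e) e)
    if (inherits(ours, "error")) next  # separable / rank-deficient draw
    expect_lt(max(abs(ours$coefficients - oracle_grid_logistic(X, y))),
              5e-3)
  }
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(status = factor(rep(c("case", "control"), 20),
                                  levels = c("control", "case")),
                  a = factor(rep(c("x", "y"), each = 20)),
                  b = factor(rep(c("u", "v"), each = 20)))  # b aliases a
  expect_error(fit_logistic(d, c("a", "b")), "rank deficient")
  sep <- data.frame(status = factor(rep(c("case", "control"), each = 20),
                                    levels = c("control", "case")),
                    x = factor(rep(c("yes", "no"), each = 20)))
  expect_error(fit_logistic(sep, "x"), "separation")
  one_class <- data.frame(status = factor(rep("case", 5),
                                          levels = c("control", "case")),
                          x = factor(c("a", "b", "a", "b", "a")))
  expect_error(fit_logistic(one_class, "x"), "both cases and controls")
})

test_that("relative_risk is the product of the profile's odds ratios", {
  fit <- make_fit(list(
    drinking = c("non-drinker" = 1, drinker = 3.75),
    hot_food = c("<2/wk" = 1, ">=2/wk" = 2.72),
    fruit = c("<2/wk" = 1, ">=2/wk" = 0.25)
  ))
  ref <- list(drinking = "non-drinker", hot_food = "<2/wk",
              fruit = "<2/wk")
  expect_equal(relative_risk(fit, ref), 1)
  prof <- list(drinking = "drinker", hot_food = ">=2/wk", fruit = "<2/wk")
  expect_equal(relative_risk(fit, prof), 3.75 * 2.72, tolerance = 1e-12)
  # single-deviation multiplicativity
  rr_each <- vapply(names(prof), function(v) {
    one <- ref
    one[[v]] <- prof[[v]]
    relative_risk(fit, one)
  }, numeric(1))
  expect_equal(relative_risk(fit, prof), prod(rr_each), tolerance = 1e-12)
  # single-factor fit equals that factor's OR
  expect_equal(relative_risk(fit, prof, include = "hot_food"), 2.72)
  expect_error(relative_risk(fit, list(drinking = "heavy",
                                       hot_food = "<2/wk",
                                       fruit = "<2/wk")), "unknown level")
  expect_error(relative_risk(fit, prof, include = "salt"), "absent")
})

test_that("forward selection is deterministic and honours the cut-offs", {
  d <- generate_case_control(default_cohort_spec(n_cases = 2000, seed = 31))
  forced <- c("age_band", "sex", "smoking", "drinking")
  cands <- c("education", "hot_food", "pickled_food", "fruit",
             "family_history", "gi_disease")
  tr1 <- forward_select(d, forced, cands)
  tr2 <- forward_select(d, forced, cands)
  expect_identical(tr1$steps, tr2$steps)
  expect_true(all(forced %in% tr1$final_variables))
  expect_true(all(c("education", "hot_food", "pickled_food", "fruit") %in%
                    tr1$final_variables))
  entered <- tr1$steps[tr1$steps$action == "enter", ]
  expect_true(all(entered$p_value < 0.05))
  expect_error(forward_select(d, forced, c("smoking", "fruit")),
               "disjoint")
  expect_error(forward_select(d, forced, cands, p_enter = 0.2,
                              p_remove = 0.1), "p_enter")
})

test_that("no candidate below the entry cut-off leaves the forced model", {
  # pure-noise candidates at small n: force an empty selection
  fs <- list(
    factor_spec("sex", c("female", "male"), c(.5, .5), c(0, log(2))),
    factor_spec("n1", c("a", "b"), c(.5, .5), c(0, 0)),
    factor_spec("n2", c("a", "b"), c(.5, .5), c(0, 0))
  )
  d <- generate_case_control(cohort_spec(fs, n_cases = 120,
                                         controls_per_case = 2,
                                         matching_factors = "sex",
                                         seed = 8))
  tr <- forward_select(d, forced = "sex", candidates = c("n1", "n2"),
                       p_enter = 1e-6)
  expect_identical(tr$final_variables, "sex")
  expect_true(all(tr$steps$action == "reject"))
})

test_that("re-screening recovers a conditionally associated variable", {
  expect_identical(rescreen_nonsignificant(
    generate_case_control(default_cohort_spec(n_cases = 50, seed = 1)),
    "sex", character(0)), structure(character(0), p_values = numeric(0)))

  # a factor masked marginally but associated conditionally: protective
  # exposure concentrated among drinkers
  set.seed(99)
  n <- 20000
  drink <- rbinom(n, 1, 0.3)
  z <- rbinom(n, 1, plogis(-1 + 2.5 * drink))   # correlated exposure
  eta <- -2 + 1.4 * drink - 1.2 * z
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(
    status = factor(ifelse(y == 1, "case", "control"),
                    levels = c("control", "case")),
    drinking = factor(ifelse(drink == 1, "drinker", "non-drinker"),
                      levels = c("non-drinker", "drinker")),
    z = factor(ifelse(z == 1, "yes", "no"), levels = c("no", "yes")))
  added <- rescreen_nonsignificant(d, "drinking", "z")
  expect_identical(as.character(added), "z")
})

test_that("interaction screening detects a planted interaction and not noise", {
  sim_pair <- function(n, g, seed) {
    set.seed(seed)
    smoke <- rbinom(n, 1, 0.3)
    drink <- rbinom(n, 1, 0.15)
    eta <- -2.5 + 0.3 * smoke + 1.2 * drink + g * smoke * drink
    y <- rbinom(n, 1, plogis(eta))
    data.frame(
      status = factor(ifelse(y == 1, "case", "control"),
                      levels = c("control", "case")),
      smoking = factor(ifelse(smoke == 1, "smoker", "non-smoker"),
                       levels = c("non-smoker", "smoker")),
      drinking = factor(ifelse(drink == 1, "drinker", "non-drinker"),
                        levels = c("non-drinker", "drinker")))
  }
  # power: strong smoking x drinking interaction (log-OR 1) at n = 20,000
  hits <- vapply(1:10, function(s) {
    scr <- interaction_screen(sim_pair(20000, 1.0, s),
                              c("smoking", "drinking"),
                              pairs = list(c("smoking", "drinking")))
    scr$retained
  }, logical(1))
  expect_gte(sum(hits), 9)
  # type-I: no interaction, retention stays near alpha = 0.05
  false_hits <- vapply(1:60, function(s) {
    scr <- interaction_screen(sim_pair(3000, 0, 1000 + s),
                              c("smoking", "drinking"),
                              pairs = list(c("smoking", "drinking")))
    scr$retained
  }, logical(1))
  expect_lte(sum(false_hits), qbinom(0.9995, 60, 0.05))
  # empty pair list
  empty <- interaction_screen(sim_pair(500, 0, 1), c("smoking", "drinking"),
                              pairs = list())
  expect_equal(nrow(empty), 0)
})
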