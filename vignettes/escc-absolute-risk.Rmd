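---
title: "Estimating individualized 5-year absolute risk of esophageal squamous cell carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individualized 5-year absolute risk of esophageal squamous cell carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(escrisk)
```

## The problem

Esophageal squamous cell carcinoma (ESCC) is heavily concentrated in a few
high-incidence regions, notably around the Taihang Mountains in northern
China, where endoscopic screening of everyone over 40 is impractical.
A useful triage tool answers a personal question from questionnaire data
alone: *given this person's age, sex and lifestyle, what is the probability
that they develop ESCC in the next five years, allowing for the chance
that they die of something else first?* People with a very low absolute
risk can be spared an invasive endoscopy; people with a high one are the
efficient targets for it.

`escrisk` implements that estimate as a four-stage pipeline in the
tradition of Gail-type absolute-risk models:

1. **Relative risk.** A multiplicative odds model fitted to
   frequency-matched case-control data by unconditional logistic
   regression. Under the rare-disease assumption the fitted odds ratios
   approximate relative risks, and a profile's relative risk `r` is the
   product of its non-reference odds ratios.
2. **Population attributable risk (PAR).** Bruzzi's case-based estimator,
   `PAR = 1 - mean over cases of 1 / r(x_i)`, which needs only the case
   covariate distribution and the fitted model — no cohort follow-up.
3. **Baseline hazard.** Registry incidence is a population composite; the
   hazard of a *lowest-risk* individual is obtained by deflation,
   `h1(age band, sex) = incidence(age band, sex) * (1 - PAR)`.
4. **Absolute risk.** Over each 5-year age band `j` that the projection
   horizon crosses, the cause-specific hazard `h_j = r * h1_j` competes
   with non-ESCC mortality `m_j`:
   `increment_j = h_j / (h_j + m_j) * S_{j-1} * (1 - exp(-(h_j + m_j) * width_j))`,
   with survival `S_j = S_{j-1} * exp(-(h_j + m_j) * width_j)` from
   `S_0 = 1`. The 5-year absolute risk is the sum of the increments,
   and the number needed to investigate (NNI) to find one case is
   `ceiling(1 / risk)`.

## Why the synthetic cohort exists, and what it emulates

The original study records (244 newly diagnosed ESCC cases, 1,220 healthy
controls from Linzhou and Ci counties) are available only on request, and
the registry rate tables sit in unavailable supplementary material. So
that every stage stays testable, `generate_case_control()` produces a
frequency-matched case-control study with the same design and published
effect sizes:

* controls are drawn factor-wise from the published control-arm
  prevalences (drinking 7.79%, smoking 28.77%, hot food ≥2/wk 11.97%,
  pickled/salted food ≥2/wk 6.23%, fresh fruit ≥2/wk 58.61%, education
  >6 years 44.67%);
* cases are drawn factor-wise from the *tilted* distribution
  `P(level j | case) = p_j R_j / sum_k p_k R_k` with `R_j` the published
  adjusted odds ratios (drinking 3.75, smoking 1.27, hot food 2.72,
  pickled food 2.45, fruit 0.25, education 0.38) — the exact case-control
  identity of a no-interaction multiplicative odds model;
* the control joint distribution over the matching factors (5-year age
  band × sex) is then set by quota to replicate the realized case
  distribution at the design ratio (5:1), using largest-remainder
  apportionment for non-integer quotas. The "±5 years" matching of the
  source study is realized as exact quota matching on 5-year bands
  (40–44, …, 70–74); published 10-year age margins are split evenly over
  their two 5-year bands, which share the 10-year group's adjusted OR.
* family history of upper-GI cancer and history of upper-GI disease are
  carried as *conditionally null* candidates (log-OR 0): their published
  associations are crude only, and the study's selection dropped both, so
  they give the two-phase selection realistic negative examples.

The generator assumes the factors are mutually independent within each
arm. Real questionnaire data are not: smoking and drinking co-occur,
diet correlates with education, and matching factors correlate with
lifestyle. Passing tests on this cohort therefore demonstrate that the
*estimators* are correct under the generating model — not that the model
is a faithful portrait of rural Henan. Two consequences worth keeping in
mind:

* the "parameter recovery" tests apply to the six lifestyle factors only.
  Frequency matching *forces* the control margin over age band and sex to
  equal the case margin, so the generating age/sex log-odds-ratios are by
  design not recoverable from the matched data (their fitted coefficients
  converge to about zero). That is a property of matched designs, not a
  bug;
* confounding-driven phenomena (e.g. a variable that is null marginally
  but associated conditionally) are exercised by purpose-built scenarios
  in the tests rather than by the default generator.

Synthetic rate tables stand in for the unavailable registry data.
`generate_rate_table()` uses a deterministic log-linear age trend,
`rate = base * exp(slope * (age mid - 60)) * sex_ratio^[male]`, per
100,000 person-years over 5-year bands from 40 to 75. The pipeline
defaults are a scientist's reading of the setting rather than fitted
values: ESCC incidence `base = 100` per 100,000 at age 60 (the published
order of magnitude for these counties), `slope = 0.08` per year (roughly
a doubling per decade, typical of ESCC incidence curves), male/female
ratio 1.2; non-ESCC mortality `base = 1000` per 100,000, `slope = 0.09`
(a Gompertz-like all-cause curve), ratio 1.3. Absolute-risk *values*
computed from these tables are therefore illustrative; the published
per-profile risks are not reproducible without the original supplementary
tables, and the package does not claim to reproduce them.

## The two-phase variable selection

The model is built the way the source study describes:

1. age band, sex, tobacco smoking and alcohol drinking are forced in
   a priori;
2. the remaining candidates enter by forward selection with entry
   p < 0.05 and departure p > 0.10. The entry/departure test is a block
   likelihood-ratio test (all dummy columns of a factor at once) — the
   study names only the cut-offs, and the LRT is the natural block test;
3. candidates that failed univariable screening are re-screened against
   the multivariable model (`rescreen_nonsignificant()`) and kept if they
   improve the fit at p < 0.05;
4. all pairwise cross-product terms are screened
   (`interaction_screen()`); pairs whose augmented fit is degenerate
   (empty cross-cells) are reported as `NA` and never retained.

The candidate *order* is a configuration input. The study ordered
candidates by a random-forest importance score; that ranking is outside
this package's scope, and the default order is the study's final
inclusion list followed by the remaining candidates alphabetically. With
a block-LRT forward step the order only breaks exact ties, so this choice
is inert in practice.

## Numerical choices

* **Logistic fitter.** Newton–Raphson on the binomial log-likelihood,
  convergence at max |score| < 1e-8 or relative log-likelihood change
  < 1e-10, at most 100 iterations; covariance is the inverse observed
  information. Any |coefficient| exceeding 15 during iteration is
  reported as complete/quasi-separation with an error rather than a
  silently divergent estimate. Rank-deficient designs error naming the
  collinear columns. The fitter is cross-checked in the tests against
  `glm()` and against a derivative-free coordinate grid search.
* **Crude odds ratios.** Plain cross-products with Wald intervals on the
  log scale; zero cells are a hard error by default (a Haldane–Anscombe
  0.5 correction is available by flag) so that published-table arithmetic
  is reproduced exactly.
* **PAR anchoring.** With protective factors in the model (fruit,
  education), the dummy-coding reference is *not* the lowest-risk profile
  and the reference-anchored Bruzzi PAR is negative (the reference
  profile is riskier than the population average). Following the
  convention of Gail-type tools, `estimate_par()` and `absolute_risk()`
  anchor relative risks at the lowest-risk level of each included factor
  by default, which keeps PAR in [0, 1) and the baseline hazard below the
  composite incidence. Projected absolute risks are invariant to the
  anchor as long as both stages use the same one; `anchor = "reference"`
  is available for comparison.
* **PAR factor set.** The default excludes age band and sex: the baseline
  hazard is already age- and sex-specific, and including their odds
  ratios would double-count demography. The same exclusion applies to the
  profile relative risk in `absolute_risk()`
  (`include_demographics = TRUE` reverses both for sensitivity analyses).
* **Hazard conversion.** Rates per 100,000 person-years are divided by
  1e5 to give per-person-year hazards — the usual rare-event
  approximation; no `-log(1-x)` transform.
* **Bands.** Half-open `[lo, hi)`: a person aged exactly at a band edge
  starts in that band, and the horizon end is exclusive. A projection
  window extending past the table support is an error, not an
  extrapolation.
* **ROC/AUC.** Rank-based Mann–Whitney AUC with ties counted one half;
  DeLong-type placement variance for the CI; Youden's J for the optimal
  cutoff (the study marks optimal cut-off points without naming a
  criterion), ties resolved to the lower threshold. Cross-validation uses
  outcome-stratified folds (a 1:5 case:control ratio makes unstratified
  folds fragile) and pools all out-of-fold scores into one ROC, matching
  the convention of reporting a single cross-validated AUC. Variable
  selection is frozen outside the folds by default, as the single
  reported model suggests; re-running selection per fold can be done by
  calling `forward_select()` inside a custom loop.

## Problem sizes used in the test-suite simulations

Simulation-based checks use sizes chosen to make the tested property
sharp while keeping the suite quick to run: parameter recovery and
selection operating characteristics use 100 replicates at 2,000 cases
with 5:1 controls; PAR consistency one cohort of 50,000 cases;
tilting consistency 50,000 cases; interaction power 10 replicates at
n = 20,000 and type-I behaviour 60 replicates at n = 3,000; the
CV-vs-apparent optimism check 10 study-sized replicates (244 cases). The
oracle comparisons (grid-search MLE, discrete-time risk integrator,
pair-counting AUC) are exhaustive at small n where enumeration is exact.

## Known limitations

* Factor-wise independence in the generator (above): correct estimators,
  idealized data.
* The PAR is a single scalar, not age-specific, mirroring the single
  published value; an age-varying PAR would need cohort or registry
  covariate data the design does not include.
* No confidence intervals on PAR or on absolute risks; the model
  covariance is available for delta-method extensions.
* Conditional logistic regression (matched-set analysis) and penalized
  fits are out of scope; the unconditional fit with matching factors as
  covariates follows the source analysis.
* Absolute-risk magnitudes depend directly on the rate tables supplied;
  with the synthetic defaults they are plausible for a high-incidence
  region but not comparable person-for-person with the published table.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(run_config(out_dir = "escc_run", seed = 1))

# the fitted odds-ratio table, PAR and the risk grid:
summary(res$fit)
res$par
head(res$grid[order(-res$grid$risk), ])

# one individual:
prof <- list(age = 70, sex = "male", smoking = "smoker",
             drinking = "drinker", education = "<=6y",
             hot_food = ">=2/wk", pickled_food = ">=2/wk", fruit = "<2/wk")
ar <- absolute_risk(res$fit, prof, res$baseline, res$mortality)
ar
nni(ar)
```
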