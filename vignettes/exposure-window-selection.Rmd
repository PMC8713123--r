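---
title: "Exposure-window selection with penalized additive models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-window selection with penalized additive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the model and
its assumptions, the tunable constants and why they default as they do, what
the synthetic-data generator does and does not emulate, the numerical
choices inside the fitting engine, and the places where the design was
genuinely open and a decision had to be made. It states no empirical result
that the test suite does not itself compute.

## 1. The question and the model

A cross-sectional cohort is scored for disease severity once, at
recruitment, and the severity score is dichotomized (here: a skin-severity
index split at 10, i.e. clear/mild versus moderate/severe). Ambient
exposure is summarized per participant as the trailing mean of a daily
environmental series over a candidate window preceding the recruitment
date. The candidate windows are 0 (the recruitment-day value itself), 7,
15, 30, 60, 90, 120, 180, 270 and 365 days. The convention for a window of
N > 0 days is the mean over the N calendar days ending the day *before*
recruitment: the phrase "preceding recruitment" is read literally, and the
day-of value is kept as a separate tenth candidate rather than folded into
the windows. This is auditable in `trailing_mav()` and tested against
direct arithmetic.

The outcome model is a penalized additive logistic regression,

$$\operatorname{logit} E[y_i] = f_1(X_i) + f_2(\text{age}) + f_3(\text{BMI})
 + f_4(\text{lon},\text{lat}) + f_5(\text{TEWL}) + f_6(\text{SH})
 + \text{sex} + \text{season} + \text{investigator} + \text{class},$$

with each $f$ a penalized smooth. Season comes from fixed calendar
solstice/equinox cut-offs (Mar 20, Jun 21, Sep 22, Dec 21, boundary day
starting the new season); sub-day astronomical precision is immaterial for
a seasonal factor and would add an ephemeris dependency. The nine-class
socio-economic classification collapses to higher (1–3), middle (4–6) and
working (7–9); the source tables for this convention overlap at class 6 and
the tabulated form (6 = middle) was followed — a flagged decision, recorded
in the code's documentation.

Model support is measured on the Akaike scale with effective degrees of
freedom: $\mathrm{AIC} = -2\,\hat\ell + 2\,\mathrm{EDF}$, where EDF is the
trace of the influence matrix of the converged penalized fit (plus one for
the Gaussian scale). This is the *conditional* AIC; engines that apply a
smoothing-uncertainty correction will print slightly different numbers
(a cross-engine check in the test suite bounds the difference on a shared
fit at a few units, with per-term EDFs agreeing to about two decimals).
All within-package comparisons use the one definition consistently, which
is what ΔAIC-based selection requires.

## 2. The selection machinery

**Window screening.** Per variable, ten models (confounders plus one smooth
of one window column) are fitted; the lowest-AIC window moves forward. Ties
break toward the shorter window — shorter exposure histories are the more
conservative claim.

**Collinearity reduction.** Long-window averages of co-measured series are
often correlated beyond what stable fitting tolerates. Iteratively, the
pair of columns with the highest absolute Pearson correlation above 0.8 is
standardized and replaced by dimension 1 of its principal component
decomposition (correlation scale, because the members have incommensurate
units; loadings unit-norm; sign fixed so the first-named member loads
positively; label `"A/B Dim 1"`). The loop recomputes correlations
including new composites and terminates because every merge removes a
column. Composites are treated as *atomic* terms downstream: a composite is
dropped whole during backward selection.

**Backward ΔAIC-6 selection with the nesting rule.** From the base model,
all single-term deletions are fitted; every fitted model enters a candidate
pool; the walk steps to the best deletion while it does not worsen AIC by
more than `stop_delta` (default 6, so the walk explores the whole region
that could still enter the top set). The top set is every pool model within
ΔAIC ≤ 6 of the pool minimum, then filtered by the nesting rule: a model is
removed if a strictly nested simpler candidate sits within 2 AIC of it.
Two consequences of this design are worth making explicit:

* The pool is the set of models *visited by the backward path*, not all
  subsets — backward selection is the stated procedure and keeps the cost
  at $O(p^2)$ fits. A brute-force enumeration oracle in the tests confirms
  that on fixtures where the backward path visits the optimum, the retained
  set equals the all-subsets answer.
* The rule as literally stated could eliminate the pool's AIC minimum
  (a nested simpler model within +2 of the best model also triggers it).
  The package follows the invariant that the minimum is never eliminated:
  the minimum is exempt. The brute-force oracle implements the identical
  guarded rule.

**Double penalty.** Each smooth's roughness penalty has a null space (for a
second-order difference penalty after the sum-to-zero constraint: the
linear trend). An extra, separately-smoothed penalty on that null space
lets the restricted marginal likelihood shrink a term *entirely* out of the
model. A term counts as selected out when its total EDF falls below 0.05.
A caution from the package's own verification: at cohort-scale sample sizes
the criterion (in this engine *and* in an independent reference engine,
which agree per-seed to about two decimals of EDF) regularly leaves
pure-noise terms with a few tenths of an EDF rather than shrinking them
below 0.05, so the double-penalty route is best read as strong shrinkage
with occasional survivors, not a hard variable eliminator. The tests assert
the verified shrinkage rates, not the idealized ones.

## 3. The fitting engine

Smooths are cubic B-splines with evenly spaced knots over the observed
covariate range (default basis size k = 10; 5×5 tensor product with one
penalty per margin for the spatial surface) and an order-2 difference
penalty — P-splines. A sum-to-zero constraint over the observed data is
absorbed into each block by a QR null-space reparameterization, so every
smooth is identifiable next to the intercept.

The inner loop is penalized IRLS with step-halving on the penalized
deviance; its trace is stored on the fit and asserted non-increasing (to
1e-8) by the tests. The outer loop chooses smoothing parameters by
(Laplace-approximate, for the binomial family) restricted marginal
likelihood. The optimizer is the generalized Fellner–Schall multiplicative
update rather than a per-parameter grid search: with up to eleven penalties
per model and hundreds of models per backward run, a grid-plus-refinement
scheme per penalty is far outside the compute budget, while the
Fellner–Schall update converges in a few dozen inner fits regardless of the
number of penalties. Each proposed update is *accepted only if it improves
the criterion*, with log-scale step-halving otherwise. Three numerical
details matter and were each the result of a real failure mode found during
development:

1. **Blockwise penalty determinants.** $\log|S_\lambda|_+$ and the
   pseudoinverse needed by the update are computed per term block. A global
   eigenvalue tolerance misclassifies a lightly penalized block as null
   space whenever another term's smoothing parameter is many orders of
   magnitude larger, silently removing the term's barrier against
   $\lambda \to 0$ and producing runaway wiggle.
2. **Structural rank.** Within a block, the *rank* of the combined penalty
   is computed from the unweighted structural sum of its penalties, then
   exactly that many eigenvalues of the weighted sum are kept. This matters
   for double-penalty blocks, which deliberately mix a huge null-space
   smoothing parameter with a small roughness one.
3. **Separation guard.** Steps whose fitted logits leave the numerically
   meaningful range (|η| ≥ 30) are rejected: creeping complete separation
   collapses the IRLS weights, degenerates the Laplace determinant and
   makes the criterion spuriously favorable. Converged fits with
   standardized coefficients above 15 and saturated logits raise an error
   naming separation. Forcing $\lambda = \infty$ is supported exactly, by
   restricting a term to its penalty null space — this is what makes the
   GLM/OLS oracle equivalences in the tests exact rather than asymptotic.

Prediction on new data clamps covariates outside the training range to the
boundary (constant extrapolation) with a warning; unknown factor levels are
an error. Partial effects are centered by construction (the absorbed
constraint), carry pointwise ±1.96·SE bands from the Bayesian coefficient
covariance $(X^TWX+S_\lambda)^{-1}\phi$, and are flagged significant when
no horizontal line fits inside the band. The concordance statistic is
computed by midranks (ties count one half) with a stratified bootstrap
(cases and non-cases resampled separately, default 2000 resamples, seeded)
for its interval. Adjusted $R^2$ is deviance-based:
$1 - \frac{D_{res}/(n-\mathrm{EDF})}{D_{null}/(n-1)}$.

## 4. Imputation

Hourly records are averaged to daily values using all valid hours — a day
is missing only if it has *no* valid hour; no minimum-coverage threshold is
imposed because the upstream convention is simply "24-hour averages". The
imputer models each variable as a smooth natural-spline time trend (default
12 df per year, at least 4 — enough for sub-seasonal drift without chasing
synoptic noise) plus jointly Gaussian same-day residuals across variables.
Because every variable shares one trend basis, the M-step for the trend
coefficients is exact ordinary least squares on the completed data (the
residual covariance cancels), and the covariance M-step includes the
conditional-covariance correction — so this is exact EM and the
observed-data log-likelihood is provably non-decreasing, which the tests
assert. Convergence is a maximum relative change of imputed values below
1e-4 (cap 100 iterations). Negative imputed pollutant values are clamped to
zero *after* convergence, outside the loop, preserving monotonicity while
honoring physical bounds; the documented validity bound of roughly 40%
missingness per variable triggers a warning, not an error.

Linear interpolation is kept as an explicit baseline (`linear_impute()`):
for isolated missing days in a strongly autocorrelated series it is a
genuinely strong competitor, and the EM imputer's advantage appears where
it should — inside multi-day gaps, where same-day information from the
other variables is the only signal available.

## 5. The synthetic world

The generator's defaults are a fixed "stated world", chosen once on realism
grounds and then left alone; tests and acceptance criteria are run against
it, not tuned to it. Each daily series is

mean + seasonal cosine + linear trend + interannual drift + shared-factor
noise + idiosyncratic AR(1) noise,

with: winter-peaking nitrogen oxides declining over the years
(the emission-control story), summer-peaking temperature and ozone, a
shared latent "stagnant air" factor loading positively on pollutants and
negatively on wind (the source of strong same-day cross-correlations), a
near-unit-root interannual component per variable, and ozone produced by a
structural equation — negative in NO (titration), negative in humidity,
positive in wind, negative in fine particulate matter (radical sink) — so
that long-window averages of those four variables genuinely carry
information about long-window ozone. Two structural facts earned their
place by breaking the pipeline when absent: without same-day
cross-correlation the EM imputer has nothing to condition on, and without
interannual drift all long-window averages are phase-shifted annual
sinusoids that collapse into a single composite, which real multi-year
records do not do.

Missingness is isolated days plus contiguous gaps (lengths uniform on
2..7 by default), per variable, with the gap share of the budget set at
40%. Cohorts draw recruitment dates over the last ~22 months of panel
coverage, age uniform on 1–30, sex Bernoulli(1/2), BMI and the two skin
measurements lognormal around cohort-plausible medians, a 3-group class
distribution of 0.30/0.25/0.45, and an investigator mix dominated by two
raters. The outcome is Bernoulli with logit
$\beta_0 + g(z) + \text{covariate terms}$, where $z$ is the standardized
true-window trailing average and $g$ is linear, saturating (tanh) or a
Gaussian bump with amplitude 1.5 on the logit scale by default — a strong
but epidemiologically plausible dominant driver (odds ratio ≈ 4.5 per SD).
The severity score is synthesized *consistently with the label* (gamma tail
above 10 for cases, scaled beta below 10 for non-cases), so dichotomization
in downstream code is exercised honestly.

What the generator does **not** emulate: atmospheric chemistry beyond the
linear ozone coupling (no photolysis kinetics), hourly-scale weather
structure (the hourly expansion is daily value + i.i.d. jitter, purely to
exercise ingestion), spatial structure beyond a lon/lat jitter field,
missing-not-at-random mechanisms, and any dependence of the skin-barrier
covariates on the outcome. A green end-to-end test therefore establishes
that the machinery recovers a known window/variable under realistic
correlation structure — not that any particular real-world estimate is
correct.

## 6. Tolerances, tie-breaks and degenerate inputs

* Inner IRLS: relative penalized-deviance change < 1e-8, cap 200.
* Outer REML: max |Δ log λ| < 1e-3, cap 50; per-step multiplicative clamp
  of 100; λ clamped to [1e-7, 1e9].
* Screening ties: shorter window wins. Report ordering: AIC, then fewer
  terms, then the formula string.
* Constant exposure columns (no distinct values) are a basis error, not a
  silent degenerate fit; constant columns are likewise an error in the
  collinearity reducer (their correlation is undefined).
* A cohort below 30 rows, an outcome with one observed class, a factor
  with one observed level, and recruitment dates without 365 days of panel
  history are all errors with named causes.
* Configuration files are JSON (not YAML): the JSON library is part of the
  package's minimal dependency set and the schema is flat enough that YAML
  adds nothing.

## 7. Known limitations

* The AIC is conditional on the selected smoothing parameters; no
  smoothing-uncertainty correction is applied. ΔAIC comparisons within one
  run are internally consistent, but absolute AIC values are not promised
  to match other engines bit-wise.
* The backward pool approximates the all-subsets pool; pathological AIC
  landscapes could hide a top-set member the walk never visits. The
  enumeration oracle in the tests bounds this on small fixtures only.
* The double-penalty EDF threshold of 0.05 is a definition, not a
  guarantee; see §2.
* The surrogate experiment's "no transformations, default settings" maps to
  this package's defaults (k = 10 P-splines, REML); it is an interpretation,
  not a numerical replication of any other engine.
* Bootstrap intervals for the C-index are percentile intervals; no
  acceleration/bias correction.
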