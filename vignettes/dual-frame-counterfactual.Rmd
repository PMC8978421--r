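---
title: "Methods: counterfactual comparison of dual-frame and cell-only RDD designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual comparison of dual-frame and cell-only RDD designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimation strategy

Dual-frame (DF) random-digit-dialing surveys draw independent samples of
landline and cell numbers.  As landline coverage erodes, the natural policy
question is whether the landline frame can be dropped.  `rddframes`
implements the counterfactual approach used in national practice: the
single-frame (SF) cell design is constructed *from the DF sample itself*, by
discarding the landline respondents and reweighting the remaining cell
respondents with the SF selection probability.  The two designs are then
compared on weight dispersion, representativeness and prevalence estimates.
Because the SF sample is a subsample of the DF sample, the comparison is
conservative (the samples are dependent); it isolates the design question
from period effects that would contaminate a comparison of two separate
surveys.

## Selection probabilities and weights

An eligible person can be reached through each cell number they own
(one-stage) and through each landline number of their household followed by
a Kish draw among the `e_LL` eligible members (two-stage).  Summing the
per-route expected selection rates gives the overlapping dual-frame
probability

$$\pi_i^{df} = \frac{n_{LL}}{N_{LL}}\frac{t_{LL}^i}{e_{LL}^i}
             + \frac{n_{C}}{N_{C}}\frac{t_{C}^i}{e_{C}^i}, \qquad e_C^i = 1,$$

and dropping the landline term gives $\pi_i^{sf}$.  This additive form is
the expected number of interviews of person $i$ under number-level sampling,
so inverse-probability totals are design-unbiased for the phone-covered
population (the test suite verifies this by simulation with full response).
Consequences adopted here:

* the fieldwork simulator keeps every completed interview, including the
  rare event of one person being interviewed through two different dialed
  numbers — deduplicating would make the additive formula an approximation;
* probabilities are computed from *reported* multiplicities (identical to
  the true ones unless the generator's misreport switch is on), with a cap
  (default 3 numbers per frame) as a guard against extreme weights;
* a probability above 1 raises an error rather than being clamped: it
  signals mis-specified frame counts, not a legitimate design;
* no weight trimming is applied anywhere — dispersion comparisons are about
  the raw designs.

The coefficient of variation of weights uses the population SD (divisor
$n$); the convention is fixed and documented because max/min and CV are
reported comparatively, where the convention cancels.

## Raking calibration

Design weights are calibrated to reference margins by the raking ratio
(iterative proportional fitting on the weights): cycle over the margin
variables, multiplying each unit's weight by target/current category totals.
Choices:

* margins are shares scaled to the reference population total, so converged
  weights sum to the population size (which makes deft and total-estimation
  checks meaningful);
* stopping rule: maximum relative margin deviation below `1e-8`, or 100
  cycles — far below any reporting precision;
* sex and age are raked as one cross-classified sex × age margin (12 cells)
  by default; the marginal reading is available via `margin_spec =
  "marginal"`.  The joint reading is the stricter and the more common
  interpretation of "gender by age" in calibration practice;
* plain raking only — no bounds on adjustment factors (logit raking) and no
  explicit nonresponse-propensity step, matching the procedure under study;
* structural zeros (a target category with no sample unit) abort with the
  category named, since raking cannot repair them.

The raking fixed point is checked in the tests against an independent
brute-force IPF oracle on contingency tables, and order-invariance of the
converged weights is asserted.

## Representativeness diagnostics

The standardized distance per category is
$d = 100 (p_B - p_A) / \sqrt{(p_A q_A + p_B q_B)/2}$, aggregated as an
unweighted mean of $|d|$ over a variable's categories ($D$) and an unweighted
mean of $D$ over variables (mean D) — no category-size weighting at either
level, which is exactly how the published worked-example aggregates
reconstruct.  Distances on calibration covariates are computed with design
weights (calibration would zero them by construction); distances on external
covariates use calibrated weights.  Rounding is half-away-from-zero and is
a presentation concern only; `rounded_aggregation = TRUE` reproduces printed
aggregates from values at display precision.

The R-indicator uses the two-sample formulation: stack the sample on a
census-like benchmark, fit a main-effects logistic model for membership, and
convert the predicted membership probability $m(x)$ to the selection
propensity scale as the odds $m/(1-m)$.  With the benchmark weighted to
population counts and each interview counted once, these odds estimate the
sampling rate at $x$; they are capped at 1 (a person cannot be sampled more
than once), which also guarantees $R = 1 - 2\,S(\hat\rho) \in [0,1]$.  On a
saturated two-stratum design the procedure reduces to the closed-form SD of
the two known sampling rates, which is the anchor used in the tests.  Sample
design weights, when supplied, are normalized to the sample size so the
indicator is invariant to their scale.  Partial (variable-level)
R-indicators and standard errors are out of scope.

## Estimation

Prevalences are Hájek ratio means.  The variance is Taylor linearization
under a single-stage with-replacement approximation with calibrated weights
treated as fixed:
$\widehat{var} = \frac{n}{n-1}\sum_i w_i^2 (y_i - \bar y)^2 / (\sum_i w_i)^2.$
Whether SEs should account for calibration (residual-based linearization) is
deliberately left out: the fixed-weight form is the standard conservative
default, and a bootstrap oracle in the tests bounds the discrepancy on a
fixed sample.  `deft` divides by the binomial SRS variance $p(1-p)/n$
(no finite-population correction, consistent with the with-replacement
approximation).  Subgroup estimates (ages 18–30 and 60–75) reuse the
full-sample calibrated weights without re-calibration.  AAPOR response rate
3 uses the proportional (CASRO) eligibility factor
$e = \text{known eligible}/(\text{known eligible} + \text{known ineligible})$
per frame, the conventional choice.  Degenerate subgroup estimates (0 or 1)
leave deft and the relative difference as `NA` in reports, while the bare
`deft()` and `relative_difference()` functions treat them as errors.

## What the synthetic generator emulates — and what it does not

Defaults are anchored to the French adult (18–75) population as seen by a
national telephone health survey:

* **Category shares** follow published labor-force margins (sex 48.7/51.3;
  six age bands; six education levels; household sizes 1–5+; six
  urbanization classes; twelve regions).  Printed shares carry rounding
  residue, so the constructor normalizes each vector to sum to 1.
* **Equipment**: cell ownership ~96% overall, decreasing with age (99% in
  the youngest band to ~87% in 65–75) and increasing with education
  (log-odds shifts from −0.9 for primary education to +0.8 for university);
  landline ownership is a *household* attribute, ~77% person-level coverage,
  increasing with the age of the oldest member.  `implied_equipment_rates()`
  gives the exact model-implied marginal for validation.
* **Frames**: every owned number plus non-working numbers to reach 50%
  (landline) and 33% (cell) non-working rates, the rates observed in French
  RDD practice; frame size is `round(working/(1 − rate))`.
* **Multiplicity**: 1 number with probability 0.9, 2 with 0.09, 3 with 0.01
  per equipped frame.  No published multiplicity distribution exists; the
  weight formulas only need $t \ge 1$ variation to be exercised.
* **Households** are formed within household-size category after an
  age-sorted-with-noise ordering — a deliberately simple pairing that still
  yields couple-like intra-household age correlation so that $e_{LL}$ varies
  realistically.  The generated population is restricted to the eligible
  ages 18–75, so $e_{LL}$ equals household size.
* **Health indicators** (the seven used in national reporting: poor
  self-reported health, chronic disease, activity limitation, obesity,
  physical inactivity, daily smoking, lifetime suicide attempt) follow
  logistic models in age and education with baselines near published
  prevalences, plus a residual effect of phone-equipment class for daily
  smoking and suicide attempt (cell-only higher): differences between cell
  and landline users are documented not to be fully explained by
  demographics, and this residual effect is what makes the SF design's
  coverage bias non-removable by calibration.
* **Fieldwork**: per-attempt contact probabilities by age band and frame
  (truncated-geometric contact process, default cap 20 attempts),
  cooperation ~0.45–0.50, a small partial-interview probability (partials
  exercise the P term of RR3 and are excluded from respondents), and a
  fraction (0.35) of never-answered numbers coded unknown-eligibility.  The
  landline answerer is drawn uniformly among household members and the Kish
  selectee independently among eligibles, so a configurable recontact stage
  (default success 0.9) is needed when they differ — reproducing the
  practical pattern that a sizeable share of landline interviews is not with
  the person who picked up.  The 40/60 landline/cell allocation of dialed
  numbers is the conventional stratification.

Not emulated: calendar/time-slot call scheduling, interviewer effects,
geography beyond categorical labels, smartphone/SMS modalities, measurement
differences between modes, and the real joint dependence of education with
age.  Passing tests therefore show that the *pipeline* is correct under a
plausible population model — not that any particular real survey is
unbiased.  The call-process model is a stand-in producing realistic
observable outcomes (dispositions, attempts per complete), not a
reconstruction of any fielded protocol.

## Problem sizes and determinism

The reference scenario (`study_config()`) uses 150,000 persons and 45,000
dialed numbers, giving roughly 11,000 DF completes — a scale at which the
deft and CV comparisons between designs are resolved well beyond their
Monte-Carlo noise while a full run stays in the tens of seconds.  Unit and
property tests use populations of 1,500–8,000 and a 100,000-person
generation for share-convergence checks; design-unbiasedness is verified
over 200 fieldwork replicates on a fixed 3,000-person population.  A master
seed drives per-stage streams (population, fieldwork, replicates) derived
with distinct offsets, so a stage can be re-run without perturbing the
others and identical configurations are byte-identical end to end.

## Known limitations

* The SF sample being nested in the DF sample, differences between designs
  cannot be tested inferentially; the package reports magnitudes only.
* Variance estimation ignores calibration and the without-replacement
  correction; both make the reported SEs slightly conservative.
* The R-indicator's propensity scale depends on the benchmark being a
  (near-)census; with a small benchmark the odds conversion is noisy.
* Raking is unbounded; badly under-covered categories can produce large
  adjustment factors (visible in the max/min ratio, by design untrimmed).
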