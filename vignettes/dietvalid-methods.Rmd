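---
title: "Measurement-error methods behind dietvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-error methods behind dietvalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietvalid)
```

`dietvalid` quantifies how well short-term dietary self-report instruments
(two 24-h recalls: an online self-administered tool, "A", and an
interviewer-administered multiple-pass recall, "B") measure usual intake,
using objective reference measures: recovery biomarkers for protein,
potassium and sodium, a predictive biomarker for total sugars, and measured
total energy expenditure as the reference for energy intake. This vignette
documents the model, the derivations, the numerical choices and the design
decisions, and what the synthetic-data generator does and does not emulate.

## The measurement-error model

All analyses are on the natural-log scale (intakes are positive and
right-skewed; the natural log pairs with the `exp` back-transform used for
percentage differences). For participant $i$, occasion $j$:

$$M_{ij} = T_i + u_{ij}, \qquad
  Q_{ijm} = \beta_{0m} + \beta_{1m} T_i + r_{im} + \varepsilon_{ijm},$$

where $T_i \sim N(\mu_T, \sigma^2_T)$ is true usual log intake, $M$ the
reference (biomarker-derived intake, or TEE for energy), $u$ its
within-person error, and for each tool $m$: $\beta_{0m}$ a constant bias,
$\beta_{1m}$ an intake-related bias slope (flattened reporting when
$\beta_1 < 1$), $r_{im}$ a person-specific bias stable across repeats, and
$\varepsilon$ independent within-person error. The two tools' person
biases $(r_{iA}, r_{iB})$ are bivariate normal with covariance
$\sigma_{rAB}$ — people who over-report on one recall tend to over-report
on the other.

**Identifiability.** Without an anchor the scale of $T$ is arbitrary. The
reference is modelled as unbiased (intercept 0, slope 1) — the recovery
biomarker convention. The TEE reference and the sugars predictive biomarker
are given the same unbiased-reference structure; their (possibly different)
error behaviour is absorbed into $\sigma^2_u$, which is free per nutrient.

**Functionals.** For the mean of $k$ administrations of tool $m$,

$$\lambda_m(k) = \frac{\beta_{1m}\sigma^2_T}
  {\beta_{1m}^2\sigma^2_T + \sigma^2_{rm} + \sigma^2_{\varepsilon m}/k},
  \qquad
  \rho_m(k) = \frac{\beta_{1m}\sigma_T}
  {\sqrt{\beta_{1m}^2\sigma^2_T + \sigma^2_{rm} + \sigma^2_{\varepsilon m}/k}}.$$

$\lambda$ is the regression-calibration slope: the factor by which a log
relative risk estimated with the tool is attenuated. $\rho$ is the
model-implied correlation between a single administration (or a $k$-mean)
and $T$; it is reported as the correlation with true intake. $\lambda(k)$
is strictly increasing in $k$ when $\sigma^2_\varepsilon > 0$ and converges
to $\beta_1\sigma^2_T/(\beta_1^2\sigma^2_T + \sigma^2_r)$: repeat
administrations remove within-person error but not person-specific bias.

**Fitting.** Each participant's observed sub-vector of log values (up to 3
reference, 3 tool-A, 3 tool-B) is multivariate normal with structured mean
and covariance; the likelihood marginalizes missing entries, which is valid
under missing at random and uses no imputation. Optimization is BFGS with
analytic gradients over an unconstrained parameterization: variances as
$\texttt{floor} + e^\ell$ and the person-bias correlation as $\tanh z$, so
every iterate implies an admissible covariance. The floor ($10^{-10}$)
keeps the likelihood bounded on degenerate (noise-free) data, where
variance components would otherwise run to zero and the covariance to
singularity; its effect on any reported quantity is below $10^{-6}$.

Starting values are the model-implied method-of-moments estimates:
per-instrument means, the scatter about those means, and averages over the
exchangeable occasion orbits. On complete balanced data this estimator *is*
the maximum-likelihood estimate (the invariant covariance pattern is closed
under multiplication, so the ML solution is the orbit-averaged scatter),
which both gives the optimizer an exact start there and provides a strong
internal consistency check, exercised in the tests at $n = 2000$.

**Intervals.** The default 95% CI for $\lambda$ and $\rho$ is the delta
method on the unconstrained scale, using the inverse observed information
and a finite-difference gradient of the functional; a
participant-resampling percentile bootstrap (seedable, default 1000
replicates) is available, and is the automatic fallback if the information
matrix is singular. Calibration of the delta interval is checked by
simulation in the test suite (500 studies of 200 participants).

**Mean % difference.** Per participant, the mean of log tool values minus
the mean of log reference values; the average $\bar d$ is reported as
$(e^{\bar d} - 1)\times 100$ with a back-transformed t-interval. This is
the Bland–Altman mean difference computed on replicate means.

**Densities.** Nutrient densities (g/MJ) are formed first — self-report
nutrient over self-report energy; biomarker nutrient over TEE — and the
identical model is then fit to the density values.

## Biomarker derivation

Constants live in `derivation_constants()` and are overridable:

| quantity | default | meaning |
|---|---|---|
| PABA excretion | 0.93 | fraction of dose in complete 24-h urine |
| nitrogen excretion | 0.81 | fraction of dietary N in 24-h urine |
| potassium / sodium excretion | 0.80 / 0.86 | recovery fractions |
| N → protein ratio | 6.25 | g protein per g N; per-record overrides via a `nitrogen_ratio` column |
| thermic effect of food | 0.10 | fraction of TEE |
| Weir coefficients | 3.941, 1.106 | kcal/L of VO2, VCO2 per minute |
| kcal → MJ | 0.004184 | |

PABA recovery classifies collections: 85–110% complete, 50 to <85%
adjustable, otherwise excluded (boundaries inclusive at 50, 85 and 110).
The adjustment multiplies urinary N/K/Na by $93/\text{recovery}$ — the
reading of "adjusting to 93% recovery" as a proportional rescaling of the
measured amount; the identity holds exactly at recovery 93. Resting energy
expenditure uses the mean of the last 10 of 15 one-minute VO2/VCO2
readings (the first minutes are the settling period), and
$\mathrm{TEE} = (\mathrm{REE} + \mathrm{AEE}) / (1 - 0.10)$.

The total-sugars calibration is log-linear in urinary sucrose + fructose
with age and sex terms. Its published coefficients are not reproduced here;
the defaults (`a = 2.5, b = 0.48, c = 0.008/year, d = -0.12` for female)
are synthetic placeholders of realistic magnitude and must be replaced for
real analyses. Plasma antioxidants (β-carotene, vitamins C and E) are never
converted to intakes — concentration biomarkers support ranking (ICC) only.

**Exclusion conventions.** "Two or more missed voids" is $\ge 2$; ">5%
weight change" is strict and compares each visit weight to the first
appointment; wear-time bounds are strict (<23 h, >25 h); the
recall-proximity rule uses a calendar-date difference of at most one day.
Main-mode rules (voids, weight) always apply; sensitivity modes add their
rule on top.

## Agreement statistics

The two-way mixed-effects model for occasion-level values of two methods is

$$y_{imj} = \mu + \tau_m + b_i + c_{im} + e_{imj},$$

with fixed method effects $\tau$ (sum-to-zero), subject effects $b$, a
subject-by-method interaction $c$ and residuals $e$; by default the
interaction and residual variances are method-specific. This is the same
structured-normal likelihood machinery as the measurement-error model (with
all slopes fixed at 1); the homogeneous special case is verified against
`lme4` in the tests. The absolute-agreement ICC with fixed raters is

$$\mathrm{ICC} = \frac{\sigma^2_b}
 {\sigma^2_b + \overline{\sigma^2_c} + \overline{\sigma^2_e}
  + \sum_m \tau_m^2 / (M-1)},$$

with heterogeneous variances combined by arithmetic mean and the $\tau$
term penalizing systematic offsets. Its CI is a subject-resampling
percentile bootstrap. For pairs in different units (plasma concentration
vs estimated intake) the log values are z-standardized within method before
the fit — absolute agreement across incommensurable units is otherwise
undefined; this is an interpretation, flagged in the function
documentation, and % differences are suppressed for standardized fits.

Bland–Altman summaries use $d = \log x - \log y$: bias
$(e^{\bar d}-1)\times100$ (the ratio of geometric means as a percentage)
and limits $(e^{\bar d \pm 1.96 s_d}-1)\times100$ with $s_d$ the sample
standard deviation and the conventional 1.96 multiplier (not a t
quantile).

## What the generator emulates — and what it does not

`simulation_config()` encodes the emulated design: 200 participants, 3
occasions about 14 ± 2 days apart, recalls 1–3 days (first tool, order
randomized) and a further 2–4 days (second tool) after each biomarker
collection, 10% of records missing at random per instrument, ~60% female,
ages 18–65, weights by sex (means 81/67 kg, SD 13), small multiplicative
per-visit weight drift, PABA recovery N(96, 6²) (mostly complete, a few
percent adjustable), per-void miss probability 0.08 (so that roughly 2% of
collections lose two or more voids), armband wear N(23.8, 0.6²) h.

Per-nutrient truth is specified as a *validity profile* — the
single-administration $(\lambda, \rho)$ and mean % difference of each tool,
from which `tool_params_from_validity()` solves
$\beta_1 = \rho^2/\lambda$, $\mathrm{var}(Q) = (\rho/\lambda)^2\sigma^2_T$,
with the residual variance split 30/70 between person bias and
within-person error. The default profiles make the online tool's protein
attenuation 0.30 (the primary, protein-like scenario; 0.38 for the
interviewer tool), with potassium-, sodium-, sugars- and energy-like
profiles alongside, and a person-bias correlation of 0.5 between tools.
The between-person variances of log intake (0.03–0.10) and the reference
within-person variances (0.02–0.20) are realistic placeholder magnitudes,
not estimates from any study. Raw signals are constructed by inverting the
derivations (urinary N = protein × 0.81/6.25, calorimetry series whose
last-10-minute Weir mean is exact, and so on), with multiplicative noise
attached where it cannot leak into the derived value — so the
generate-then-derive round trip is exact (relative error below $10^{-9}$)
for complete collections, and collections with recovery < 85% lose analyte
proportionally, which the PABA adjustment inverts exactly.

Deliberately *not* emulated: food- or meal-level structure; correlation of
true intakes across nutrients; day-of-week and seasonal effects;
informative (non-MAR) missingness such as under-reporters skipping
collections; laboratory assay error as a separate component; any
association between plasma antioxidant concentrations and the simulated
nutrients. Passing tests therefore demonstrate that the estimators recover
the assumed structure at the study's scale — not that real data satisfy
that structure.

## Numerical choices and degenerate inputs

* Natural log everywhere; values $\le 0$ are an input error listing the
  offending records, never silently dropped.
* Variance floor $10^{-10}$; optimization tolerance `reltol = 1e-12`,
  `maxit = 500`; non-convergence is flagged on the returned fit (and is a
  distinct exit code in the CLI), never silently replaced.
* Method-of-moments starts; sample moments are clamped into the admissible
  region (variances at the floor, |person-bias correlation| ≤ 0.99) before
  transformation.
* Likelihood evaluation groups participants by missingness pattern and
  works from per-pattern sufficient statistics (count, column sums,
  scatter), so cost per iteration is independent of $n$ given the pattern
  set; gradients are analytic, validated against finite differences in the
  tests.
* Ties at exclusion boundaries follow the stated inclusive/strict
  conventions; `classify_paba(85)` is complete, a 5.0% weight change is
  retained, a 6.25% change excluded.
* Test and simulation sizes were chosen to make Monte-Carlo checks sharp
  but cheap: moment checks at $n$ = 20,000–50,000 draws, estimator
  equivalence at $n$ = 2000 participants, parameter recovery over 100 and
  interval coverage over 500 replicate studies of 200 participants.

## Known limitations

* The model is univariate per nutrient; no joint multi-nutrient fit and no
  regression calibration of external cohort data.
* Stratified analyses are independent re-fits per stratum (as in the
  emulated design), not a shared-parameter joint model, so strata cannot
  borrow strength.
* The delta CI can be anti-conservative in small strata; the bootstrap is
  the safer choice there.
* The sugars calibration coefficients and food-specific nitrogen ratios
  are configuration inputs, with placeholder defaults.
* The ICC between quantities in different units depends on the
  z-standardization convention documented above.
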