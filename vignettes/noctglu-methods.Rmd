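---
title: "Nocturnal hypoglycemia and sleep quality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nocturnal hypoglycemia and sleep quality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctglu)
```

## The scientific problem

People with type 1 diabetes frequently experience nocturnal hypoglycemia
(NH): sensor glucose below 3.9 mmol/L (Level 1) or below 3.0 mmol/L
(Level 2) during the night. Most such episodes are asymptomatic, and it
is an open question how the *characteristics* of NH — whether it
occurred at all, how many episodes, how long, how deep — relate to how
well the person feels they slept. This package implements a complete,
testable analysis pipeline for that question using blinded CGM traces at
a 15-minute cadence, a daily 5-point sleep-quality score (1 = very
poorly, 5 = very well), a participant table (age, sex, Gold and DAFNE
hypoglycemia-awareness scores, treatment type), and capillary meter
downloads for sensor-accuracy assessment.

Because patient-level CGM data of this kind are generally not shareable,
the package ships a synthetic cohort generator with known ground truth;
every stage of the pipeline is validated against that truth or against
independent oracles.

## Night definitions and per-night metrics

* **Nocturnal window.** The half-open interval [00:00, 06:00) of the
  night's date. At the 15-minute cadence this contains exactly the 24
  expected readings (00:00 through 05:45); a reading stamped 06:00
  belongs to the day. The sleep score reported on morning *D* is paired
  with the window of date *D* — "how well did you sleep last night"
  refers to the night ending that morning.
* **Night QC.** Nights with fewer than 20 in-window readings are
  excluded. Denominators for all per-night metrics are *observed*
  readings, not the expected 24.
* **Hypoglycemia and episodes.** Strictly below threshold (a reading of
  exactly 3.9 mmol/L is in range). Each reading represents the 15-minute
  interval starting at its timestamp, so one below-threshold reading
  already meets the "at least 15 min" episode definition and a run of
  *k* consecutive below-threshold readings is one episode of 15*k*
  minutes. Runs are never merged across an in-range reading, and a data
  gap (successive readings more than 15 min apart) breaks a run —
  unobserved time never counts as hypoglycemia. An episode truncated by
  the 06:00 boundary still counts if at least one in-window reading is
  below threshold.
* **AUC.** Sum over below-threshold readings of
  (threshold − glucose) × 15 min, in mmol/L·min; it mixes depth and
  duration in one number.
* **Mean, %CV, TIR.** Arithmetic mean; 100 × sample SD / mean; percent
  of readings inside 3.9–10.0 mmol/L, both ends inclusive. With these
  conventions %time < 3.9, TIR and %time > 10 partition every night
  exactly.
* **Night classes.** `level2` if any reading < 3.0, else `level1_only`
  if any reading < 3.9, else `none`. Nightly NH<3.9 duration is binned
  for reporting as Q0 (0 min), QI (1–45), QII (46–90), QIII (91–150),
  QIV (> 150).

The episode scan is validated against an exhaustive O(n²) run
enumeration on 1,000 random nights, and the AUC against a literal
re-summation of its formula.

## The inferential model

Sleep score is an ordinal 5-level outcome with strong within-person
correlation across nights, so the pipeline fits a random-intercept
proportional-odds model: for participant *i*, night *t*,

$$P(Y_{it} \le k \mid x_{it}, u_i) = \operatorname{logistic}(\kappa_k - x_{it}'\beta - u_i), \qquad u_i \sim N(0, \sigma_u^2),$$

with strictly increasing cut-points $\kappa_1 < \dots < \kappa_{K-1}$.
Under this sign convention $e^{\beta} < 1$ means lower odds of a
*higher* (better) sleep score. Each model carries exactly one glycemic
exposure (presence, episode count, duration, AUC at either threshold,
or nocturnal mean glucose, %CV, TIR) plus age (years, uncentered) and
sex (female = 1); exposures are refitted one per model rather than
jointly, mirroring the one-row-per-exposure reporting convention, and
duration is reported per 15 minutes. Exposure odds ratios are invariant
to covariate centering, so none is applied.

### Estimation

The marginal likelihood integrates $u_i$ out per participant:

$$\ell = \sum_i \log \int \prod_t P(y_{it} \mid x_{it}, u)\, \varphi(u; 0, \sigma_u^2)\, du .$$

The integral is evaluated by *adaptive* Gauss–Hermite quadrature: each
group's integrand mode is found by damped Newton iteration (the ordinal
log-likelihood is concave in $u$, so the mode is unique), the
quadrature is centred and scaled there, and 15 nodes are used by
default (1 node gives the Laplace approximation; the node count is a
user argument, and doubling it changes the log-likelihood by less than
1e-6 relative on all test fixtures). Optimization runs on an
unconstrained parameterization — $\beta$, $\kappa_1$, log-differences of
successive cut-points (which enforces ordering), and $\log \sigma_u$
clamped to $[-10, 3]$ — with `nlminb` at a relative tolerance of 1e-10.
Standard errors come from the inverse of a numerically differentiated
observed-information matrix on the natural scale; a fit is reported as
converged only when the optimizer converged, the information matrix is
positive definite, and the post-hoc gradient norm is small. Confidence
intervals are Wald at ±1.96 SE.

Two independent oracles check the machinery: a dense-trapezoid
integration of the same marginal likelihood written in plain R (no code
shared with the quadrature path), which agrees to better than 1e-6
relative, and `MASS::polr` for the $\sigma_u = 0$ collapse, where
coefficients agree to 1e-3 and intercept-only cut-points reproduce the
empirical cumulative logits to 1e-4. No installed package fits the full
mixed ordinal model, so the likelihood oracle carries the mixed case.

## The synthetic cohort generator

The generator's defaults *are* the study conditions the pipeline
targets: 27 participants × 28 nights, 15-min cadence, roughly 24% of
nights with NH < 3.9 mmol/L, and 518 capillary pairs.

* **Glucose.** Participant baselines are drawn N(7.5, 1.2²) mmol/L
  (clipped to [4.5, 12]); within a night the path is baseline + a
  stationary AR(1) (ρ = 0.85 per 15-min step, innovation SD
  0.45 mmol/L), clipped to the sensor span [1.1, 27.8] and rounded to
  0.01 mmol/L.
* **Hypoglycemia excursions.** A night receives an injected excursion
  with probability 0.239. The excursion replaces its core readings with
  a smooth half-cosine dip running from just under the 3.9 threshold
  (at most 3.8 mmol/L at the edges) down to a drawn nadir
  (uniform 2.2–3.6 mmol/L); the core length is gamma-distributed
  (shape 2.1, scale 4 steps, i.e. mean ≈ 126 min, SD ≈ 87 min,
  matching the observed duration distribution), and 8% of excursion
  nights carry a second, disjoint dip (the study pattern: at most two
  episodes per night). Nights *not* selected are floored at
  4.0 mmol/L, so NH presence is exactly Bernoulli(0.239) and the
  generator's truth is unambiguous. This floor is the one deliberate
  departure from realism: real nights can graze the threshold, but an
  exact presence indicator is what makes parameter-recovery targets
  interpretable.
* **Sleep scores.** Drawn from the same proportional-odds model the
  analysis fits, with covariates computed by the *analysis* metric code
  (the generator calls the night-summary internals, so simulation truth
  and analysis definitions cannot drift). Default coefficients: NH
  presence log(0.49); age −0.02 per year and female −0.2 (plausible
  magnitudes; the source analyses adjust for age and sex without
  reporting their effects); episode-count, duration and AUC generative
  coefficients default to 0 because those quantities are deterministic
  functions of the same injected excursions — turning all of them on at
  once would confound every single-exposure fit. Recovery simulations
  activate exactly one coefficient at a time. Cut-points default to
  (−4.3, −2.8, −1.0, 1.0) and $\sigma_u$ to 0.8, chosen once so that
  no-NH nights average a score near 3.5 (SD ≈ 1.0) and NH nights near
  3.2 under the default effects; the within-person intraclass
  correlation on the latent scale is ≈ 0.16.
* **Capillary pairs.** Sensor readings are sampled and perturbed
  multiplicatively: capillary = sensor / (1 + e),
  e ~ N(0, s) with s = (MARD/100)·√(π/2), so the expected mean absolute
  relative difference |capillary − sensor|/capillary = E|e| equals the
  configured target (13.6% by default). Draws outside the physiologic
  span are redrawn; meter timestamps are offset up to 3 min either way.
* **Determinism.** One global integer seed; participants, random
  intercepts, traces, scores and capillary errors each use a named
  substream derived from it, so a seed fixes the cohort bit-exactly.

What passing tests on this generator do *not* show: realism of daytime
glucose (only the nocturnal window is generated), meal/insulin
dynamics, diary non-response, device clock drift, or weekday/alcohol/
exercise structure in sleep scores. Those are out of scope by design.

## Descriptive layer

Stratified comparisons of level-1-only vs level-2 nights summarise each
metric as mean (SD) and median (IQR) and test continuous metrics with an
independent-samples t test when a Shapiro–Wilk check (α = 0.05 in each
stratum) supports normality in both strata, otherwise Kruskal–Wallis;
proportions (episode counts) use chi-squared. The normality gate is a
documented stand-in — the convention "t or Kruskal–Wallis based on
normality" leaves the check unspecified — and the test actually used is
always recorded in the output. Gold-score associations with NH
parameters use Spearman's rank correlation across nights. No
multiple-testing adjustment is applied, matching the source convention
(two-sided α = 0.05).

## Smoothing and inflections

The sleep-score-versus-mean-glucose relationship is explored with a
single-pass locally weighted running-line smoother: at each distinct
observed x, a degree-1 weighted least-squares line over the nearest
`ceiling(frac·n)` points with tricube weights, evaluated at x. The
default span `frac = 0.8` is a package choice (no bandwidth is
prescribed by the source); there are no robustness iterations. The
smoother is exact on linear data, equals a pointwise global
tricube-weighted regression at `frac = 1`, and tracks
`stats::lowess(iter = 0)` closely (the two differ only in
neighbour-count rounding). Inflections are grid points where the sign
of successive fitted slopes flips; sign changes whose adjacent slopes
are below a noise floor (default 1e-3 score units per mmol/L) are
suppressed. On near-flat stretches — which genuinely occur when the
score–glucose relationship plateaus — slopes hover around zero and
several low-magnitude inflections can be reported; the floor is
configurable when a sparser summary is wanted. Smoothing is fitted on
night-level points, not participant aggregates.

## Sensor accuracy

Capillary readings are matched to the nearest-in-time sensor reading
(ties of availability notwithstanding, a sensor reading may serve
several capillary readings); pairs further than 3 min apart are
discarded. MARD is mean |capillary − sensor| / capillary × 100 —
asymmetric by construction, with the capillary reference in the
denominator. Error grids are evaluated in mg/dL (conversion factor
18.016, stated once so the grids are bit-reproducible): Clarke zones
follow the canonical published rule set in its canonical order (zone A
checked first with inclusive bounds, then E, C, D, residual B — which
also fixes boundary ties deterministically), and Parkes type-1 zones
are point-in-region tests against the published consensus boundary
vertex tables, extended past the last vertex with the final segment's
slope; Parkes edge ties go to the more favorable zone. Both grids
assign exactly one zone to every point of a 200 × 200 lattice over
(0, 30] mmol/L squared in the test suite.

## Problem sizes and numerical choices

Parameter-recovery acceptance runs use 200 replicate cohorts of
27 × 28 nights per exposure with 15-node quadrature — the scale at
which the mean recovered odds ratio is a stable estimate of the
generative value while a full run stays in the minutes range on one
CPU. The null-calibration check (all generative effects zero) uses the
same scale and verifies 95% Wald coverage between 0.90 and 0.99.
Degenerate inputs fail loudly: QC-failed nights refuse metric
computation, zero-variance exposures refuse fitting (the pipeline notes
and skips them, e.g. in a cohort with no NH nights), constant inputs
make Spearman's rho `NA` with a note, and empty pair sets refuse MARD.

## Known limitations

Single-site, naive-local-time semantics (no daylight-saving
arithmetic); no random slopes or non-proportional odds; Wald rather
than profile intervals; published clinical analyses of this kind rarely
state their quadrature or optimizer settings, so third-decimal
agreement with printed odds ratios is not a goal — recovery of
generative truth is.
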