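---
title: "Methods: cross-species age translation with transtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species age translation with transtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transtime)
```

## The problem

Comparative work on primate development and aging needs a way to say
"a chimpanzee at age *x* corresponds to a human at age *y*".  transtime
implements an event-scale approach: developmental and aging events
(reflex onsets, growth milestones, menarche, transcriptional states,
structural aging markers) observed in several species are placed on a
common 0–1 ordering, and each species' chronological ages are regressed
on that ordering.  Inverting one species' curve and evaluating
another's translates ages between them.

All ages are handled in **days post conception**, so prenatal and
postnatal events share one axis; postnatal ages add the species'
gestation length (shipped defaults, user-overridable), and in-vitro
(organoid) incubation days enter through a configurable offset
(default 0, i.e. incubation days are used directly, since there is no
agreed placement of incubation onset on the conception axis).  Natural
logs are used throughout; translation results are invariant to the log
base.

## The event scale and imputation

Let \(a_{es}\) be the mean log age of event \(e\) in species \(s\)
(the unweighted mean of log ages when several time points contribute —
averaging logs rather than raw days is a package choice; either
convention yields a monotone, nearly identical ordering).  Events are
rarely observed in every species, so missing cells are filled first by
an iterative scheme that mirrors the model's own structure:

1. initialise event means from observed cells;
2. regress each species' observed log ages on the current event means
   (one affine fit per species);
3. fill that species' missing cells with its fitted prediction;
4. recompute means and repeat until the largest change in any filled
   cell drops below `tol` (default 1e-6, `max_iter` 100).

Observed cells are never altered, complete tables pass through
unchanged, and on tables where each species is an exact affine
function of the event means (the no-noise, no-curvature case) the
fixed point reproduces the missing cells exactly.  No uncertainty is
propagated from imputation — single imputation matches the downstream
fixed-effects treatment.

The event scale is then the min–max normalisation of the
cross-species mean log age: the earliest event scores 0, the latest 1.
It is invariant to any common affine transform of the log ages.

## The translating-time model

The core regression, fitted by ordinary least squares with treatment
coding (human as the reference species, since alignments are
conventionally read against humans):

\[
\log(\text{age}) = \beta_0 + \beta_1 E + \beta_2 E^2
 + \text{species} + \text{event type}
 + E \times \text{species} \times \text{event type} + \varepsilon ,
\]

with all two-way terms implied by the full factorial expansion of the
three-way interaction, and the quadratic term shared across species
(the formula attaches no species interaction to it).  Event types come
from a closed vocabulary (body growth, brain growth, life history,
structural aging, facial structure, locomotor forelimb, transcription,
behavior, other); their interactions are what makes **heterochrony** —
shifts in the relative timing of specific processes — testable as a
nested-model F test against the fit without event-type terms.

One structural property is worth knowing: because the event scale is
built by min–max normalising the cross-species *mean* curve, that mean
curve is affine in the scale by construction, so any curvature shared
identically by all species is absorbed into the scale itself and the
fitted \(E^2\) coefficient reflects only curvature that survives
relative to the mean (species- and type-specific deviations).  The
unit tests therefore validate the quadratic term against data curved
on a *fixed* scale axis.

### Translation

Translation operates at the individual level, not per organ system:
event-type effects are collapsed by averaging with their observed
frequencies, giving each species a marginal curve
\(\log(\text{age}) = A_s + B_s E + \gamma E^2\).  An age in the source
species is solved back to its score on the increasing branch of the
quadratic (the cancellation-free root
\(E = 2(A_s - y)/(-B_s - \sqrt{B_s^2 - 4\gamma(A_s - y)})\); a zero
\(\gamma\) reduces to linear inversion), then evaluated on the target
species' curve and exponentiated.  Same-species translation returns
the input exactly; scores outside \([0,1]\) are returned but flagged
as extrapolation, since late-life alignments for sparsely sampled
species are necessarily approximate.  Ages above a concave curve's
apex have no solution and raise an error naming the attainable bound.

## Transcriptomic age transfer

Expression matrices (TPM or RPKM, genes × samples) from a reference
species train six regressor families on `log(value + 1)` features
against log age: lasso- and elastic-net-regularised linear models
(penalty tuned by internal cross-validation), support-vector
regression, k-nearest-neighbour, random forest, and Gaussian-process
regression.  Samples are split ~70/30 (seeded); families are compared
by test-set RMSE in log-age units and the best is selected.  Applying
the selected reference-trained model to another species' (or
organoids') expression yields reference-species-equivalent ages; each
transferred sample is exported as a `transcription` time point for the
main model.  RMSE is computed on log ages to match the model's fitting
frame.  Regularised predictors shrink toward the training mean, so
transferred ages are mildly attenuated at the extremes of the training
age span; transfers are only meaningful within that span, and the
recovery tests are constructed accordingly.

A non-parametric cross-check, `correlation_align()`, correlates one
profile against a reference series (genes filtered at
`log10(expression) > 0.5` in the target profile; both sides
log10(x+1)-transformed) and reports the reference age of the strongest
Pearson correlation, ties resolved to the youngest age with a flag.

## Trajectory milestones

Gradual traits are converted to time points three ways:

* **Growth milestones** — logistic and Gompertz curves fitted by
  Levenberg–Marquardt least squares (data-derived starting values:
  asymptote at the series maximum, inflection near the half-maximum
  age), lowest AIC wins; non-convergent or non-increasing series fall
  back to isotonic regression with a warning.  `milestone_age(fit,
  pct)` inverts the curve in closed form; since sigmoids never attain
  their asymptote, `pct = 100` means \((1 - 0.01) A\).
* **Peak ages** — smoothing spline (GCV-chosen smoothness), maximum on
  a fine grid; boundary maxima are flagged as censored peaks.
* **Attainment ages** for integer counts (e.g. ossified carpal bones)
  — isotonic regression, first *observed* age whose fit reaches
  `adult_value - 0.5`.  No interpolation between observation ages:
  counts are step-valued, and a step from 0 to the adult value at age
  *a* must attain at exactly *a*.

## Variation and survival

`cv_profile()` summarises within-species dispersion as sd/mean of
linear-scale ages across populations per event (a CV of log ages is
not a standard dispersion measure), with an empirical 5th–95th
percentile band across events — a guide to the plausible spread of
extrapolated alignments.  `sex_slope()` regresses male on female log
ages (the axis convention is a package choice; the swapped-axis slope
is also reported) and flags events with |studentized residual| > 3.

`build_survival()` computes the fraction surviving *up to* each
distinct age from death-age cohorts (no censoring machinery:
inputs are complete cohorts or validated life-table fractions), and
`rescale_survival()` maps every grid age through the fitted
translation while leaving fractions untouched — monotone translations
preserve curve validity.  `survival_quantile_age()` is the step
inverse (smallest grid age at or below the target fraction); the step
convention makes quantile-then-rescale and rescale-then-quantile agree
exactly.

## Synthetic data: what it emulates and what it does not

Every input class has a seeded generator with serialisable ground
truth, so all pipeline stages have parameter-recovery tests without
external data:

* `gen_event_table()` — species-by-event log ages
  \(\alpha_s + \beta_s E_e + \gamma E_e^2 + N(0, \sigma^2)\), with
  latent scores uniform on \([0,1]\) sorted and the extreme events
  pinned at exactly 0 and 1 (the scale is defined by its earliest and
  latest events; pinning makes the realized scale coincide with the
  latent axis when \(\sigma = 0\), giving exact oracles).  Per-species
  intercepts and slopes derive from two published anchors each: an
  early neural event (28–40 days post conception by species) and the
  oldest age the alignment covers (68 y in humans, 57 y in
  chimpanzees, down to 15 y in marmosets), so noise-free tables
  reproduce those alignments exactly.  Defaults: 9 species, 64 events,
  \(\gamma = -0.4\), \(\sigma = 0.05\)–0.1 log-days, 30% of cells
  missing completely at random (the data's missingness mechanism is
  unknown; MCAR is the neutral choice), every event kept in at least
  one species.  Optional heterochrony injection multiplies one
  (species, event-type) slope for power studies.
* `gen_expression_pair()` — informative genes with monotone log-age
  signal \(a_i + b_i \log t\), a known warp mapping target ages onto
  the reference timeline, lognormal noise; uninformative genes are
  age-independent.
* `gen_growth_series()`, `gen_attainment_series()`,
  `gen_survival_cohort()` (Gompertz mortality via flexsurv),
  `gen_population_ages()` (lognormal per-event CVs parameterised by
  the 5th/95th percentiles 0.01–0.13 with a 0.3 cap, the dispersion
  shape reported for human populations), `gen_sex_ages()`.

The generators deliberately do **not** simulate transcriptome
covariance structure, phylogenetic correlation among species,
non-random missingness, or measurement heterogeneity between data
sources.  Passing recovery tests therefore shows the estimators are
correct and well-calibrated under the stated generative model — not
that real cross-species compilations satisfy that model.

## Problem sizes and numerical choices

The test-suite and acceptance computations use 9 species × 60–64
events, 200 genes × 40 samples per species, 200-replicate null
simulations for the heterochrony type-I check, and a 10^5-individual
cohort for the survival oracle — sizes at which every stage's
behaviour is already asymptotically stable while a full run stays
around a minute.  Quadratic inversion uses the citardauq form to avoid
catastrophic cancellation near the scale origin; event-table CSVs are
written at 17 significant digits so round trips are bit-identical;
all stochastic steps take explicit integer seeds and are pure
functions of (spec, seed).

## Known limitations

* Fixed-effects OLS only: no mixed effects, no phylogenetic
  correction, no imputation-uncertainty propagation.
* Extrapolation beyond the fitted scale range is flagged, not
  forbidden — interpret flagged translations (very old great apes)
  as approximate.
* The coding of factors (and hence individual coefficients) is a
  convention; translations, R², and F are invariant to it, printed
  coefficients are not.
* Regularised transfer predictors attenuate ages near the edges of
  their training span; train on the widest available age range.
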