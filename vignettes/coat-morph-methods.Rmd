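---
title: "Methods: coat-morph analysis of camera-trap surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coat-morph analysis of camera-trap surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`feralcoats` implements a complete analysis chain for coat colour and
pattern morphs of feral cats (*Felis catus*) observed on a camera-trap
network: raw image labels are mapped to a small set of modelling
categories, images are grouped into detection events, sites are filtered
for trustworthy absences, each site receives a modal coat type, and two
multinomial logistic regressions relate coat morphs to landscape and to
nightly lunar/weather conditions. A synthetic-survey generator with known
ground truth makes every stage verifiable end to end. This vignette
records the modelling assumptions, parameter choices and their rationale.

## The coat taxonomy

Raw labels are a pattern (solid, blotched, broken, spotted, striped,
ticked, tortoiseshell, tuxedo, unknown), a colour (black, brown, orange,
mixed, unknown) and a white-markings flag. White is controlled by a
separate locus, so the flag is independent of pattern and colour, with one
exception: tuxedo — a mostly-white cat — is *defined* by white coverage
and requires `white = TRUE`. Exactly 13 legal pattern-colour types exist:
the five tabby patterns in brown or orange, solid black, tortoiseshell
(always a mixed mosaic) and tuxedo.

For modelling, types collapse to five categories of assumed ecological
similarity: `solid_black`, `mackerel_brown` (broken, spotted, striped and
ticked tabbies — patterns with a shared camouflage role), `blotched_brown`
(kept separate: no other felid shows blotching, so its role is unknown),
`orange` (all orange tabbies pooled; colouration assumed to dominate
pattern at small sample sizes) and `tortoiseshell`. Tuxedo cats and
records with an unknown field are `excluded` and never enter a model.

Design choices worth noting:

* **Grey** is folded into brown at ingest (grey cats sit on a gradient to
  brown); the vocabulary itself has no grey value, and the recode is
  logged.
* **Validation rejects** illegal pairs (e.g. solid + orange) rather than
  coercing them, so labelling errors surface immediately.
* The tuxedo label is taken as authoritative input: the "more than half
  white" judgement cannot be re-derived from labels.

## Events, retention, modal coat types

An **event** is a maximal run of images of one cat at one camera with
consecutive images at most 60 s apart (a strictly longer gap opens a new
event). Images of different known individuals never merge; images without
an individual identity are grouped by time within their site and
category, so every event carries a single category. Event counts are
invariant to input order and non-increasing in the gap parameter.

**Retention**: a camera that operated fewer than 83 days and never
recorded a cat is a potential false negative and is dropped; any site
with a detection, or operating at least the threshold, is kept. The
83-day figure is the 95th percentile of times to first cat detection.
The percentile uses ECDF linear interpolation (`quantile type 4`)
followed by a ceiling to whole days — rounding up is the conservative
direction, retaining fewer doubtful absences.

**Modal coat type**: the category with the most identified individuals at
a site; ties fall to the category with more events; residual ties fall to
a fixed order (descending survey-wide prevalence) and are flagged. Solid
black cats carry no identifying markings, so per-site black "individuals"
are imputed as `max(1, round(black images / images-per-cat))` using the
survey-wide images-per-identifiable-cat ratio — applying the global ratio
locally. Over-estimation is tolerable here because where black images are
plentiful, black would top the site ranking regardless.

**Black abundance**: the ratio estimator divides identifiable images
(total − black − unknown-coat; tuxedo images remain in the pool) by the
number of identified individuals, then divides the black image count by
that rate. In simulation the estimator is accurate when images per
individual are homogeneous; with site-level capture processes it
undershoots the true resident count because residents that are never
photographed still exist in the truth but not in the identified pool —
the analysis drivers print this gap rather than hiding it.

## The lunar clock

Nights are classified by the moon's illuminated fraction at local
midnight (survey-wide timezone, default UTC+10): above 0.80 is *full*,
below 0.20 is *new*, anything between is excluded from temporal
modelling (both inequalities strict). The fraction uses a cosine
phase-age model on the mean synodic month (29.530588 d) anchored at the
2000-01-06 18:14 UTC new moon:
$f(t) = \tfrac12\,(1 - \cos 2\pi a(t)/P)$ with $a(t)$ the age since the
epoch modulo $P$. The dichotomy only needs threshold crossings, for which
this model errs by at most a few hours near the cut points; an ephemeris
table (`date, fraction`) can be supplied where exactness matters.
Near-threshold nights may therefore classify differently from an exact
ephemeris — an accepted limitation.

Because the fraction lingers near its extremes (its distribution over a
cycle is arcsine-like, not uniform), each 20 %/80 % tail covers
$\arccos(0.6)/\pi \approx 29.5\%$ of the cycle: about 59 % of nights
enter the temporal model, and full and new nights sit within 1 % of
parity over any multi-year window.

## Multinomial logistic regression

Both models use a from-scratch maximum-likelihood multinomial logit with
the reference category's coefficients fixed at zero. Newton–Raphson on
the exact observed information with step-halving; convergence requires a
relative log-likelihood change below `tol = 1e-8` *and* a score maximum
below $10^{-6} n$. The coefficient covariance is the inverse observed
information at the optimum; equivalence with an independent reference
implementation is enforced in the test suite to four decimals.

Numerical and inferential choices:

* **Rank checks**: the design is QR-checked up front and rank deficiency
  reported with the offending column names.
* **Separation** is detected by coefficient-norm growth (‖B‖∞ > 30) and
  flagged loudly, never truncated silently; an optional ridge penalty
  (added to both score and information, and to the reported covariance)
  yields a finite shrunk fit for degenerate inputs.
* **Intervals**: "97.5 % confidence interval" is taken literally as a
  two-sided 97.5 % interval ($z \approx 2.2414$); the level is a
  parameter, so 95 % is one argument away. Significance is
  interval-excludes-1 with no multiplicity correction, matching field
  practice for these models.
* **Standardization**: continuous predictors are z-scored by default and
  the transform recorded, so odds ratios are per standard deviation;
  raw-unit mode is available.

**Spatial model**: response = modal coat type per retained site
(reference `solid_black`, the most common and distinct morph — absence is
not meaningful since all retained modelled sites detected cats);
predictors = elevation (m), topographic roughness, isothermality, FPAR,
distance to nearest town (km) and vegetation class
(grassland/woodland/forest, grassland reference).

**Temporal model**: response over full/new camera-nights = captured coat
category, with an explicit `absence` level as reference (capture-free
nights vastly outnumber captures). A night with several captured
categories contributes one row per category and no absence row — this
keeps a one-outcome-per-row likelihood while counting every category's
detection. Predictors = rainfall (mm), solar exposure, minimum
temperature (°C), a new-moon dummy (new = 1, so positive coefficients
mean higher activity on dark nights) and the moon × solar interaction
(solar exposure proxies cloud cover).

## PDE activity index

PDE = 100 × capture nights / operating nights. The bootstrap resamples
**sites** with replacement (nights within a site are dependent), B = 1000
by default, seed mandatory; the pooled index (total captures / total
nights) is primary and the mean-of-site-PDEs variant is reported
alongside. The bootstrap SE converges to the exact resampling sd, which
the tests verify by enumeration on toy configurations.

## The synthetic survey generator

Defaults are the package's study conditions: 651 sites, 365 nights.
Covariates span realistic Tasmanian ranges (elevation uniform 0–1500 m,
FPAR 0.2–0.95, distance to town exponential with 15 km mean, vegetation
25/30/45 % grassland/woodland/forest). Site coat fields come from a
softmax-linear model whose default intercepts reproduce a plausible
marginal prevalence (roughly 43/33/16/5/3 % across the five categories)
and whose slopes mirror reported effect sizes for Tasmanian feral cats
(elevation odds ratios 2.5 for orange, 4.0 for tortoiseshell, 0.64 for
blotched brown; FPAR 1.3 and forest 1.9 for mackerel brown; isothermality
2.7 and FPAR 1.5 for orange). Each site holds one dominant category
(1 + Poisson(1) individuals) plus minority intruders (probability 0.15,
one individual each), giving the modal-coat stage realistic tie pressure.

Nightly captures are Bernoulli per resident category: probability 0.022
on full-moon nights, multiplied per category on new-moon nights
(1.6/1.5/1.5/1.0/2.0 for black/mackerel/blotched/orange/tortoiseshell —
an activity advantage on dark nights for everything except orange);
intermediate nights use the geometric mean, and never enter the temporal
model anyway. Captures expand to image bursts under 60 s spacing;
individual identities are withheld with probability 0.25 and always for
solid black cats; rare unknown-coat and tuxedo captures exercise the
exclusion paths; 5 % of deployments are cut to 30–80 nights to exercise
retention. Weather is drawn independently of moon phase (configurable
correlation is out of scope).

Reproducibility note: every generation stage draws from its own derived
RNG substream. Early in development the site-covariate draw and the
category draw shared a seed, which silently correlated elevation with the
category inverse-CDF pick — the kind of artefact only a ground-truth
recovery test catches.

**What the generator does not emulate**: spatial autocorrelation of
covariates and of cat territories, movement between sites, weather
station distance (weather is per camera-night, not interpolated from
stations tens of km away), seasonality, and per-individual capture
heterogeneity. Passing recovery tests therefore demonstrate correctness
of the estimation machinery under the stated generative model, not
robustness to these real-data complications.

## Verification strategy and problem sizes

The test suite checks, at sizes chosen to keep a full run in well under a
minute per file: oracle equivalence of the MLE against an independent
reference on 20 random designs (n = 200, K ≤ 4, P ≤ 4); closed-form
cross-ratio recovery on a saturated 2×2 design; Wald interval coverage of
a known truth (50 replicates at n = 2000, nominal 97.5 %); ground-truth
recovery of the generator's non-zero coefficients through the spatial
builder; a configured moon-effect multiplier of 2.0 recovered within
±25 % from one year-long 250-site survey; bootstrap SEs against exact
enumeration; and arithmetic identities over the shipped published survey
tallies. End-to-end spatial odds ratios are attenuated toward 1 relative
to the generating truth because the modal coat type is a noisy measure of
the site's dominant category — visible in `analysis/03_spatial_model.R`'s
truth comparison, and expected of the real survey too.

## Known limitations

* The mean-synodic lunar model can misclassify nights within a few hours
  of a threshold crossing; supply an ephemeris table for exactness.
* The black-cat ratio estimator is biased low for *resident* abundance
  whenever some individuals are never photographed, and biased high when
  other coat types are image-poor; it is used only to rank categories
  within sites, not as a population estimate.
* Odds ratios from standardized predictors are per sample standard
  deviation and not comparable across surveys without the recorded
  scaling.
* No spatial autocorrelation or random effects: sites are treated as
  independent, and camera-nights within a site are independent given the
  covariates in the temporal model (the PDE bootstrap, by contrast, does
  respect within-site dependence).
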