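# feralcoats

Analysis of coat colour and pattern morphs of feral cats (*Felis catus*)
recorded by camera-trap networks, for wildlife ecologists asking whether
pelage phenotypes track landscape features or lunar conditions. The
package covers the full chain from raw image labels to fitted models:

* a validated **coat taxonomy** — 13 legal (pattern, colour) types plus a
  white-markings flag, collapsed to five modelling categories
  (`solid_black`, `mackerel_brown`, `blotched_brown`, `orange`,
  `tortoiseshell`; tuxedo and unknown-coat records are excluded);
* an **event pipeline** — images < 1 min apart become events, cat-free
  cameras operating < 83 days are discarded as potential false negatives,
  each site gets a *modal coat type* (most identified individuals, ties
  broken by events), and unmarked black cats are counted with a ratio
  estimator: images-per-cat = identifiable images / identified
  individuals, estimated black = black images / images-per-cat;
* a **lunar clock** — illuminated fraction from a cosine phase-age model
  on the mean synodic month; nights with fraction > 0.80 are *full*,
  < 0.20 are *new*, the rest are dropped from temporal modelling;
* from-scratch **multinomial logistic regression** by Newton-Raphson
  maximum likelihood. With reference category coefficients fixed at 0,
  P(yᵢ = k) = exp(xᵢ'βₖ) / Σⱼ exp(xᵢ'βⱼ); Wald odds-ratio intervals
  exp(β̂ ± z·se) at a two-sided 97.5 % level (z ≈ 2.2414). The *spatial*
  model regresses modal coat type (solid black reference) on elevation,
  roughness, isothermality, FPAR, distance to town and vegetation class;
  the *temporal* model regresses nightly captures (absence reference) on
  weather, a new-moon dummy and the moon × solar-exposure interaction;
* the **PDE activity index** — 100 × capture nights / operating nights —
  with site-level bootstrap standard errors;
* a **synthetic survey generator** with known ground truth (softmax coat
  field over covariates, per-category moon multipliers, marked
  individuals with an unknown-ID rate, unmarked black cats), so every
  stage is testable without the original images.

## Worked example

Simulate a year-long 651-site survey and push it through the whole chain
(this is `analysis/01_simulate.R`–`05_activity.R`; the numbers below are
the actual script output at the seeds committed there):

```r
library(feralcoats)
sv   <- simulate_survey(sim_config(), seed = 20240501)
prep <- prepare_events(sv)               # events + retention + daily records
survey_black_estimate(prep)
#> Black-cat ratio estimate
#>   images per identifiable cat: 19.73 (21668 images / 1098 individuals)
#>   estimated black individuals: 463.11 (~463) from 9139 black images
```

Modal coat types and the spatial model:

```r
black <- survey_black_estimate(prep)
summ  <- site_summaries(prep$model_events, black$images_per_cat)
table(summ$modal_category)
#> blotched_brown mackerel_brown         orange    solid_black  tortoiseshell
#>             87            215             55            230             60
sp <- run_spatial(sv)   # wraps the steps above + fit + Wald intervals
```

Significant spatial effects (odds ratios per standard deviation,
solid-black reference) in that run included orange at higher elevation
(OR 2.09, interval 1.41–3.11), blotched brown at lower elevation
(OR 0.61, 0.45–0.83) and mackerel brown in forest (OR 1.85, 1.07–3.21) —
attenuated toward 1 relative to the generating truth because the modal
type is a noisy readout of a site's dominant category.

Temporal model and activity index:

```r
tm <- run_temporal(sv, seed = 20240504)
subset(as.data.frame(tm$odds_ratios), predictor == "moon_new")
#>          category odds_ratio lower upper significant
#>       solid_black      1.696 1.520  1.89        TRUE
#>    mackerel_brown      1.426 1.280  1.59        TRUE
#>    blotched_brown      1.527 1.312  1.78        TRUE
#>            orange      0.995 0.839  1.18       FALSE
#>     tortoiseshell      2.022 1.722  2.37        TRUE
tm$pde$full; tm$pde$new
#> PDE [full]: 3.64% (bootstrap SE 0.100, 647 sites, B = 1000, ...)
#> PDE [new]:  5.42% (bootstrap SE 0.133, 647 sites, B = 1000, ...)
```

Every coat type except orange is more likely to be captured on new-moon
nights — exactly the generating truth (per-category new:full multipliers
1.6/1.5/1.5/1.0/2.0), recovered through the full pipeline.

The `analysis/` directory holds the five numbered driver scripts; run
them in order from the repository root, each writes its tables under
`results/`. The methods vignette
(`vignettes/coat-morph-methods.Rmd`) documents the models, parameter
defaults and generator design.

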