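---
title: "Nutritional geometry of lifespan and reproduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutritional geometry of lifespan and reproduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscape)
```

## The problem

In the nutritional geometric framework, an animal's intake of two
macronutrients — here protein (P) and carbohydrate (C), in mg — is treated
as a point in a two-dimensional nutrient space, and a life-history trait as
a surface over that space. An animal confined to a single diet of fixed P:C
mass ratio can only move along a ray through the origin (its *nutritional
rail*); a grid of diets crossing several ratios with several total
concentrations spreads individuals across the space so the surface can be
estimated. `nutriscape` implements the full analysis chain for such
experiments in the marula fly *Ceratitis cosyra*: two selection lines
(control, CT, and lines upward-selected on the age of female oviposition,
US), each sex, with lifespan (LS, days), lifetime egg production (LEP,
eggs) and daily egg production (DEP, eggs/day) as traits.

Two experimental designs are covered:

* **No-choice**: each fly gets one of 15 liquid diets (P:C ratios 0:1,
  1:8, 1:4, 1:2, 1:1 at 45, 180 and 360 g/L total concentration); the full
  design is 15 diets x 2 lines x 4 replicates x 2 sexes x 5 flies = 1200
  flies.
* **Choice**: each fly gets one of four complementary diet pairs (a 1:1
  and a protein-free 0:1 diet at 180 or 360 g/L) for 16 days in four 4-day
  measurement intervals; 4 pairs x (4 CT + 3 US replicates) x 2 sexes x 5
  flies = 280 flies.

## Intake accounting

Diets are liquids in graduated pipette tips. Consumption is the drop in
diet length, converted to microlitres by a linear calibration
(`calibration()`); the default anchors a full tube at 100 uL, since the
exact standard curve behind the published measurements is not available.
Evaporation is estimated from control tubes of the same diet over the same
interval; the per-cell mean control loss is subtracted and the result
floored at zero, because negative consumption is physically impossible
(`evaporation_correction()`). Volumes convert to nutrient masses through
the diet's densities: a diet with mass parts $p$ : $c$ at total
concentration $k$ g/L carries $\frac{p}{p+c}\,k/1000$ mg protein and
$\frac{c}{p+c}\,k/1000$ mg carbohydrate per uL, so protein + carbohydrate
mass always equals volume x $k/1000$ (mass balance). Micronutrients and
dye, constant across diets, are ignored.

## The response-surface model

Analysis records carry intake per day lived (cumulative mg divided by
lifespan, so short- and long-lived flies are comparable) and are
z-standardized (mean 0, sd 1, denominator $n-1$) within each model-fitting
dataset. On standardized intakes $z_P, z_C$ the second-order model for a
standardized trait $z_T$ is

$$z_T = \beta_0 + \beta_P z_P + \beta_C z_C + \gamma_{PP} z_P^2 +
  \gamma_{CC} z_C^2 + \gamma_{PC} z_P z_C + u_{rep} + \varepsilon$$

with a random intercept $u_{rep}$ per replicate population. `surface_fit()`
fits the linear-only model (the nutritional gradients $\beta_P, \beta_C$)
and the full model (adding the quadratic terms, whose negative values
indicate a peak and positive a trough, and the correlational term). Raw
polynomials of the standardized intakes are used, not orthogonal
polynomials, following the response-surface tradition for selection
gradients. Models are estimated by maximum likelihood (not REML) so that
each term can be tested by a likelihood-ratio chi-square against the model
without it (`term_tests()`); REML likelihoods are not comparable across
fixed-effect structures. When the replicate variance estimates at the zero
boundary, the fit falls back to ordinary least squares with replicate as a
fixed factor, which keeps nested likelihood ratios well defined; with the
random-effect variance at zero the coefficients equal OLS on the same
design matrix.

Overall consumption is compared between lines and sexes with
`fit_total_consumption()`: square-root-transformed total daily consumption
(to normalise right-skewed residuals) on line, sex, their interaction,
concentration and P:C ratio, with replicate as a random intercept.

## Comparing landscapes

Whether two groups (lines, sexes, or two traits of the same flies joined
by a dummy "trait type" factor) share a landscape is tested by sequential
model building (`sequential_compare()`): six nested fixed-effects models
add, in order, the linear effects, their group interactions, the quadratic
effects, their interactions, the correlational effect, and its
interaction. Each block is judged by a partial F-test on the residual sums
of squares of its model pair,

$$F = \frac{(SS_r - SS_c)/DF_1}{SS_c/DF_2},$$

with $DF_2$ the residual degrees of freedom of the larger model. Residual
sums of squares come from fixed-effects fits (replicate as a fixed
covariate, configurable off) because residual SS is not well defined under
a mixed model, and the published comparison tables print SS/df consistent
with classical partial F-tests. The group main effect is included from the
first model onward; the published residual degrees of freedom (592, 588,
586 at n = 600) imply a slightly different covariate set that the source
does not describe, so `DF2` is reported as implemented rather than forced.
When a linear or quadratic block is significant (default alpha = 0.05), a
univariate follow-up tests each nutrient's interaction term separately by
likelihood ratio to attribute the difference.

Intakes are always standardized on the pooled two-group set (both groups
share one intake space). The trait is standardized pooled by default; for
comparisons of two different traits (`standardize = "by_group"`) each
trait is standardized within itself, since traits measured in different
units (days vs eggs) have no common raw scale.

## Nutritional landscapes and optima

For visualisation and optimum location, thin-plate regression splines are
fitted on *untransformed* trait values and mg/day intakes
(`fit_landscape()`, via `mgcv::gam(y ~ s(P, C, bs = "tp"))`), with the
smoothing parameter chosen by generalized cross-validation. Because the
thin-plate penalty is isotropic while carbohydrate intakes span several
times the range of protein intakes, both axes are scaled to unit standard
deviation internally before fitting; without this, the argmax of even a
noiseless test surface is displaced by one or two grid cells along the
flat carbohydrate direction. The basis dimension defaults to
`k = min(100, n - 2)`, large enough that noiseless surfaces are
near-interpolated. Predictions are evaluated on a 100 x 100 grid over the
observed bounding box and masked to the convex hull of the observed
intakes — the spline is not trusted where no fly ate.

`find_optimum()` takes the grid argmax inside the hull and refines it by
Nelder-Mead on the spline (rejecting refined points outside the hull);
exact grid ties break toward lower protein, then lower carbohydrate. A
flat landscape returns the hull centroid with a warning.
`optimum_region()` bounds the optimum by a case-resampling bootstrap of
the argmax: rows are resampled, the landscape refitted, and the
$(1-\alpha)$ region is the smallest set of grid cells, by bootstrap count
rank, covering that share of bootstrap argmaxes (always including the
point estimate's cell). This is a standard bootstrap argmax region; the
published analysis names a package for this step but not its algorithm.

## Dietary choice and regulation

For choice data the *random-feeding null* assigns half of each fly's total
consumed volume to each tube of its pair ("equal amounts of each food"
interpreted as equal volumes, since the foods are liquids measured
volumetrically) and converts via the diets' densities
(`expected_random_intake()`). Observed minus expected intake is tested
against zero per nutrient with a two-sided one-sample t-test
(`random_feeding_test()`); significant departures are classified as a
protein or carbohydrate preference by the sign of the mean difference. The
per-nutrient (rather than combined) test is a package choice; the source
does not state the test's dimensionality.

The *regulated intake point* of a group is the mean cumulative (P, C)
intake across flies pooled over all diet pairs
(`regulated_intake_point()`), reported with its C:P ratio ("1:x").
Regulation is compared between groups by `compare_regulation()`:
cumulative carbohydrate intake on protein intake, group, and their
interaction with a replicate random intercept (ML); a significant
interaction indicates the groups defend different intake ratios.

## The synthetic-data generators

No raw data accompany the published study, so the package ships generators
that emulate both designs and make every stage testable.

**No-choice** (`generate_experiment1()`): each fly draws a daily feeding
volume lognormally (CV 0.35) around a diet-specific mean that scales as
$100\sqrt{180/k}$ uL/day with concentration $k$ — flies on dilute diets
drink more, so realized intakes spread along each rail while total
nutrient intake stays comparable; upward-selected flies consume 10% more
and controls 10% less than this baseline, emulating the reported line
difference in overall consumption. Lifespan is gamma-distributed around
the lifespan surface value at the fly's realized intake (positive support;
sd 6 days by default), dish egg counts are negative binomial (size 8) with
daily mean from the DEP surface over 6-day dishes, replicate effects are
additive normal shifts (sd 1.5 days for lifespan, 0.3 eggs/day for DEP),
and 2% of flies are flagged as non-natural deaths. The default true
surfaces (`default_surfaces()`) reproduce the qualitative structure of the
published landscapes: carbohydrate-dominated lifespan peaking at low P:C
with carbohydrate intake in the low-to-mid 20s mg/day in every group;
control-line DEP peaking near (1.6, 16.7) mg/day; upward-selected DEP
rising with protein only. The source states no generative model and no
within-cell variances; these noise levels were chosen once as realistic
for such traits and are not tuned.

**Choice** (`generate_experiment2()`): per line, total tube volumes solve
the two-diet mixing equations for the line's cumulative 16-day (P, C)
target — by default the published mean intakes, a 1:3.6 blend for CT and
1:3.2 for US — split evenly over the four intervals and perturbed by
lognormal multipliers per fly (CV 0.15) and per interval (CV 0.20).
Unreachable targets (outside the cone of the two rails) fall back to the
nearest single-rail point with a message. No fly dies before day 16.
`as_tube_measurements()` converts generated volumes back into raw
tube-length tables (with evaporation and control tubes) so the intake
accounting can be exercised end to end; with noiseless controls the
reconstruction is exact.

What the generators do *not* emulate: temporal switching between tubes
within an interval, age-dependent feeding, correlations between lifespan
and egg-laying beyond those induced by shared intake, male reproductive
output, or evolution across selection generations. Passing tests therefore
demonstrate that the statistical machinery recovers known structure under
realistic designs and noise — not that the biological conclusions of any
particular dataset are correct.

## Numerical choices and limitations

* All mixed models use `lme4::lmer` with ML and singular-fit checks
  suppressed; boundary fits are handled as described above.
* Simulation-based checks (parameter recovery over 20 generator seeds at
  n = 300 per landscape; type-I error of the comparison tests over 500
  null datasets at the study sample sizes, n = 600 and n = 280) run inside
  the test suite in about a minute. Null-simulation loops are seeded once
  and draw datasets from a continuous RNG stream; reseeding each dataset
  with adjacent integers produces correlated Mersenne-Twister streams and
  visibly inflates the Monte-Carlo error of rejection-rate estimates.
* The likelihood-ratio interaction test in `compare_regulation()` is
  slightly anticonservative at the choice experiment's sample size when
  the generator's multiplicative intake noise makes the carbohydrate
  residuals heteroskedastic; this is a property of the chi-square
  approximation under those conditions, not of the implementation (see the
  test suite's calibration checks).
* Published gradient standard errors and the exact printed optima cannot
  be reproduced without the raw data; the package verifies instead the
  quantities that are arithmetic functions of printed values (partial F
  from printed sums of squares, regulated-intake ratios from printed
  means, design counts) and the structural behaviour of every estimator.

## A worked example

```{r, eval = FALSE}
x <- generate_experiment1(design_exp1(seed = 11))
rec <- prepare_analysis(x$flies)$records
ctf <- subset(rec, line == "CT" & sex == "F")
summary(surface_fit(ctf, "LS"))
L <- fit_landscape(ctf$P_day_mg, ctf$C_day_mg, ctf$LS)
find_optimum(L)
plot(L)
```
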