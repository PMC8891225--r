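---
title: "Drought-response phenomics for augmented soybean trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drought-response phenomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodrought)
```

## Overview

`phenodrought` implements a complete analysis chain for drought-response
field phenomics in a diverse crop collection grown in augmented row-column
designs:

1. **Synthetic trial generation** — designs, weather seasons, genotype and
   spatial effects, and plot-level time series with known ground truth.
2. **Environment indices** — thermal time (GDD), FAO-56 reference
   evapotranspiration, cumulative water deficit (CWD), and the crop water
   stress index (CWSI) from canopy temperature.
3. **Trait extraction** — beta growth-curve fits per plot and the derived
   traits: maximum canopy height (CH), maximum absolute growth rate
   (AGRmax), thermal time to 75% cover (CC75), degree of indeterminacy
   (DET), rate of senescence (SNC), and phenology (R2, R5 and phase
   durations) from a fitted reproductive-stage curve.
4. **Mixed-model analysis** — emergence filtering, Tukey outlier cleaning,
   REML variance components with AIC selection over six candidate spatial
   structures, genotype BLUPs and broad-sense heritability.
5. **Drought-response analysis** — the drought index Yr, correlation
   suites, redundancy-based variable reduction, and a correlation-scaled
   PCA of multi-trait responses.

The synthetic generator is first-class, tested code: it is the instrument
that makes every downstream stage verifiable against known truth, since
plot-level raw data from comparable published trials are generally not
deposited.

## The trial design

Each simulated field is an augmented row-column design. By default three
check genotypes are replicated nine times, nine checks six times, 13 checks
three times, and 334 entries are unreplicated, giving 454 plots and 359
distinct genotypes per field — two fields (well-watered control and
rain-out-shelter drought) per season, two contrasting seasons. The number
of blocks and their grid is not a property of the replication scheme, so it
is configuration: the default is 9 blocks of 6 x 9 cells, which holds 454
plots with spare capacity and gives the replicated checks good
connectivity across blocks. Check placement samples blocks proportionally
to remaining capacity, one plot per block where the replicate count
permits.

Growth groups 1–4 (late to early maturity) control sowing date, sowing
density (45/55/65/75 seeds m⁻²), row spacing (0.40 m for GP1–2, 0.25 m for
GP3–4) and thinning (to 60% of seeding density in GP1–2 only), reproducing
the standard agronomy for these maturity classes.

## The generative model and its analysis twin

Plot values of manually scored traits follow the same linear mixed model
later used for analysis:

\[ y = \mu_{GP} + g + b + r + c + e, \]

with genotype, block, field-row, field-column and residual effects all
centred Gaussian. Genotype effects are drawn once per genotype and shared
between the control and drought fields, so treatment contrasts on BLUPs are
meaningful. Drought multiplies the genetic value \((\mu + g)\) of a trait
by a configurable factor; the implied broad-sense heritability
\(\sigma^2_G/(\sigma^2_G+\sigma^2_e)\) is recorded as ground truth.

Canopy growth uses the determinate beta growth function

\[ w(t) = w_{max}\Big(1 + \frac{t_e - t}{t_e - t_m}\Big)
   \Big(\frac{t}{t_e}\Big)^{t_e/(t_e-t_m)}, \qquad 0 \le t \le t_e, \]

on a thermal-time axis, constant at \(w_{max}\) beyond \(t_e\). The same
family generates canopy height, canopy cover (followed by a linear
post-peak senescence decline) and the reproductive-stage score (asymptote
near stage 7.5). Drought plots get a multiplicative reduction of the
height asymptote (0.89 for the short-drought season, 0.71 for the
long-drought season, matching reported average canopy-height reductions of
11% and 29%), a negative shift of the development times, and accelerated
senescence. Canopy temperature is generated as
\(T_c = T_a + dT_{ll} + s\,(dT_{ul}-dT_{ll})\) with stress level
\(s \in [0,1]\), which makes CWSI exactly recoverable.

Default curve parameters (height asymptote 82–94 cm falling from GP1 to
GP4, \(t_e\) near 1000 GDD with \(t_m = 0.42\,t_e\), cover asymptote 0.95,
senescence onset near 1500 GDD) were chosen once to give trait magnitudes
typical of a diverse soybean collection — mean CH near 88 cm, AGRmax near
12–13 cm per 100 GDD, SNC near 0.4 under control conditions. Fifteen
simulated flights between 150 and 1800 GDD emulate a UAV campaign.

What the generator does **not** emulate: image-level noise structure
(orthomosaics, pixel masking), spatially correlated residuals, genotype ×
treatment interaction beyond the uniform multiplier, soil-water dynamics,
and non-Gaussian trait distributions. Passing tests therefore demonstrate
correctness of the analysis machinery under the declared model, not
robustness to every pathology of real field data.

## Environment computations

Daily GDD uses the capped-average rule
\(\max(0, (\min(T_{max},T_{cap})+\min(T_{min},T_{cap}))/2 - T_{base})\)
with soybean defaults \(T_{base} = 10\,°C\), \(T_{cap} = 30\,°C\), both
configurable; all thermal-time outputs are relative to this single
configuration. Reference evapotranspiration is the FAO-56 Penman–Monteith
daily form with soil heat flux 0, albedo 0.23, the clear-sky envelope from
extraterrestrial radiation, and actual vapour pressure from daily mean
relative humidity; net longwave loss is floored at zero so heavily
overcast days cannot produce negative radiation terms. CWD is the running
sum of ET0 − precipitation from 1 April.

CWSI baselines are a practical point: the classical approach needs
purpose-measured non-stressed and non-transpiring baselines. When these
are not supplied, `estimate_baselines()` uses a low quantile (5th) of the
canopy–air differential among well-watered plots for the lower baseline
and a high quantile (95th) over all plots (plus an optional margin) for
the upper one, per flight. This assumes the flight contains both
unstressed and severely stressed canopies; when stress spans the full
range the mean absolute CWSI recovery error stays below 0.05 in the test
suite. Manual baselines override the estimate.

## Trait extraction: numerical choices

Curve fitting is nonlinear least squares (Levenberg–Marquardt with an
analytic Jacobian) on the parameterization \((w_{max}, t_m, \Delta t_e)\)
with \(t_e = t_m + \Delta t_e\), making the constraint \(t_m < t_e\) a box
bound. Three starts (\(t_m\) at 0.3/0.5/0.7 of the observed time range,
\(t_e\) at 1.2 × the last observation, \(w_{max}\) at the observed
maximum) guard against local minima; the lowest-RSS converged fit wins and
an exact fit short-circuits the remaining starts. Non-convergence yields
missing traits rather than errors, so one bad plot cannot kill a batch;
missing traits are later removed together with other missing data, never
imputed.

CC75 and the R1/R2/R5 crossings are bisection roots on the rising limb;
a crossing whose level exceeds the fitted asymptote is missing. AGRmax
uses the closed form \(w_{max}\,\frac{2t_e-t_m}{t_e(t_e-t_m)}
(t_m/t_e)^{t_m/(t_e-t_m)}\) (the curve's derivative at \(t_m\)), reported
per 100 GDD; the tests verify it against numerical differentiation. The
R-stage fit uses only scores in stages 1–6 — the early, single-sigmoid
part of the developmental trajectory — with the same beta family (the
asymptote left free). SNC smooths the cover series with a 3-point running
median and takes the difference between the maximum and the mean of the
two lowest post-peak values, clamped to [0, 1]. DET
(\(t_e\) of height minus thermal time to R1) is deliberately left
unclamped: negative values are a meaningful signature of strongly
determinate plots.

## Mixed models, model selection and heritability

Plots with emergence below 30% are removed (a plot exactly at 30% is
kept); Tukey's rule (1.5 IQR fences, type-7 quartiles) flags outliers per
trait × treatment × season; a skewness rule (|skewness| > 1 and values
> −1) triggers a log1p transform, operationalizing "transform where the
distribution requires it" — BLUPs are reported on the analysis scale.

Six candidate random-effect structures are fitted per trait, all
containing Genotype, varying the spatial part over Block, Row, Column and
their within-block nested versions (the fully crossed base structure is
overparameterized when columns nest in blocks). The fixed part is an
intercept only, so models are compared by
\(-2\,\ell_{REML} + 2k\) with \(k\) = variance components (residual
included) + 1; lowest value wins, ties break to fewer parameters, then to
candidate order. Fitting is REML via lme4 with a derivative-free optimizer
followed by a damped Newton polish of the interior variance parameters on
the profiled REML deviance (central differences, step capped at 10%,
boundary components held at zero). The polish exists because shrinkage
predictions are visibly sensitive to the last digits of the variance
ratio: with it, balanced single-factor fits agree with the closed-form
ANOVA estimators to better than 1e-6 and with closed-form shrinkage BLUPs
to better than 1e-8.

BLUPs are intercept + predicted genotype effect;
\(H^2 = \sigma^2_G/(\sigma^2_G+\sigma^2_e)\), classed low (< 0.30),
medium (0.30–0.60) or high (> 0.60). Summaries report n, min, max, mean,
sd and CV% for the full collection and per growth group. Per-date traits
(CW, LSEN, CWSI) are fitted as separate responses per observation date.

## Drought-response analysis

The drought index \(Y_r = (C - D)/C\) is computed on genotype BLUPs for
genotypes present in both treatments; it is 0 for equal performance,
positive when drought reduces the trait. \(Y_r\) is undefined when the
control BLUP is within \(10^{-6}\) trait standard deviations of zero (the
ratio is ill-posed there; the choice of floor is ours, documented, since
no convention exists). \(Y_r\) is not computed for PLV and CC75 (scored
or reached before the drought window) nor for DET (a growth-habit trait).
The CV of \(Y_r\) is computed on raw \(Y_r\) values with |mean| in the
denominator; a min-max normalization is available behind a flag but is not
the default, since the published "normalized" variant is not defined
precisely enough to reproduce.

Variable reduction before the PCA walks each declared subset of response
variables in order and drops any variable whose absolute correlation with
an already-retained variable reaches 0.8. The PCA itself is
correlation-scaled (columns standardized; the published analysis says
"standardized" without naming the scaling, and correlation scaling is the
only choice that makes trait units commensurable), on complete cases
only, with the genotype count reported. CWSI enters as \(Y_r\) at the
last measurement date; canopy wilting and leaf senescence enter as the
maximum BLUP over dates, as they exist only in the drought field.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → extract → fit → respond → report,
writing plain CSV outputs, a text report with the per-trait and per-date
summary tables, and a JSON manifest containing the master seed, a
configuration checksum, per-stage row counts and an MD5 checksum of every
output file. Identical configuration + seed reproduce identical files.
Stages communicate in memory within one call; a stage requested without
its upstream stage raises an error naming the stage to run first. A thin
command-line wrapper (`inst/scripts/phenodrought-pipeline.R`) exposes the
same functionality with `--config`, `--seed`, `--outdir`, `--stages`.

All randomness derives from one master seed through a deterministic
per-stage offset scheme, so single stages are reproducible in isolation.

## Problem sizes used in the test suite

The unit suite exercises the machinery on small fields (36 plots, 32
genotypes, 4 blocks) where closed-form oracles and structural invariants
are checked exactly. The scientific-scale checks use the full 454-plot /
359-genotype design: heritability recovery averages 50 simulated trials
per true \(H^2 \in \{0.2, 0.5, 0.8\}\), and the drought-index calibration
(mean \(Y_r\)(CH) under a uniform 0.71 height multiplier) averages 50
end-to-end simulate–extract–model runs. These sizes give Monte-Carlo
standard errors comfortably below the tolerances asserted, and were chosen
as the package's own verification design.

## Known limitations

* Residuals are spatially independent within the mixed models; AR1 x AR1
  or spline field-trend models are out of scope.
* The six candidate structures are a documented default, configurable but
  not exhaustive.
* Quantile CWSI baselines are biased when a flight lacks severely
  stressed plots; supply manual baselines in that situation.
* The generator's drought effect is a uniform multiplier: it calibrates
  the mean of \(Y_r\), not its genotype-level dispersion.
* Emergence, when simulated, is independent of genotype; real
  establishment failures can be confounded with genetics.
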