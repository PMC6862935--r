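---
title: "From time-series heading scores to genetic architecture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From time-series heading scores to genetic architecture: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoQTL)
```

phenoQTL turns per-plot time series of percent-heading scores into heading
date and rate of heading, estimates how heritable those traits are, and
maps their genetic basis in a biparental RIL population. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions that were genuinely open.

## The phenology model

Percent heading for one plot follows a logistic growth curve

$$y_i = \frac{\phi_1}{1 + e^{-(\phi_2 + \phi_3\,\mathrm{day})}},$$

with $\phi_1$ fixed at 100 because a plot always finishes heading. The two
free parameters are the logit-scale intercept $\phi_2$ (unitless) and the
slope $\phi_3$ (per day). Heading date is the day where the curve crosses
50% — evaluated on a 0.1-day grid over the full day range
(`headingDate()`), which agrees with the closed form $-\phi_2/\phi_3$ to
within half a grid step whenever the crossing lies inside the range. The
rate of heading is $\phi_3$ itself: two plots can head on the same day yet
progress at very different speeds, and the rate is the trait that captures
that.

Scores arrive in 10% increments and only span the part of the season when
staff were in the field, so the raw series constrain the asymptotes
weakly. `augmentAnchors()` therefore adds 0% points 10, 20 and 30 days
before the first observation and 100% points 10, 20 and 30 days after the
last — dates when no plot had started, or all had finished, heading. On a
noise-free logistic series these anchors sit on the asymptotes and move
the 50% intersect by less than 0.1 day (a property the tests check); on
noisy series they stop the fit from chasing a runaway slope.

**Fitting.** `fitLogistic()` minimizes the residual sum of squares with a
damped Gauss–Newton (Levenberg–Marquardt style) iteration on
$(\phi_2, \phi_3)$ — the model has an analytic Jacobian, so a generic
optimizer buys nothing. Convergence is declared when the SSE improves by
less than 1e-8 (or at 200 iterations); failure is flagged on the returned
object rather than thrown, so one bad plot cannot stop a 676-plot run.
Initialisation was an open choice. A logit-scale regression (percents
clipped into [1, 99] for the transform only) is a good slope start, but it
is misled when a plot's 50% crossing falls outside the scored window — the
series is then one long plateau plus anchors. We therefore anchor the
intercept at the empirical 50% crossing (midway between the last day below
and the first day above 50) and run the optimizer from two starts, the
logit slope and a crossing-span slope, keeping the lower SSE. The tests
hold the result to the minimum of a dense 2-D grid search and to `nls`.

Observations exactly at 0 or 100 are kept as-is in the least-squares fit;
only the initialisation transform clips. No monotonization or smoothing is
applied to the series — raw field scores do occasionally go backwards, and
the fit should see them.

## Label machinery around a plot-image classifier

When a classifier scores plot images on days between visual scorings, the
training labels must be imputed. The stated intent of the field protocol
is a weighted average of the two surrounding scores with weights based on
the distance in days, i.e. linear interpolation
(`imputePercentLabel()`); scoring days are recovered exactly. We note the
protocol's printed weight formula transposes the two intervals and has a
negative denominator (its own worked case would yield ±35 where the
interpolant is 25); the implementation follows the stated intent.

Repeated re-scoring of the same plots shows that visual labels carry about
10% one-class (±10%) and 5% two-class (±20%) errors. The soft-label target
(`buildSoftLabel()`) encodes exactly that: mass 0.7 on the labelled class,
0.1 one class away, 0.05 two classes away. At the boundary classes (0%,
100%) the out-of-range mass is folded back onto the labelled class rather
than renormalized proportionally — this keeps the sum exactly 1 while
leaving the labelled class strictly dominant, which proportional
renormalization would not guarantee. The training error
(`softLabelError()`) is the mean absolute per-class difference — an L1
metric up to the 1/11 scale, so partial credit accrues smoothly.

Consensus is two-level: per image, the element-wise sum of the 9 patch
distributions is argmaxed (`consensusImage()`); per plot, a majority vote
over image labels (`consensusPlot()`). Ties break deterministically to the
lower class. Whether plot-level aggregation of percent heading should
average percentages instead of voting classes is not settled by the
protocol; voting is the default and averaging is a one-liner on the
returned table. No pixels are touched anywhere — patches are geometry
records (`gridPatches()`), and the classifier is an injected function, so
the machinery is testable without a trained network.

## Heritability and the spatial mixed model

Plot phenotypes follow
$$y_{ijk} = g_i + y_j + r_{k(j)} + e,$$
with entry $g_i \sim N(0, \sigma^2_G)$, year and rep-within-year random,
and — in multi-year tables — an entry-by-year term $\sigma^2_{GY}$, which
the multi-year heritability formula requires. The residual is iid or
separable AR1 ⊗ AR1 over the field's (row, column) grid within year;
missing grid cells are handled by subsetting the dense correlation matrix,
not by imputation. Broad-sense heritabilities on a line-mean basis are

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e/r}
\qquad\text{and}\qquad
H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GY}/y + \sigma^2_e/(yr)}.$$

`fitVarianceComponents()` maximizes the restricted likelihood directly.
The residual variance is profiled out, so the search runs over log
variance *ratios* and atanh-transformed correlations — one Brent search
for the single-year iid model, a Nelder–Mead simplex with three restarts
otherwise. On balanced single-year iid data the estimates match the
classical ANOVA expected-mean-squares solutions to 1e-5 (tested), and the
iid case is cross-checked against lme4. Ratios driven to the boundary are
reported as exactly zero. Whether the single-year H² denominator should
use the spatial or iid residual variance is not determined by the formulas
themselves; both fits are available and the report states which was used.

`entryValues()` returns BLUPs (`mu + u` from the mixed-model equations,
shrunken toward the grand mean) or BLUEs (GLS with entry fixed, which
reduces to arithmetic entry means under balance). BLUPs feed the scans;
BLUEs are the unshrunken entry means for reporting.

## Genetic architecture in a biparental RIL population

Markers are filtered on MAF ≥ 0.1, missingness ≤ 30% and heterozygosity
≤ 6% (`filterMarkers()`), the standard GBS cleanup for an F5 population
where residual heterozygosity should be near $0.5^5 \approx 3\%$.

Because a biparental RIL population has neither structure nor kinship, the
association model collapses to per-marker simple regression
$y_i = \beta_{i,k} + e$ with a two-sided t-test and Bonferroni control at
$\alpha/m$ (`markerScan()`). Heterozygotes are set missing by default —
the effect of interest is the substitution between homozygote parental
classes — with midpoint coding available. The scan is closed-form
vectorized algebra, verified against `lm()` per marker.

`epistasisScan()` tests every pair of scan-significant markers with the
extra-sum-of-squares F-test of
$y_i = \alpha_{i,j} + \beta_{i,k} + \varepsilon_{i,j\cdot k} + e$ against
the additive submodel, reporting
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS_{add}}/\mathrm{RSS_{full}})$ —
the standard regression-LOD mapping, chosen because the underlying
protocol reports LOD without defining it. The Bonferroni family is the set
of tested pairs. A bimodal heading-date distribution is tested against the
3:1 early:late split that two-gene dominant epistasis predicts for inbreds
(`segregationTest()`; the proportions come from enumerating the four
equally frequent two-locus homozygote classes).

For polygenic traits with no mappable loci — the rate of heading behaves
this way — `genomicPredictionCV()` runs G-BLUP with a VanRaden
relationship matrix (centred, frequency-scaled doses), estimating the
variance ratio by eigen-decomposed REML per training fold, masking 10% of
lines for 100 replications. "Fraction of heritable genetic variance
modelled" is not a standardized quantity; we report
$\bar r^2 / H^2$, the cross-validated predictive $r$ squared against the
trait's broad-sense heritability, and flag it undefined when $H^2 \le 0$.

## What the synthetic-data generator emulates

The generator exists so every stage above is testable against known truth.
Its defaults describe the study system the package targets: 300 F5 RILs
(residual heterozygosity $0.5^g$ for $g$ selfing generations of single-seed
descent), a 21-chromosome map, crossovers per chromosome Poisson with mean
length/100 and uniform positions (Haldane, no interference — no map-model
information argues otherwise), optional segregation distortion as gametic
viability selection at one marker. Heading date is built from two
main-effect photoperiod-analogue loci plus a distal locus whose effect
reverses sign with the background (a dominant-epistasis pattern: three
two-locus classes alike, one distinct), over a polygenic tail; the rate
trait is purely polygenic by default, mirroring the empirical finding that
no large-effect rate loci are mappable. Trials are laid on a row-major
grid with separable AR1 spatial residuals; visual scores discretize the
latent curve to 10% classes and then mislabel at 10% (±1 class) and 5%
(±2 classes), clipped at the boundary classes — clipping, not reflection,
keeps the support valid. Steepness of the per-plot curve is exposed as a
parameter (`rate`, default mean 0.3/day, giving a ~2-week heading window)
rather than asserted, because its true distribution is not documented.

What it does **not** emulate: scorer drift and autocorrelated mislabels
(errors here are independent across plot-days), weather-driven gaps in the
scoring calendar, genotyping error and missingness patterns of real GBS
data (markers come out clean; the filters are exercised by separate
fixtures), multi-environment G×E beyond additive year effects, and any
image content. Passing tests therefore show the *estimators* are correct
and calibrated under the stated noise model — not that field data meet
that model.

Every stochastic operation takes an integer seed and expands it into
per-operation substreams by fixed offsets, so a single run seed makes the
whole pipeline bit-reproducible while stages stay independently rerunnable.

## Numerical choices and degenerate inputs

* Logistic fits on all-0 or all-100 series are errors (no information);
  non-convergence is a flag. Ties on the 0.1-day grid take the earliest
  day.
* Monomorphic markers get $p = 1$ and an undefined effect; perfectly
  collinear marker pairs are skipped with a flag in the epistasis scan.
* Variance ratios are optimized on the log scale, correlations on the
  atanh scale, so the optimizer never leaves the valid domain; profiling
  the residual variance removes the scale direction that makes
  variance-component likelihoods badly conditioned.
* Day-of-year is 1-based (Jan 1 = 1); plot (row, column) coordinates and
  VCF positions are 1-based at every file boundary.

## Problem sizes used in the shipped tests

The test suite simulates at the scale the estimators are meant for while
staying laptop-friendly: 50 seeded replicates of the 300-line,
420-marker scan-plus-epistasis recovery; 50 seeded 300-entry × 2-rep
variance-component recoveries; 200 plots for heading-date recovery under
the mislabel model; 200 permutations for family-wise error calibration
and 2000 draws for segregation-test calibration. Larger populations only
tighten these checks.

## Known limitations

The REML engine covers exactly the model family above — it is not a
general mixed-model language. The AR1 ⊗ AR1 covariance is built densely,
which is comfortable to a few thousand plots per year but not beyond. The
VCF reader handles biallelic GT-only records, by design. BayesA is not
implemented; G-BLUP is the shipped whole-genome model, and the
cross-validation harness accepts any predictor with the same signature.
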