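---
title: "Episodic wildfire-smoke analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episodic wildfire-smoke analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokewave)
library(dplyr)
```

smokewave analyses short, severe wildfire-smoke episodes: a few days in
which a plume dominates surface PM2.5 over a populated region. The pipeline
takes gridded daily-mean PM2.5 fields from a 2x2 factorial ensemble of
chemical-transport-model runs (two wildfire-emissions datasets x two
meteorological drivers, plus no-wildfire controls), decomposes the ensemble
spread into emissions and meteorology components, scores the fields against
monitor observations, converts the wildfire PM2.5 increment into county
health burdens via log-linear concentration-response functions, and
validates the resulting incidence rate ratios against emergency-department
(ED) visit counts. This vignette records the models, the tunable
parameters, and the design decisions; the README shows the basic workflow.

## The factorial uncertainty decomposition

The four wildfire-inclusive members are labeled by emissions dataset
(CAMS or QFED) and meteorological driver (FNL or NAM). Their cell-wise
mean is the *ensemble average*, treated as the best-estimate field and as
the denominator for relative uncertainties. The uncertainty attributable
to each factor is the signed half-sum of the paired member differences
that vary only that factor:

$$U_{\mathrm{emis}} = \tfrac{1}{2}\left[(Q_{F} - C_{F}) + (Q_{N} - C_{N})\right],
\qquad
U_{\mathrm{met}} = \tfrac{1}{2}\left[(C_{F} - C_{N}) + (Q_{F} - Q_{N})\right],$$

where $C$/$Q$ denote the CAMS/QFED members and subscripts the driver. The
subtraction order (QFED minus CAMS, FNL minus NAM) is a recorded constant,
not a parameter: reversing it only flips the sign, so exposing it as an
option would create silently incompatible outputs. For an ensemble that is
*additive* in the two factors (no interaction), each factor's field equals
the injected factor difference exactly and is invariant to the other
factor — the property the test suite asserts to machine precision.

Relative uncertainty is $100\,U/\bar{P}$ percent against the ensemble
average $\bar{P}$. Cells with $\bar{P}$ at or below a floor (default
1 µg m⁻³) are masked `NA` rather than reported: near-zero denominators
produce percentages in the thousands that say nothing about the plume.
Tabular reports round half away from zero to one decimal
(`round_half_up()`), the convention used in published uncertainty tables;
all internal arithmetic is full precision.

## Monitor-based evaluation

Monitors are joined to the grid by nearest cell center (`pair_monitors()`).
Nothing fancier is warranted: on a regular grid with uniform spacing the
nearest-center cell is the cell containing the monitor except exactly on
cell edges, and spatial interpolation would smuggle smoothing into the
evaluation. Out-of-domain sites are skipped (and listed), monitor-days with
missing values dropped with a count.

`evaluate_pairs()` pools all site-days and reports

* MB $= \overline{m - o}$ (µg m⁻³) and RMSE $= \sqrt{\overline{(m-o)^2}}$,
* NME $= 100\sum|m-o|/\sum o$ and NMB $= 100\sum(m-o)/\sum o$ (%),
* slope, intercept and $R^2$ of the OLS regression of model on
  observation.

The regression puts the model on the ordinate: evaluation asks how the
simulation responds to observed reality, and with this orientation a
low-biased model yields slope < 1 alongside a small positive MB, the
pattern evaluation tables in this field usually show. $R^2$ is the OLS
coefficient of determination (for simple OLS, the squared Pearson
correlation). Identities RMSE ≥ |MB| and NME ≥ |NMB| hold by construction
and are asserted over randomized inputs. A per-site breakdown is available
via `evaluate_pairs(pairs, by = "site_id")`; the pooled single-row summary
is the default because a short episode gives each site only a handful of
days.

## County exposure and the health-impact core

The exposure change is computed from episode means: each field is averaged
over the analysis window (`episode_mean()`), the control is subtracted
cell-wise, and the difference is aggregated to counties through a
crosswalk of non-negative cell weights that sum to one per county
(`county_exposure()`). The control is the mean of the two no-wildfire
runs by default — symmetric with the four-member wildfire average — with
any single control selectable. Crosswalk weights are *supplied*, not
derived from polygons: weight generation is GIS work that would drag heavy
dependencies into an otherwise numerical core, and regulatory
grid-to-county crosswalks ship as tables anyway.

For a county with population $\mathrm{Pop}$ and baseline incidence rate
$y_0$ (events per person per **day**), an exposure change $\Delta x$
sustained over $n$ days yields

$$\Delta Y = y_0 \,\mathrm{Pop}\,(1 - e^{-\beta \Delta x})\, n,$$

with $\beta$ the concentration-response coefficient (per µg m⁻³). Storing
$y_0$ per person-day and multiplying by the day count makes the episode
length explicit instead of burying it in the rate; `irr()` uses the same
convention for baseline events $y_0\,\mathrm{Pop}\,n$. ΔY saturates at
the baseline events as $\beta\Delta x \to \infty$ and linearizes to
$y_0\,\mathrm{Pop}\,\beta\,\Delta x\,n$ for small $\beta\Delta x$; both
limits are tested.

Uncertainty in $\beta$ propagates to ΔY by the delta method,
$\mathrm{Var}(\Delta Y) = (y_0\,\mathrm{Pop}\,\Delta x\,
e^{-\beta\Delta x}\,n)^2\,\mathrm{SE}(\beta)^2$, the default because it is
deterministic and exact to first order. A seeded Monte-Carlo mode
($\beta \sim N(\beta, \mathrm{SE})$) is provided as a cross-check; the two
agree within 5% whenever $\mathrm{SE}\cdot\Delta x < 0.05$, which the test
suite verifies. ΔY at exactly $\Delta x = 0$ has zero variance under
either method.

Aggregated over any county grouping,

$$\mathrm{IRR} = \frac{\sum \Delta Y}{\sum \mathrm{baseline\ events}} + 1,
\qquad
\mathrm{CI}_{95} = \sum \Delta Y \pm 1.96\sqrt{\textstyle\sum \mathrm{Var}},$$

with the CI bounds mapped to the ratio scale by the same
divide-and-add-one. The estimator is a ratio of sums, so it is exactly
invariant to how counties are partitioned into regions — an associativity
property the tests assert — and a normal-theory interval is appropriate
because the variance comes from the coefficient, not from Poisson noise in
the events.

The endpoint registry (`default_endpoints()`) ships four short-term PM2.5
morbidity endpoints — asthma ED visits, respiratory ED visits,
cardiovascular hospital admissions, work-loss days — whose coefficients
are *synthetic*: they are back-computed so a sustained 100 µg m⁻³ exposure
change produces ~40%, ~8%, ~15% and ~50% rate increases respectively,
realistic relative magnitudes for a severe smoke episode. No published
epidemiological coefficient is asserted anywhere in the package; real
analyses should construct `health_impact_function()`s from the literature
they intend to cite. Baseline rates may be county-specific (the default:
each county profile carries its own $y_0$) or endpoint-level via the
registry override, since either granularity is defensible and sources
differ.

## Observed IRR and validation

`observed_irr()` compares mean daily ED visits during the smoke wave with
mean daily visits over surrounding baseline days:
$\mathrm{IRR} = (\sum s / n_s)/(\sum b / n_b)$. Its 95% CI uses the
standard Poisson log rate-ratio approximation,
$\exp(\log \mathrm{IRR} \pm 1.96\sqrt{1/\sum s + 1/\sum b})$ — documented
and swappable, since exact interval conventions differ across the source
literature. The default baseline window is seven days on each side of the
episode, separated from it by a three-day buffer so that plume arrival and
clearance days contaminate neither window; both lengths are explicit
parameters because the epidemiological convention varies.

`compare_irr()` joins observed and modeled per-region IRRs and flags CI
overlap. Note the two estimators answer slightly different questions: the
observed ratio estimates $e^{\beta\Delta x}$ (rates during vs outside the
wave) while the modeled ratio is $2 - e^{-\beta\Delta x}$ (attributable
over baseline events plus one). The two agree to second order in
$\beta\Delta x$ and diverge as exposure grows; at the county exposures the
default synthetic study produces ($\beta\Delta x \lesssim 0.2$) the gap is
well inside Poisson CI widths, which is why the round-trip recovery study
(`irr_recovery_study()`) demands ≥ 90% CI coverage only for well-powered
comparisons (≥ 500 baseline events).

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defines the study: a 20 x 30 grid of 12 km cells, a
smooth ~5 µg m⁻³ background with a mild spatial gradient, and a Gaussian
plume of width 3 cells advecting 9 columns per day across the domain for
3 days starting 2023-06-06. Emissions variants scale the plume amplitude
(CAMS 0.9, QFED 1.25 — a ~30% systematic difference, consistent with the
factor-of-two spreads reported between satellite fire-emission products);
meteorology variants shift its trajectory by about a cell (FNL (0,0),
NAM (1,−1)), mimicking transport-path disagreement between drivers. The
base amplitude of 180 µg m⁻³ puts ensemble-average daily means near
190 µg m⁻³ at the core — the >100 µg m⁻³ daily means observed in major
cities during severe smoke events — and the construction guarantees the
factorial decomposition's ground truth: with equal trajectory shifts the
emissions-uncertainty field is exactly (s₂ − s₁) x plume.

Thirty monitors sit at random cell centers with Gaussian observation noise
(sd 5 µg m⁻³, truncated at zero). Twenty counties tile the grid as 5 x 6
cell blocks with equal cell weights; populations are log-uniform on
10⁵–10⁶ so region baselines accumulate several hundred events over the
14-day baseline window at the default asthma ED rate of 2.2 x 10⁻⁵ events
per person-day. The default β = −ln(0.6)/100 ≈ 5.11 x 10⁻³ per µg m⁻³
makes a 100 µg m⁻³ exposure change a 40% modeled rate increase, a
headline-magnitude smoke-wave effect; its SE of 5 x 10⁻⁴ keeps
SE·Δx < 0.05 across the domain so the delta method is trustworthy. Visit
counts are Poisson with rate $y_0\,\mathrm{Pop}\,e^{\beta\Delta x_d}$ per
region-day.

What passing tests on these data do **not** show: the generator has no
chemistry, no wind fields, no plume rise, no correlated monitor errors, no
day-of-week or seasonal structure in visits, and counties are rectangles
with equal weights. Results on real model output and administrative
records will inherit errors these simplifications cannot produce —
mistimed plumes, spatially correlated bias, baseline-rate
misspecification. The synthetic study validates the *arithmetic and
statistical machinery*, not any atmospheric model.

## Numerical and interface choices

* **Episode window.** The analysis window is a parameter everywhere
  (`days`); defaults take the field's full day axis. When text and table
  captions of a source disagree on a window (e.g. a 3-day episode cited
  against a 4-day evaluation), pick explicitly — the package does not
  guess.
* **Grid.** Row/column indices with uniformly spaced cell-center
  coordinates; no map projections. Crosswalks and monitor pairing carry
  explicit indices or nearest-center lookup, so fields from any projected
  model grid can be ingested after regridding outside the package.
* **NetCDF layout.** One file per scenario, `pm25(day,row,col)` in
  `ug m-3` (mg m⁻³ converted on read), scenario labels as global
  attributes. Validation happens on load; a negative cell or non-uniform
  axis is a refusal, not a warning.
* **Degenerate inputs.** Σobs = 0 flags the normalized metrics `NA` with a
  warning; zero baseline events, empty day selections, incomplete
  factorials, and counties without crosswalk cells are errors naming the
  offender.
* **Determinism.** Every stochastic step (monitors, populations, visit
  counts, Monte-Carlo draws) takes a seed, defaulting to the
  configuration's master seed; seeded runs are byte-reproducible, which
  `run_all()` records as per-stage MD5 checksums in its manifest.
* **Problem sizes.** The test suite runs the full pipeline on 10 x 12 to
  20 x 30 grids, 3-day episodes, 20 counties, 20-replicate recovery
  studies, and 1,000-pair evaluation oracles — sizes chosen so the whole
  suite completes in well under a minute while every code path, including
  the end-to-end workflow, is exercised.

## Known limitations

Exposure aggregation ignores within-county population distribution (the
crosswalk weight is the only spatial weighting). The health core covers
short-term morbidity only — no mortality, no long-term endpoints, no
economic valuation, no age-stratified exposed populations. The observed
IRR assumes independent Poisson counts across days; overdispersion or
day-of-week structure would widen true intervals relative to the reported
ones. And the validation comparison inherits the estimator mismatch noted
above at very large exposures ($\beta\Delta x \gtrsim 0.5$), where the
modeled ratio saturates at 2 while the observed ratio does not.
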