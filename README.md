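# smokewave

Episodic wildfire-smoke analysis in R: factorial-ensemble uncertainty
decomposition of gridded PM2.5 fields, monitor-based model evaluation, and
county-level short-term health impact assessment with incidence-rate-ratio
validation against emergency-department visit counts.

## The problem

During severe smoke episodes — a few days in which a wildfire plume
dominates surface PM2.5 over a populated region — air-quality model output
is often the only spatially continuous exposure estimate, especially in
counties without regulatory monitors. Two questions follow immediately.
How much of the simulated concentration is an artifact of the modeling
choices (which fire-emissions inventory, which meteorological driver)?
And what does the simulated exposure imply for acute health outcomes such
as asthma emergency-department (ED) visits — and can those estimates be
checked against real visit counts?

smokewave implements the full analysis chain for both questions, for
anyone post-processing a small factorial ensemble of chemical-transport
model runs (e.g. CMAQ driven by CAMS/QFED fire emissions crossed with
FNL/NAM meteorology) into exposure, uncertainty, and health-burden
estimates. A synthetic plume generator with known ground truth makes every
stage testable without any model output or restricted health records.

## The methods in brief

**Uncertainty decomposition.** With four wildfire members labeled by
emissions dataset *E* ∈ {CAMS, QFED} and driver *M* ∈ {FNL, NAM}, the
cell-wise ensemble average is the best-estimate field, and

    emis_uncertainty = 1/2 [(QFED_FNL − CAMS_FNL) + (QFED_NAM − CAMS_NAM)]
    met_uncertainty  = 1/2 [(CAMS_FNL − CAMS_NAM) + (QFED_FNL − QFED_NAM)]

isolate each factor's signed contribution; relative values are percentages
of the ensemble average.

**Evaluation.** Monitor-days are paired with the nearest grid-cell center
and scored with the standard battery: mean bias, normalized mean error,
normalized mean bias, root mean square error, and OLS slope/R² of model on
observation.

**Health impacts.** For county exposure change Δx (episode-mean scenario
minus no-wildfire control, crosswalk-weighted), baseline rate y₀ (events
per person-day), population Pop, and a log-linear concentration-response
coefficient β:

    ΔY  = y₀ · Pop · (1 − e^(−β·Δx)) · n_days
    IRR = ΣΔY / Σbaseline_events + 1,   CI₉₅ = ΣΔY ± 1.96 √(ΣVar(ΔY))

with Var(ΔY) from the delta method (seeded Monte-Carlo cross-check
included).

**Validation.** Observed IRRs from daily ED-visit counts (smoke-wave vs
baseline daily rates, Poisson log-ratio CI) are compared region-by-region
with modeled IRRs, flagging CI overlap.

## Worked example

```r
library(smokewave)

cfg <- synthetic_config(seed = 1)     # 20x30 grid, 3-day plume, 20 counties
sim <- simulate_inputs(cfg)           # ensemble + monitors + counties + visits

avg <- ensemble_average(sim$ensemble)
avg
#> <conc_field AVERAGE-AVERAGE: 3 day(s) x 20 x 30, range [5.00, 189.83] ug/m3>

factor_uncertainty(sim$ensemble, "emissions")
#> <uncertainty_field emissions: absolute range [0.00, 59.69] ug/m3, 0 masked cell(s)>

glance(evaluate_pairs(pair_monitors(avg, sim$monitors)))
#> # A tibble: 1 × 8
#>   slope intercept    r2     mb   nme   nmb  rmse n_pairs
#>   <dbl>     <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl>   <int>
#> 1 0.999    -0.663 0.991 -0.698  13.1 -2.66  4.27      90

hif <- health_impact_function("asthma_ed_visits", cfg$beta, cfg$beta_se)
exposure <- county_exposure(episode_mean(avg),
                            episode_mean(control_average(sim$ensemble)),
                            sim$crosswalk)
burden <- county_burden(exposure, sim$counties, hif, n_days = 3)
dplyr::arrange(burden, dplyr::desc(irr))[1:3, c("county_id", "delta_x",
                                                "delta_events", "irr",
                                                "ci_low", "ci_high")]
#> # A tibble: 3 × 6
#>   county_id delta_x delta_events   irr ci_low ci_high
#>   <chr>       <dbl>        <dbl> <dbl>  <dbl>   <dbl>
#> 1 C08          39.1         5.47  1.18   1.15    1.21
#> 2 C13          38.9         5.79  1.18   1.15    1.21
#> 3 C14          37.0         2.75  1.17   1.14    1.20

obs <- observed_irr(sim$visits, attr(sim$visits, "smoke_days"),
                    attr(sim$visits, "baseline_days"))
glance(compare_irr(obs, irr(burden, by = "region_id")))
#> # A tibble: 1 × 3
#>   n_regions n_overlap overlap_fraction
#>       <int>     <int>            <dbl>
#> 1         4         4                1
```

Reading it: the evaluation slope ≈ 1 and MB ≈ −0.7 µg m⁻³ say the
ensemble-average field tracks the (noisy) monitors almost perfectly, as it
must on synthetic truth-plus-noise data. The plume-core counties show
3-day mean exposure increments near 40 µg m⁻³ and modeled IRRs around
1.18 — an 18% increase in asthma ED visits — and in all four regions the
modeled IRR falls inside the 95% CI of the IRR observed in the simulated
visit counts.

Every result object is a tibble or has `as_tibble()`/`tidy()`/`glance()`
methods, and `autoplot()` draws fields, uncertainty maps and
observed-vs-modeled forest plots. `run_all(cfg, out_dir)` executes the
whole chain (simulate → evaluate → uncertainty → health → validate) with a
JSON run manifest; `inst/cli/smokewave.R` exposes the same stages as shell
subcommands.

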