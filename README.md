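# revisit

Foraging-site revisitation analysis for GPS telemetry. Given hourly fixes
of tracked animals in a projected (metre) coordinate system, `revisit`

1. **detects revisited sites** by moving-circle recursion: one candidate
   site per fix, visits = maximal in-circle intervals of the interpolated
   track, merged when the animal is away for less than a minimum time
   (default 12 h), with the circle radius chosen where the across-site
   variance of visit counts peaks (candidates 100–500 m; default 250 m);
2. **tests non-randomness of site placement** against availability:
   complete-spatial-randomness points inside an a-LoCoH home range
   (isopleth 1, 500 m water buffer excluded), compared covariate by
   covariate with a two-sample Kolmogorov test repeated 10,000 times on
   100-vs-100 subsamples (mean ± SD of *D* and *p*), so the verdict does
   not ride on an enormous *n*;
3. **models the revisitation rate** — visits per seasonal (NDVI wet/dry)
   period — as lognormal: per-variable quadratic regressions on
   1000-bin means, then per sex × season stratum a random-intercept mixed
   model on scaled covariates, selected backwards by AIC with a 2-ΔAIC
   parsimony rule, allow-listed interactions, stratified resampling, and
   Nakagawa–Schielzeth marginal/conditional R².

Because collar data of endangered species are routinely withheld, the
package ships a seeded **synthetic-study generator**: smooth covariate
rasters with a controllable phosphorus–nitrogen correlation, a river and
waterholes, NDVI seasonality, and hotspot-attraction trajectories whose
attractiveness is a planted log-linear (with quadratic terms) function of
the transformed covariates. Every pipeline stage is validated against that
known truth; see `vignettes/revisitation-methods.Rmd` for the model,
conventions and limitations.

## Core model

For site *i* of individual *j* in season *s*, the response is the log
revisitation rate, and the stratum-level model is

    log(rate_ij) = beta0 + Σ_k beta_k z(x_k) + Σ_k gamma_k z(x_k)^2
                   [+ allow-listed interactions] + alpha_j + eps_ij
    alpha_j ~ N(0, sigma_alpha^2),  eps_ij ~ N(0, sigma_eps^2)

with covariates √distance-to-water, EVI, phosphorus, day temperature and
log1p slope (nitrogen leaves via the |r| > 0.5 collinearity screen;
precipitation is exploratory only). Marginal and conditional R² are
`Rm2 = sf²/(sf²+sa²+se²)` and `Rc2 = (sf²+sa²)/(sf²+sa²+se²)` where `sf²`
is the variance of the fixed-effect predictor.

## Worked example

```r
library(revisit)

cfg    <- studyConfig(nIndividuals = 5, nBulls = 3, durationYears = 1, seed = 1)
bundle <- genStudy(cfg)           # trajectories + rasters + water + truth

selectRadius(bundle$trajectories, recursionConfig())
#> [1] 200
#> attr(,"variances")
#>      100      200      250      300      400      500
#> 256.2317 292.6949 279.1855 256.9936 213.6428 181.1760   (per-seed values vary)

report <- runPipeline(bundle, pipelineConfig(availabilityN = 3000,
                                             ksIter = 500, nRep = 50, seed = 1))
#> [detect] sites=43800 visits=1130925
#> [water_filter] kept=41592 removed=2208
#> [seasons] years=1 fallback=0
#> [home_range] hulls=1 areaKm2=77.2558322908274
#> [correlation_screen] dropped=nitrogen
#> ...
report
#> runReport
#>   radius 250 m; 82540 site-season records; 3000 availability points
#>   24 KS tests, 24 binned regressions, 4 model strata
#>   [cow.dry] dw + dw:phos + evi + evi:phos + evi:slope + I(dw^2) +
#>             I(evi^2) + I(phos^2) + I(temperature^2) + phos + slope +
#>             temperature | Rm2 0.403 Rc2 0.404
```

Reading the output: 43,800 fixes become candidate sites; 2,208 fall inside
the 500 m water buffer. The chosen cow/dry-season model keeps phosphorus
with a negative quadratic coefficient — the hump-shaped phosphorus
preference the generator planted — and the marginal R² (fixed effects
only) is 0.40 against a conditional 0.40 including between-individual
variation. `writeReport(report, "out/")` serialises the
same numbers to JSON and CSV.

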