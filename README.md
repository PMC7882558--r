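# climpaths

Climate shapes the population dynamics of long-distance migratory birds at
every stage of the annual cycle — on the breeding grounds, along the
migration route, and in the non-breeding range — and it does so through
multiple paths: directly, and indirectly through the timing of breeding,
clutch size, and fledgling production. `climpaths` is an R package for
ecologists who want to trace those paths in long nest-box survey series. It
implements, end to end:

1. **Sliding-window climate signal detection.** For each site and climate
   variable, every contiguous run of months up to 12 months before a June
   anchor (91 candidate windows) is aggregated and scored against an annual
   response by ΔAICc relative to the no-climate null. The scan is
   deterministic and deliberately exploratory: it ranks, you choose.
2. **A Bayesian residual dynamic structural equation model (RDSEM)** for
   annual population growth rate `R_t = ln N_t − ln N_{t−1}`, where `N_t` is
   the density index (% of Parid-free nest boxes occupied):

   ```
   R_t     = α_R + β_N·N_{t−1} + β_F1·F_{t−1} + β_F2·F_{t−2}
             + β_M·MedTemp_t + β_E·EurPrecip_t + β_A·AfrPrecip_{t−1} + ε_t
   N_{t−1} = α_N + γ·F_{t−2} + δ_{t−1}
   ```

   with autoregressive residuals `ε_t = Σ φ_k ε_{t−k} + u_t` (candidate lags
   1–3, pruned until every retained AR term's 95% interval excludes zero)
   and the indirect effect of `F_{t−2}` via density computed per posterior
   draw.
3. **A Bayesian two-level SEM (MSEM)** for nest-level fledgling production
   with latent group-mean centering: within years, fledglings respond to
   clutch size and to nestling-period temperature, precipitation and their
   interaction; between years, latent annual means of fledglings, clutch
   size and hatch date respond to winter-temperature windows in Europe and
   Africa, with full total/direct/indirect effect decomposition and simple
   slopes of the weather interaction.
4. **A forward simulator** (`gen_full_dataset()` and friends) that generates
   all three input tables — 77-year occupancy series with density
   dependence and AR-correlated residuals, tens of nests per year with the
   full within/between covariance structure, monthly climate with planted
   window effects — parameterised by default at the fitted models' posterior
   medians, so every fitting routine is validated by parameter recovery.

All samplers are seeded conjugate-block Gibbs implementations (no external
MCMC engine); everything takes and returns tidy tibbles, with
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a full 77-year study, fit the growth-rate model with AR pruning,
and decompose effects (seed 42 throughout; your numbers will match):

```r
library(climpaths)
library(dplyr)

cfg <- generator_config(seed = 42)
dat <- gen_full_dataset(cfg)          # climate, counts, nests, annual series

fit <- prune_ar_terms(build_rdsem(dat$series), seed = 42)
tidy(fit) |> filter(grepl("^growth_(med|density|fled|ar)", term))
#>   term                     median ci_lower  ci_upper n_draws  rhat nonzero
#> 1 growth_density_lag1    -0.00221 -0.00366 -0.000627    1000 1     TRUE
#> 2 growth_fled_lag1        0.0148  -0.00964  0.0399      1000 0.999 FALSE
#> 3 growth_fled_lag2        0.00349 -0.0223   0.0292      1000 0.998 FALSE
#> 4 growth_med_winter_temp -0.0208  -0.0348  -0.00683     1000 0.999 TRUE
#> 5 growth_ar2              0.399    0.174    0.646       1000 0.999 TRUE
```

Density dependence is recovered (each extra percentage point of last year's
occupancy lowers log growth by ~0.002, interval excluding zero), as are the
negative Mediterranean winter-temperature effect (−0.021 per °C) and the
planted second-order residual autocorrelation (0.399): pruning dropped the
four unsupported AR terms and kept exactly the one the simulator planted.
The fledgling effects are weakly identified in a single 77-year realisation
— their intervals cover zero, which is the honest answer at this n.

```r
fledgling_lag2_effects(fit)
#>   effect     median ci_lower ci_upper
#> 1 direct    0.00349  -0.0223 0.0292
#> 2 indirect -0.00527  -0.0157 0.000373
#> 3 total    -0.00212  -0.0291 0.0252
```

The indirect effect (fledglings two seasons back → next year's density →
growth) is the per-draw *product* of the two path draws; its median is not
the product of the path medians.

The nest-level model, on the same simulated study:

```r
mfit <- fit_msem(build_msem(dat$nests, dat$between), seed = 42)
within_total_hatch_effect(mfit)
#>   term               median ci_lower ci_upper
#> 1 within_hatch_total -0.0431  -0.0523  -0.0334
```

Within years, each day of delayed hatching costs about 0.043 fledglings,
entirely through smaller clutches (the product of the hatch→clutch and
clutch→fledglings paths, summarised per draw). `decompose_effects(mfit)`
gives the between-level total/direct/indirect table for the two
winter-temperature windows and hatch date, and `simple_slopes(mfit)` the
temperature slope at precipitation percentiles {10, 25, 50, 75, 90}.

To run everything — scan included — from one object:

```r
out <- run_pipeline(pipeline_config(
  generator = cfg,
  selected_windows = climpaths:::default_selected_windows(),
  out_dir = "report", seed = 42
))
```

which writes the annual series, both window-scan tables, the selected
windows, both model summaries, the effect decompositions, simple slopes,
and a convergence report as CSVs.

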