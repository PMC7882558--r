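---
title: "Models and methods: climate paths to population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: climate paths to population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`climpaths` implements a three-stage analysis of how climate along a
migratory songbird's annual cycle shapes its breeding population dynamics,
together with a forward simulator that reproduces the statistical structure
the models assume. This vignette describes the models, the tunable
parameters and their defaults, the numerical choices, and what validation on
simulated data does and does not establish.

## The data and derived annual variables

Three tables drive everything.

* **Annual nest-box counts**: boxes surveyed, boxes occupied by the focal
  species, boxes occupied by Parids (tits compete for the same boxes). The
  population density index is the percentage of boxes *available* to the
  focal species that it occupied,
  \(N_t = 100\,\mathrm{focal}_t / (\mathrm{surveyed}_t - \mathrm{parid}_t)\),
  and the annual growth rate is the natural-log difference
  \(R_t = \ln N_t - \ln N_{t-1}\). \(R_t\) is defined only for consecutive
  observed years; survey gaps propagate as missing values, never bridged.
  Two overlapping study areas are merged with an explicit preference rule
  (`merge_series()`), keeping the record of the larger study in overlap
  years.
* **Nest records**: one row per first breeding attempt — hatch date (integer
  days, day 1 = April 1 by default, so an intercept near 69 is early–mid
  June), clutch size, fledgling count, and nestling-period weather (mean
  daily temperature and precipitation sum over the 14 days from hatching,
  inclusive).
* **Monthly climate**: mean temperature (°C) and precipitation (mm/month)
  for ten sites along the annual cycle — breeding grounds and northern
  migration corridor ("Europe"), Mediterranean stopover region, and
  sub-Saharan non-breeding region ("Africa").

## Stage 1: sliding-window scan

For each site and climate variable, every contiguous run of months up to 12
months before a June reference anchor is a candidate predictor: the window
opening `open_lag` and closing `close_lag` months back, with
\(0 \le \mathrm{close} \le \mathrm{open} \le 12\). Thirteen monthly anchors
give \(13 \cdot 14/2 = 91\) windows. Note the deliberate off-by-one: a
12-month look-back ("July of the previous year through June") has 12
anchors, but 91 windows force 13, so lag 12 reaches June of the previous
year. We follow the 91-window convention and document it here.

Each window's monthly values are aggregated (mean by default; sums by flag)
and regressed against the annual response by ordinary least squares. The
comparison statistic is ΔAICc — the small-sample-corrected AIC of the
window model (three parameters: intercept, slope, variance) minus that of
the intercept-only null (two parameters) fitted to the same years. AICc
rather than AIC is the default because the series is short (n ≈ 77);
plain AIC is available via `criterion = "aic"`. Ties are broken toward
shorter, then more recent windows.

The scan is deterministic and *exploratory*: with 91 correlated candidates
per site/variable, the best ΔAICc is optimistically biased. `run_pipeline()`
therefore refuses to feed scan winners into the structural models unless the
windows are named explicitly or automatic selection is acknowledged with
`auto_select = TRUE`.

## Stage 2: growth-rate model (RDSEM)

The residual dynamic structural equation model separates structural
associations from serial correlation by letting the *residuals* of the
endogenous variables follow autoregressive processes:

\[
\begin{aligned}
R_t &= \alpha_R + \beta_N N_{t-1} + \beta_{F1} F_{t-1} + \beta_{F2} F_{t-2}
      + \beta_M \mathrm{MedT}_t + \beta_E \mathrm{EurP}_t
      + \beta_A \mathrm{AfrP}_{t-1} + \varepsilon_t,
      & \varepsilon_t &= \textstyle\sum_k \phi^R_k \varepsilon_{t-k} + u_t,\\
N_{t-1} &= \alpha_N + \gamma F_{t-2} + \delta_{t-1},
      & \delta_s &= \textstyle\sum_k \phi^N_k \delta_{s-k} + v_s,
\end{aligned}
\]

with \(u_t \sim N(0,\sigma^2_R)\), \(v_s \sim N(0,\sigma^2_N)\), and free
means/variances for the exogenous fledgling covariates \(F_{t-1}, F_{t-2}\)
(annual means of fledglings per nest). The three climate covariates enter
uncentered on natural scales (°C, mm) so coefficients keep their
per-degree / per-millimetre units. Because the density index is observed,
the joint posterior factorises over the two equations, and each is fitted
with the shared AR-regression Gibbs sampler.

**AR pruning.** Both residual processes start with candidate lags 1–3. After
each fit, the AR term whose posterior most widely overlaps zero (largest
two-sided tail mass across zero) is dropped and the system refitted, until
every retained AR term's 95% interval excludes zero. Structural paths are
never pruning candidates. The retained structure is a procedure outcome,
not an assumption.

**Effect decomposition.** Fledgling production two seasons back has a direct
path to growth and an indirect path via the next season's density. Both are
computed per posterior draw — the indirect effect as the product of the two
path draws, the total as their sum with the direct draw — and only then
summarised. The median of a product is not the product of medians, which is
why a summary built from per-draw products can differ in the third decimal
from arithmetic on printed path medians; the degenerate-draw identities are
what the exact tests check.

## Stage 3: nest-production model (MSEM)

Nest-level fledgling production is modelled at two levels with **latent
group-mean centering**: each within-year variable is split into a latent
year mean (the random intercept) and a within-year deviation, and the
between-year regressions act on the latent means. Observed-mean centering
is biased at finite cluster sizes and is available only as a fallback in
the generic `sample_twolevel()`.

Within year \(j\), for nest \(i\):
\[
\begin{aligned}
\mathrm{clutch}_{ij} &= C_j + b_h\,(\mathrm{hatch}_{ij} - H_j) + e^c_{ij},\\
\mathrm{fled}_{ij} &= L_j + b_t\,\tilde t_{ij} + b_p\,\tilde p_{ij}
  + b_{tp}\,\tilde t_{ij}\tilde p_{ij}
  + b_c\,(\mathrm{clutch}_{ij} - C_j) + e^f_{ij},
\end{aligned}
\]
where \(\tilde t, \tilde p\) are latent-centered nest-weather deviations
with a free 2×2 covariance. Between years, the latent means follow
\[
\begin{aligned}
H_j &\sim N(\alpha_h + h_E E_j + h_A A_j,\ \tau^2_h),\\
C_j &\sim N(\alpha_c + c_H H_j + c_E E_j + c_A A_j,\ \tau^2_c),\\
L_j &\sim N(\alpha_f + f_C C_j + f_T T_j + f_P P_j + f_E E_j + f_A A_j,\ \tau^2_f),
\end{aligned}
\]
with \(E_j, A_j\) the European February and African November temperature
windows and \(T_j, P_j\) the latent year means of nestling weather
(estimated with free means and covariance). Hatch date reaches fledglings
only through clutch size; the alternative with a free direct
hatch-to-fledglings between path (whose printed decomposition shows none)
is available via `hatch_direct = TRUE`. Fledgling counts are treated as
Gaussian at both levels — the linear-SEM treatment; no count likelihood is
offered.

`decompose_effects()` reports total/direct/indirect effects of the two
winter-temperature windows and hatch date, per draw as above.
`simple_slopes()` evaluates the moderated temperature slope
\(b_t + b_{tp}\,\tilde p\) at percentiles of the observed within-year
precipitation deviations (the centering offset is zero on the latent
scale; the raw-scale percentile is reported alongside).

## The samplers

Both models use seeded conjugate-block Gibbs samplers written for this
package:

* regression coefficients given AR terms by quasi-differenced least squares;
* AR coefficients given residuals by regressing residuals on their lags
  (conditioning on the first \(\max(\mathrm{lag})\) observations of each
  contiguous segment; rows with missing covariates break the series into
  segments and are excluded with a message);
* variances from inverse-gamma, 2×2 covariance blocks from inverse-Wishart;
* latent year means from their Gaussian full conditionals, vectorised over
  clusters;
* missing responses imputed each sweep from their full conditional under
  the AR structure.

Priors default to Normal(0, 10⁶) on coefficients (no stationarity
truncation on AR terms), Inverse-Gamma(0.001, 0.001) on variances, and a
weak inverse-Wishart (df 3, scale 0.001·I) on covariance blocks — all
configurable through `default_priors()`. Sensitivity to these diffuse
choices is the user's to probe by refitting; nothing in the package assumes
it away. Two chains with dispersed initial values are run by default, the
first half of each discarded as warm-up, and convergence is summarised by
the split-chain potential scale reduction factor with a `converged` flag at
the conventional 1.05 threshold. Fixed seeds give bit-identical draws.

Correctness is established by oracle equivalence rather than by trusting
the algorithm: with flat priors and no AR terms the posterior matches
ordinary least squares; AR coefficients on long series match exact ML
(`stats::arima`); the two-level sampler matches a random-intercept fit
(`lme4`) where the models coincide; nominal 95% intervals cover generating
values at close to nominal rate across replicates.

## The forward simulator

`generator_config()` fixes the study conditions: 77 breeding seasons,
Poisson(85) nests per year (minimum 10), and structural truth equal to the
fitted posterior medians of both models, so that parameter recovery targets
those published values directly. Climate is a per-site seasonal sinusoid
plus independent Gaussian monthly anomalies; designated windows (December–
January Mediterranean temperature, September–October African precipitation,
January–April European precipitation, February European temperature,
November African temperature) are aggregated from the generated monthly
table itself, so the scan and the fitters consume exactly what the
structural equations consumed.

Choices worth knowing:

* **Anomaly scales.** Year-to-year SDs of the designated window aggregates
  are set from climatology: 1.3 °C (Mediterranean winter), 10 mm (European
  spring precipitation), 35 mm (African autumn precipitation), 2.2 °C
  (European February), 0.5 °C (African November — interannual temperature
  variation in the humid tropics is small, so simulated values stay within
  about ±1 °C of their mean).
* **Derived intercepts.** Printed slopes, AR coefficients and variances are
  used verbatim as truth, but printed intercepts are not mutually coherent
  with any realistic climate means (they absorb the unpublished covariate
  scales of the original data). The generator therefore derives the growth,
  hatch-date and fledgling intercepts so that simulated grand means are
  coherent (mean growth ≈ 0, hatch day ≈ 69, fledglings ≈ 4.36); every
  derived value is recorded in the truth manifest.
* **Growth is simulated from its structural equation**, not as the
  log-difference of the simulated density series — the model treats the two
  as separate endogenous variables, and recomputing one from the other
  would destroy the planted regression structure. Occupancy counts *are*
  reverse-engineered from the density index, so the data-preparation stage
  round-trips it exactly up to integer rounding.
* **Residual-variance convention.** Printed AR residual variances are taken
  as innovation variances (the white-noise shock); `ar_variance =
  "marginal"` switches to stationary-variance scaling, and the manifest
  records which was used.
* **Realism modes.** `"gaussian"` draws every variable from the exact model
  likelihood — the mode used for recovery studies, since it introduces no
  clamping bias. `"clamped"` rounds counts, clips fledglings to
  `[0, clutch]`, floors precipitation at zero and keeps the density index
  in (0, 100] by reflection; it looks like field data but biases the
  boundary-adjacent parameters slightly, which is why recovery is never
  scored in clamped mode.

## What the validation shows — and what it does not

The package's primary validation surface is the generator→fitter round
trip: simulate at the published posterior medians, refit, and compare. At
the study's own scale (77 years; ~85 nests/year) the structural slopes of
both models are recovered to within Monte-Carlo error across replicates,
and interval coverage is close to nominal. Two honest caveats:

* **AR small-sample bias.** Posterior medians of autoregressive
  coefficients at n = 77 are biased toward zero by O(1/n); the planted
  growth AR(2) of 0.415 is recovered around 0.36–0.40 on average
  (conditioning on the pruning procedure retaining the term offsets part of
  the bias). Exact ML on pure AR(2) series of this length shows the same
  shortfall, so this is a property of the estimator at this series length,
  not of the implementation.
* **Synthetic ≠ field data.** The generator reproduces the *assumed*
  covariance structure — Gaussian errors, linear paths, independent
  anomalies across sites, no observation error in counts, no dispersal.
  Passing recovery tests therefore validates the estimation machinery, not
  the substantive claims about real flycatchers; with the original field
  data unavailable, coefficient estimates on real data are out of reach by
  construction.

Problem sizes used in the shipped experiments — 40 replicates for the
growth model, 30 for the nest model, with 2 chains × 1000–1500 iterations —
were chosen so each recovery mean's Monte-Carlo error is well below the
effects being recovered; all are configurable.

## Known limitations

* Gaussian likelihoods only; fledgling counts are not modelled as counts.
* Missing covariates are excluded (breaking the residual series) rather
  than imputed; only missing responses are imputed.
* The two fitted models are not joined into one system (an annual response
  cannot receive indirect effects from nest-level predictors), mirroring
  the staged analysis they implement.
* The scan implements no randomisation test against overfitting; it is
  exploratory by design and the pipeline treats it that way.
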