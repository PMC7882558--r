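#' Configuration for the forward simulator
#'
#' Bundles every quantity the simulator needs: study dimensions, the
#' structural truth for the annual growth model and the nest-production
#' model (defaulting to the fitted posterior medians so that parameter
#' recovery targets those values), and a simple climate process (per-site
#' seasonal curve plus independent monthly anomalies) with designated
#' "true" windows that feed the structural equations.
#'
#' Structural intercepts are derived internally so that simulated grand
#' means are coherent with the designated climate climatology (mean growth
#' rate near zero, mean fledgling production near its long-run value); the
#' derived values are recorded in the truth manifest.
#'
#' @param n_years Length of the simulated study (default 77 seasons).
#' @param start_year First breeding year.
#' @param nests_per_year Mean of the Poisson number of nests per year
#'   (truncated below at `nests_min`).
#' @param nests_min Minimum nests in any year.
#' @param realism_mode `"gaussian"` draws every variable from the exact
#'   model likelihood (no clamping bias — use this for recovery studies);
#'   `"clamped"` rounds counts, clips fledglings to `[0, clutch]`, keeps
#'   the density index in (0, 100] by reflection, and floors precipitation
#'   at zero.
#' @param ar_variance Whether autoregressive residual variances in the
#'   truth are `"innovation"` variances (variance of the white-noise shock;
#'   default, matching the fitted model's parameterisation) or `"marginal"`
#'   variances of the stationary residual process.
#' @param boxes_surveyed,parid_rate Nest-box totals used to back-compute
#'   occupancy counts from the simulated density index.
#' @param seed Integer seed (mandatory; all `gen_*` functions default to it).
#' @param rdsem_truth,msem_truth,sites,windows Optional overrides of the
#'   default truth lists and climate tables (see the fitted-model vignette).
#' @return A list of class `climpaths_config`.
#' @export
generator_config <- function(n_years = 77, start_year = 1942,
                             nests_per_year = 85, nests_min = 10,
                             realism_mode = c("gaussian", "clamped"),
                             ar_variance = c("innovation", "marginal"),
                             boxes_surveyed = 375, parid_rate = 0.15,
                             seed = 1, rdsem_truth = NULL, msem_truth = NULL,
                             sites = NULL, windows = NULL) {
  cfg <- list(
    n_years = n_years, start_year = start_year,
    nests_per_year = nests_per_year, nests_min = nests_min,
    realism_mode = match.arg(realism_mode),
    ar_variance = match.arg(ar_variance),
    boxes_surveyed = boxes_surveyed, parid_rate = parid_rate,
    seed = seed,
    rdsem_truth = rdsem_truth %||% default_rdsem_truth(),
    msem_truth = msem_truth %||% default_msem_truth(),
    sites = sites %||% default_sites(),
    windows = windows %||% default_windows()
  )
  structure(cfg, class = "climpaths_config")
}

# Structural truth for the annual growth model (posterior medians of the
# fitted model; residual variances are AR innovation variances by default).
default_rdsem_truth <- function() {
  list(
    growth = list(
      density = -0.003, fled1 = 0.028, fled2 = -0.004,
      med_winter_temp = -0.025, eur_spring_precip = -0.00161,
      afr_autumn_precip = -0.00066,
      ar = c("2" = 0.415), resid_var = 0.006
    ),
    density = list(
      intercept = 40.673, fled2 = 4.34,
      ar = c("1" = 0.565, "2" = 0.257), resid_var = 115.6
    ),
    fledglings = list(mean = 4.36, var = 0.702)
  )
}

# Structural truth for the nest-production model.
default_msem_truth <- function() {
  list(
    within = list(
      fled = c(nest_temp = -0.009, nest_precip = -0.002,
               temp_x_precip = 0.0044, clutch = 0.695),
      fled_resid_var = 2.98,
      clutch_hatch = -0.058, clutch_resid_var = 0.58,
      hatch_var = 2.35,
      weather_cov = matrix(c(0.994, -0.023, -0.023, 16.02), 2, 2)
    ),
    between = list(
      hatch = c(eur_winter_temp = -0.003, afr_winter_temp = -0.048),
      hatch_resid_var = 0.80, hatch_mean = 69.07,
      clutch_intercept = 8.89,
      clutch = c(hatch = -0.037, eur_winter_temp = -0.013,
                 afr_winter_temp = 0.019),
      clutch_resid_var = 0.011,
      fled = c(clutch = 1.489, nest_temp = 0.058, nest_precip = 0.006,
               eur_winter_temp = -0.071, afr_winter_temp = 0.670),
      fled_resid_var = 0.166, fled_mean = 4.36,
      weather_mean = c(nest_temp = 15.11, nest_precip = 27.35),
      weather_cov = matrix(c(3.46, -0.057, -0.057, 30.99), 2, 2)
    )
  )
}

# Ten sites along the annual cycle: breeding/European, Mediterranean
# migration corridor, and sub-Saharan non-breeding region. `temp_sd` /
# `precip_sd` are SDs of independent monthly anomalies, chosen so the
# designated window aggregates have climatologically sensible year-to-year
# spread (e.g. African temperatures vary much less than European ones).
default_sites <- function() {
  tibble::tribble(
    ~site,       ~region,         ~temp_mean, ~temp_amp, ~temp_sd, ~precip_mean, ~precip_amp, ~precip_sd,
    "laitila",   "europe",          5.0, 11.0, 1.5,  55, 20, 20,
    "hamburg",   "europe",          9.0,  8.5, 2.0,  60, 15, 20,
    "frankfurt", "europe",         10.0,  9.0, 2.2,  55, 15, 20,
    "lyon",      "europe",         12.0,  9.0, 1.8,  65, 20, 22,
    "zaragoza",  "mediterranean",  15.0,  9.0, 1.6,  35, 12, 15,
    "malaga",    "mediterranean",  18.0,  7.0, 1.838, 45, 25, 18,
    "rabat",     "mediterranean",  17.5,  5.0, 1.5,  45, 30, 18,
    "kenema",    "africa",         26.0,  1.5, 0.5, 160, 120, 40,
    "nimba",     "africa",         25.0,  1.5, 0.6, 140, 100, 40,
    "gagnoa",    "africa",         26.5,  1.2, 0.6, 135,  90, 49.5
  )
}

# The windows through which simulated climate drives the structural
# equations (lags in months before June of the breeding year).
default_windows <- function() {
  tibble::tribble(
    ~role,               ~site,       ~variable,       ~open_lag, ~close_lag,
    "med_winter_temp",   "malaga",    "temperature",    6L, 5L, # Dec-Jan
    "eur_spring_precip", "hamburg",   "precipitation",  5L, 2L, # Jan-Apr
    "afr_autumn_precip", "gagnoa",    "precipitation",  9L, 8L, # Sep-Oct, prev yr
    "eur_winter_temp",   "frankfurt", "temperature",    4L, 4L, # Feb
    "afr_winter_temp",   "kenema",    "temperature",    7L, 7L  # Nov, prev yr
  )
}

# Deterministic seasonal value (no anomaly) for one site/month.
seasonal_value <- function(sites, site, variable, month) {
  row <- sites[sites$site == site, ]
  if (variable == "temperature") {
    row$temp_mean + row$temp_amp * cos(2 * pi * (month - 7) / 12)
  } else {
    row$precip_mean + row$precip_amp * cos(2 * pi * (month - 9) / 12)
  }
}

# Climatological mean of a designated window aggregate.
window_climatology <- function(config, role, reference_month = 6L) {
  w <- config$windows[config$windows$role == role, ]
  months <- window_months(w$open_lag, w$close_lag, 2000L, reference_month)$month
  mean(vapply(months, function(m) {
    seasonal_value(config$sites, w$site, w$variable, m)
  }, numeric(1)))
}

# Aggregate the designated windows over a climate table for given years.
role_aggregates <- function(config, climate, years) {
  out <- tibble::tibble(year = years)
  for (i in seq_len(nrow(config$windows))) {
    w <- config$windows[i, ]
    agg <- aggregate_window(climate, w$site, w$variable, w$open_lag,
                            w$close_lag, years = years)
    out[[w$role]] <- agg$value
  }
  out
}

#' Simulate the monthly climate table
#'
#' Each site/variable follows a deterministic seasonal sinusoid plus
#' independent Gaussian monthly anomalies. Climate is generated from the
#' year before the study starts so that all backward-looking windows exist
#' for the first breeding season.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return Monthly climate tibble (`site`, `year`, `month`, `temperature`,
#'   `precipitation`).
#' @export
gen_monthly_climate <- function(config, seed = config$seed) {
  set.seed(seed)
  years <- (config$start_year - 1):(config$start_year + config$n_years - 1)
  grid <- tidyr::expand_grid(site = config$sites$site, year = years,
                             month = 1:12)
  grid <- dplyr::left_join(grid, config$sites, by = "site")
  n <- nrow(grid)
  temp <- grid$temp_mean + grid$temp_amp * cos(2 * pi * (grid$month - 7) / 12) +
    rnorm(n, 0, grid$temp_sd)
  precip <- grid$precip_mean +
    grid$precip_amp * cos(2 * pi * (grid$month - 9) / 12) +
    rnorm(n, 0, grid$precip_sd)
  if (config$realism_mode == "clamped") precip <- pmax(precip, 0)
  tibble::tibble(site = grid$site, year = grid$year, month = grid$month,
                 temperature = temp, precipitation = precip)
}

# Simulate a stationary AR process with given lag coefficients, returning
# n values after a burn-in. `resid_var` is interpreted per config.
sim_ar <- function(n, ar, resid_var, ar_variance, burn = 100) {
  lags <- as.integer(names(ar))
  p <- if (length(lags)) max(lags) else 0L
  innov_var <- resid_var
  if (ar_variance == "marginal" && length(lags)) {
    # scale innovations so the stationary variance equals resid_var
    phi_full <- rep(0, p)
    phi_full[lags] <- ar
    innov_var <- resid_var * marginal_to_innovation(phi_full)
  }
  e <- numeric(n + burn)
  u <- rnorm(n + burn, 0, sqrt(innov_var))
  for (t in seq_len(n + burn)) {
    val <- u[t]
    for (j in seq_along(lags)) {
      if (t > lags[j]) val <- val + ar[j] * e[t - lags[j]]
    }
    e[t] <- val
  }
  tail(e, n)
}

# Ratio innovation/marginal variance for an AR(p) process.
marginal_to_innovation <- function(phi) {
  p <- length(phi)
  acfs <- ARMAacf(ar = phi, lag.max = p)
  1 - sum(phi * acfs[-1])
}

#' Simulate the annual population series
#'
#' Iterates the two structural equations forward on their natural scales:
#' the density index responds to fledgling production of the previous
#' season with AR(1)+AR(2) residuals, and the annual growth rate responds
#' to previous density, fledgling production one and two seasons back, and
#' the three designated climate windows, with an AR(2) residual. The growth
#' intercept is derived so long-run mean growth is zero under the climate
#' climatology; the density intercept is the fitted value. Occupancy counts
#' are back-computed from the density index so the data-preparation stage
#' reproduces it.
#'
#' The growth rate is simulated directly from its structural equation (it
#' is a response variable of the model, not recomputed as the
#' log-difference of the simulated density series).
#'
#' @param config A [generator_config()].
#' @param climate Optional monthly climate table (generated if omitted).
#' @param fledglings Optional tibble (`year`, `value`) of annual mean
#'   fledgling production to drive the equations (e.g. nest-table means);
#'   years not covered are simulated from the truth mean/variance.
#' @param seed Seed.
#' @return List: `series` (annual tibble with density, growth, fledgling
#'   means and the three window aggregates; two pre-study rows carry the
#'   lagged history), `counts` (occupancy counts), `manifest` (truth).
#' @export
gen_population_series <- function(config, climate = NULL,
                                  fledglings = NULL, seed = config$seed) {
  if (is.null(climate)) climate <- gen_monthly_climate(config, seed = seed)
  set.seed(seed + 1L)
  tr <- config$rdsem_truth
  start <- config$start_year
  end <- start + config$n_years - 1L
  years_all <- (start - 2L):end

  f <- rnorm(length(years_all), tr$fledglings$mean, sqrt(tr$fledglings$var))
  names(f) <- years_all
  if (!is.null(fledglings)) {
    hit <- as.character(fledglings$year)
    f[hit[hit %in% names(f)]] <-
      fledglings$value[hit %in% names(f)]
  }

  # density index: years (start-1)..end
  yrs_n <- (start - 1L):end
  delta <- sim_ar(length(yrs_n), tr$density$ar, tr$density$resid_var,
                  config$ar_variance)
  nt <- tr$density$intercept +
    tr$density$fled2 * f[as.character(yrs_n - 1L)] + delta
  if (config$realism_mode == "clamped") {
    nt <- abs(nt)                       # reflect at 0
    nt <- ifelse(nt > 100, 200 - nt, nt) # reflect at 100
    nt <- pmin(pmax(nt, 1e-3), 100)
  } else if (any(nt <= 0 | nt > 100)) {
    warn("simulated density index outside (0, 100] in gaussian mode")
  }
  names(nt) <- yrs_n

  yrs <- start:end
  agg <- role_aggregates(config, climate, yrs)
  g <- tr$growth
  clim_mean <- c(
    med_winter_temp = window_climatology(config, "med_winter_temp"),
    eur_spring_precip = window_climatology(config, "eur_spring_precip"),
    afr_autumn_precip = window_climatology(config, "afr_autumn_precip")
  )
  e_density <- tr$density$intercept + tr$density$fled2 * tr$fledglings$mean
  growth_intercept <- -(g$density * e_density +
                          (g$fled1 + g$fled2) * tr$fledglings$mean +
                          g$med_winter_temp * clim_mean[["med_winter_temp"]] +
                          g$eur_spring_precip * clim_mean[["eur_spring_precip"]] +
                          g$afr_autumn_precip * clim_mean[["afr_autumn_precip"]])
  eps <- sim_ar(length(yrs), g$ar, g$resid_var, config$ar_variance)
  r <- growth_intercept +
    g$density * nt[as.character(yrs - 1L)] +
    g$fled1 * f[as.character(yrs - 1L)] +
    g$fled2 * f[as.character(yrs - 2L)] +
    g$med_winter_temp * agg$med_winter_temp +
    g$eur_spring_precip * agg$eur_spring_precip +
    g$afr_autumn_precip * agg$afr_autumn_precip +
    eps

  series <- tibble::tibble(
    year = years_all,
    density_index = unname(nt[as.character(years_all)]),
    growth_rate = c(rep(NA_real_, 2), r),
    mean_fledglings = unname(f)
  )
  series <- dplyr::left_join(series, agg, by = "year")

  avail <- round(config$boxes_surveyed * (1 - config$parid_rate))
  counts <- tibble::tibble(
    year = yrs_n,
    boxes_surveyed = config$boxes_surveyed,
    boxes_parid = config$boxes_surveyed - avail,
    boxes_focal = round(unname(nt) / 100 * avail),
    population_label = "synthetic"
  )

  manifest <- c(
    list(growth_intercept = unname(growth_intercept)),
    setNames(
      as.list(unlist(g[setdiff(names(g), c("ar", "resid_var"))])),
      paste0("growth_", setdiff(names(g), c("ar", "resid_var")))
    ),
    if (length(g$ar)) setNames(as.list(g$ar),
                               paste0("growth_ar", names(g$ar))) else list(),
    list(growth_resid_var = g$resid_var,
         density_intercept = tr$density$intercept,
         density_fled2 = tr$density$fled2),
    if (length(tr$density$ar))
      setNames(as.list(tr$density$ar),
               paste0("density_ar", names(tr$density$ar))) else list(),
    list(density_resid_var = tr$density$resid_var,
         fledglings_mean = tr$fledglings$mean,
         fledglings_var = tr$fledglings$var,
         ar_variance = config$ar_variance)
  )
  list(series = series, counts = counts, manifest = manifest)
}

#' Simulate the nest-level breeding table
#'
#' Draws, for each year, latent annual means of hatch date, clutch size,
#' nestling-period weather and fledgling production from the between-level
#' structural model (driven by the designated European February and African
#' November temperature windows), then nest-level records from the
#' within-level model: hatch dates around the year mean, clutch size
#' responding to within-year hatch delay, correlated nest weather, and
#' fledgling counts responding to clutch size and to the
#' temperature-by-precipitation interaction of centered nest weather.
#'
#' The hatch-date and fledgling between-level intercepts are derived so the
#' simulated grand means match the long-run values (hatch day 69 from
#' April 1 = early-mid June; 4.36 fledglings); the clutch intercept is the
#' fitted value.
#'
#' @inheritParams gen_population_series
#' @return List: `nests` (nest table), `between` (per-year designated window
#'   aggregates), `annual_latents` (latent year means), `manifest`.
#' @export
gen_nests <- function(config, climate = NULL, seed = config$seed) {
  if (is.null(climate)) climate <- gen_monthly_climate(config, seed = seed)
  set.seed(seed + 2L)
  tr <- config$msem_truth
  bt <- tr$between
  wt <- tr$within
  yrs <- config$start_year:(config$start_year + config$n_years - 1L)
  J <- length(yrs)
  agg <- role_aggregates(config, climate, yrs)
  eur <- agg$eur_winter_temp
  afr <- agg$afr_winter_temp

  eur_clim <- window_climatology(config, "eur_winter_temp")
  afr_clim <- window_climatology(config, "afr_winter_temp")
  hatch_intercept <- bt$hatch_mean - bt$hatch["eur_winter_temp"] * eur_clim -
    bt$hatch["afr_winter_temp"] * afr_clim
  h_j <- hatch_intercept + bt$hatch["eur_winter_temp"] * eur +
    bt$hatch["afr_winter_temp"] * afr + rnorm(J, 0, sqrt(bt$hatch_resid_var))
  c_j <- bt$clutch_intercept + bt$clutch["hatch"] * h_j +
    bt$clutch["eur_winter_temp"] * eur + bt$clutch["afr_winter_temp"] * afr +
    rnorm(J, 0, sqrt(bt$clutch_resid_var))
  c_mean_clim <- bt$clutch_intercept + bt$clutch["hatch"] * bt$hatch_mean +
    bt$clutch["eur_winter_temp"] * eur_clim +
    bt$clutch["afr_winter_temp"] * afr_clim
  tp_j <- mvrnorm_chol(J, bt$weather_mean, bt$weather_cov)
  fled_intercept <- bt$fled_mean -
    (bt$fled["clutch"] * c_mean_clim +
       bt$fled["nest_temp"] * bt$weather_mean[["nest_temp"]] +
       bt$fled["nest_precip"] * bt$weather_mean[["nest_precip"]] +
       bt$fled["eur_winter_temp"] * eur_clim +
       bt$fled["afr_winter_temp"] * afr_clim)
  l_j <- fled_intercept + bt$fled["clutch"] * c_j +
    bt$fled["nest_temp"] * tp_j[, 1] + bt$fled["nest_precip"] * tp_j[, 2] +
    bt$fled["eur_winter_temp"] * eur + bt$fled["afr_winter_temp"] * afr +
    rnorm(J, 0, sqrt(bt$fled_resid_var))

  nj <- pmax(config$nests_min, stats::rpois(J, config$nests_per_year))
  ji <- rep(seq_len(J), nj)
  n <- length(ji)
  dh <- rnorm(n, 0, sqrt(wt$hatch_var))
  dc <- wt$clutch_hatch * dh + rnorm(n, 0, sqrt(wt$clutch_resid_var))
  dtp <- mvrnorm_chol(n, c(0, 0), wt$weather_cov)
  df <- wt$fled["nest_temp"] * dtp[, 1] + wt$fled["nest_precip"] * dtp[, 2] +
    wt$fled["temp_x_precip"] * dtp[, 1] * dtp[, 2] +
    wt$fled["clutch"] * dc + rnorm(n, 0, sqrt(wt$fled_resid_var))

  hatch <- h_j[ji] + dh
  clutch <- c_j[ji] + dc
  fled <- l_j[ji] + df
  temp <- tp_j[ji, 1] + dtp[, 1]
  precip <- tp_j[ji, 2] + dtp[, 2]
  if (config$realism_mode == "clamped") {
    hatch <- round(hatch)
    clutch <- pmax(1, round(clutch))
    fled <- pmin(pmax(0, round(fled)), clutch)
    precip <- pmax(precip, 0)
  }
  nests <- tibble::tibble(
    year = yrs[ji], hatch_date = hatch, clutch_size = clutch,
    fledglings = fled, nest_temp = temp, nest_precip = precip
  )
  manifest <- c(
    setNames(as.list(wt$fled), paste0("within_fled_", names(wt$fled))),
    list(within_fled_resid_var = wt$fled_resid_var,
         within_clutch_hatch = unname(wt$clutch_hatch),
         within_clutch_resid_var = wt$clutch_resid_var,
         within_hatch_var = wt$hatch_var,
         within_weather_cov = unname(wt$weather_cov[1, 2]),
         within_temp_var = wt$weather_cov[1, 1],
         within_precip_var = wt$weather_cov[2, 2]),
    setNames(as.list(bt$hatch), paste0("between_hatch_", names(bt$hatch))),
    setNames(as.list(bt$clutch), paste0("between_clutch_", names(bt$clutch))),
    setNames(as.list(bt$fled), paste0("between_fled_", names(bt$fled))),
    list(between_hatch_intercept = unname(hatch_intercept),
         between_clutch_intercept = bt$clutch_intercept,
         between_fled_intercept = unname(fled_intercept),
         between_hatch_resid_var = bt$hatch_resid_var,
         between_clutch_resid_var = bt$clutch_resid_var,
         between_fled_resid_var = bt$fled_resid_var,
         between_temp_mean = bt$weather_mean[["nest_temp"]],
         between_precip_mean = bt$weather_mean[["nest_precip"]],
         between_temp_var = bt$weather_cov[1, 1],
         between_precip_var = bt$weather_cov[2, 2],
         between_weather_cov = bt$weather_cov[1, 2])
  )
  list(
    nests = nests,
    between = tibble::tibble(year = yrs, eur_winter_temp = eur,
                             afr_winter_temp = afr),
    annual_latents = tibble::tibble(year = yrs, hatch = h_j, clutch = c_j,
                                    fled = l_j, nest_temp = tp_j[, 1],
                                    nest_precip = tp_j[, 2]),
    manifest = manifest
  )
}

# Cholesky-based multivariate normal draws (rows).
mvrnorm_chol <- function(n, mean, sigma) {
  z <- matrix(rnorm(n * length(mean)), n)
  sweep(z %*% chol(sigma), 2, mean, `+`)
}

#' Simulate every pipeline input and write it to disk
#'
#' Generates the monthly climate table, the nest table, and the annual
#' occupancy counts (with the annual fledgling means from the nest table
#' driving the population equations, so the two stages are coherent), plus
#' a manifest of every generating parameter for recovery scoring. With
#' `out_dir` set, writes `climate.csv`, `annual_counts.csv`, `nests.csv`
#' (short CSV headers) and `manifest.json`.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List: `climate`, `counts`, `nests`, `series`, `between`,
#'   `manifest`.
#' @export
gen_full_dataset <- function(config, out_dir = NULL) {
  climate <- gen_monthly_climate(config)
  nest_out <- gen_nests(config, climate = climate)
  ann <- annual_summaries(nest_out$nests)
  pop <- gen_population_series(
    config, climate = climate,
    fledglings = tibble::tibble(year = ann$year, value = ann$mean_fledglings)
  )
  manifest <- c(pop$manifest, nest_out$manifest,
                list(seed = config$seed, n_years = config$n_years,
                     realism_mode = config$realism_mode))
  out <- list(climate = climate, counts = pop$counts, nests = nest_out$nests,
              series = pop$series, between = nest_out$between,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    clim_out <- dplyr::rename(climate, temp = "temperature",
                              precip = "precipitation")
    counts_out <- dplyr::rename(pop$counts, surveyed = "boxes_surveyed",
                                focal = "boxes_focal", parid = "boxes_parid",
                                label = "population_label")
    nests_out <- dplyr::rename(nest_out$nests, clutch = "clutch_size")
    write.csv(clim_out, file.path(out_dir, "climate.csv"), row.names = FALSE)
    write.csv(counts_out, file.path(out_dir, "annual_counts.csv"),
              row.names = FALSE)
    write.csv(nests_out, file.path(out_dir, "nests.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
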