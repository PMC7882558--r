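test_that("same seed reproduces every table bit for bit", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  a <- gen_full_dataset(small_config(seed = 5), out_dir = dir1)
  b <- gen_full_dataset(small_config(seed = 5), out_dir = dir2)
  expect_identical(a$climate, b$climate)
  expect_identical(a$nests, b$nests)
  expect_identical(a$series, b$series)
  for (f in c("climate.csv", "annual_counts.csv", "nests.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  c_ <- gen_full_dataset(small_config(seed = 6))
  expect_false(identical(a$nests, c_$nests))
})

test_that("climate table has the full site-by-month grid", {
  cfg <- generator_config(seed = 3)
  clim <- gen_monthly_climate(cfg)
  expect_equal(nrow(clim), 10 * 78 * 12)
  expect_equal(dplyr::n_distinct(clim$site), 10)
  # zero anomaly: every year identical
  sites0 <- dplyr::mutate(climpaths:::default_sites(),
                          temp_sd = 0, precip_sd = 0)
  clim0 <- gen_monthly_climate(generator_config(seed = 3, sites = sites0))
  one <- dplyr::filter(clim0, site == "malaga", month == 1)
  expect_equal(length(unique(round(one$temperature, 10))), 1)
})

test_that("African winter temperature varies only within about two degrees", {
  cfg <- generator_config(seed = 14)
  gn <- gen_nests(cfg)
  afr <- gn$between$afr_winter_temp
  expect_equal(sd(afr), 0.5, tolerance = 0.35)
  expect_lt(diff(range(afr)), 4)
  expect_gt(mean(abs(afr - mean(afr)) < 1), 0.9)
})

test_that("manifest names the generating value of every model parameter", {
  out <- gen_full_dataset(small_config(seed = 4))
  nm <- names(out$manifest)
  expect_true(all(c(
    "growth_density", "growth_fled1", "growth_fled2",
    "growth_med_winter_temp", "growth_eur_spring_precip",
    "growth_afr_autumn_precip", "growth_ar2", "growth_resid_var",
    "density_fled2", "density_ar1", "density_ar2", "density_resid_var",
    "fledglings_mean", "fledglings_var",
    "within_fled_clutch", "within_clutch_hatch", "within_hatch_var",
    "between_fled_eur_winter_temp", "between_fled_afr_winter_temp",
    "between_clutch_hatch", "between_hatch_resid_var", "seed"
  ) %in% nm))
  expect_equal(out$manifest$within_fled_clutch, 0.695)
  expect_equal(out$manifest$growth_ar2, 0.415)
})

test_that("population series has the documented structure and round-trips", {
  cfg <- generator_config(seed = 7)
  pop <- suppressWarnings(gen_population_series(cfg))
  expect_equal(nrow(pop$series), 79) # 77 study years + 2 seasons of history
  expect_equal(sum(!is.na(pop$series$growth_rate)), 77)
  # counts reverse-engineer the density index up to integer rounding
  di <- compute_density_index(pop$counts)
  joined <- dplyr::inner_join(di, pop$series, by = "year",
                              suffix = c("_counts", "_sim"))
  expect_lt(max(abs(joined$density_index_counts - joined$density_index_sim)),
            0.2)
  # clamped mode keeps the index inside its physical range
  popc <- gen_population_series(generator_config(seed = 7,
                                                 realism_mode = "clamped"))
  expect_true(all(popc$series$density_index > 0 &
                    popc$series$density_index <= 100, na.rm = TRUE))
  nc <- gen_nests(generator_config(n_years = 10, seed = 8,
                                   realism_mode = "clamped"))
  expect_true(all(nc$nests$fledglings == round(nc$nests$fledglings)))
  expect_true(all(nc$nests$fledglings >= 0 &
                    nc$nests$fledglings <= nc$nests$clutch_size))
})

test_that("zeroed structure reduces growth to white noise at the set variance", {
  tr <- climpaths:::default_rdsem_truth()
  tr$growth[c("density", "fled1", "fled2", "med_winter_temp",
              "eur_spring_precip", "afr_autumn_precip")] <- 0
  tr$growth$ar <- numeric()
  cfg <- generator_config(n_years = 3000, seed = 10, rdsem_truth = tr)
  pop <- suppressWarnings(gen_population_series(cfg))
  r <- pop$series$growth_rate
  expect_equal(var(r, na.rm = TRUE), tr$growth$resid_var, tolerance = 0.1)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.01)
})

test_that("growth residual autocorrelation at lag 2 matches the planted AR term", {
  # with phi1 = 0 the lag-2 autocorrelation of an AR(2) residual equals phi2
  cfg <- generator_config(n_years = 5000, seed = 15)
  pop <- suppressWarnings(gen_population_series(cfg))
  s <- pop$series[-(1:2), ]
  m <- pop$manifest
  mu <- m$growth_intercept + m$growth_density * dplyr::lag(s$density_index) +
    m$growth_fled1 * dplyr::lag(s$mean_fledglings) +
    m$growth_fled2 * dplyr::lag(s$mean_fledglings, 2) +
    m$growth_med_winter_temp * s$med_winter_temp +
    m$growth_eur_spring_precip * s$eur_spring_precip +
    m$growth_afr_autumn_precip * s$afr_autumn_precip
  eps <- (s$growth_rate - mu)[-(1:2)]
  rho <- acf(eps, lag.max = 2, plot = FALSE)$acf[3]
  expect_equal(rho, 0.415, tolerance = 0.05)
})

test_that("nest table reproduces the planted within-year structure at scale", {
  cfg <- generator_config(n_years = 77, nests_per_year = 1300, seed = 16)
  gn <- gen_nests(cfg)
  nests <- gn$nests
  expect_gt(nrow(nests), 9e4)
  dev <- function(x) x - ave(x, nests$year)
  # pooled within-year hatch-date variance
  expect_equal(var(dev(nests$hatch_date)), 2.35, tolerance = 0.05)
  # within-year regression of clutch on hatch date
  b <- coef(lm(dev(nests$clutch_size) ~ 0 + dev(nests$hatch_date)))
  expect_lt(abs(unname(b) - -0.058), 0.005)
  # weather covariance
  expect_lt(abs(cov(dev(nests$nest_temp), dev(nests$nest_precip)) - -0.023),
            0.04)
})
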