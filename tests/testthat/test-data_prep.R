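test_that("density index is the percent of parid-free boxes occupied", {
  counts <- toy_counts()
  di <- compute_density_index(counts)$density_index
  expect_equal(di[1:3], c(50, 0, 47))

  # invariant to scaling all counts by a common factor
  scaled <- dplyr::mutate(counts, dplyr::across(
    c(boxes_surveyed, boxes_focal, boxes_parid), ~ .x * 3
  ))
  expect_equal(compute_density_index(scaled)$density_index, di)

  bad <- tibble::tibble(year = 1950, boxes_surveyed = 10, boxes_focal = 0,
                        boxes_parid = 10)
  expect_error(compute_density_index(bad), "1950")
})

test_that("growth rate is the natural-log difference of consecutive densities", {
  s <- tibble::tibble(year = 2001:2004,
                      density_index = c(40, 40, 40 * exp(1), 30 * exp(1)))
  r <- compute_growth_rate(s)$growth_rate
  expect_equal(r, c(NA, 0, 1, log(30 / 40)))

  # undefined across year gaps
  g <- tibble::tibble(year = c(2001, 2002, 2004),
                      density_index = c(40, 44, 50))
  expect_message(rg <- compute_growth_rate(g), "gap")
  expect_equal(is.na(rg$growth_rate), c(TRUE, FALSE, TRUE))

  expect_error(
    compute_growth_rate(tibble::tibble(year = 1:2, density_index = c(0, 10))),
    "positive"
  )
})

test_that("growth rates telescope over gap-free spans", {
  set.seed(4)
  s <- tibble::tibble(year = 1960:1990,
                      density_index = exp(rnorm(31, log(40), 0.3)))
  r <- compute_growth_rate(s)$growth_rate
  expect_equal(sum(r[-1]),
               log(s$density_index[31]) - log(s$density_index[1]))
})

test_that("merged series prefer the named population in overlap years", {
  a <- tibble::tibble(year = c(1989:1994), density_index = 1:6,
                      population_label = "askainen")
  b <- tibble::tibble(year = c(1991, 1993, 1994, 1995), density_index = 100:103,
                      population_label = "harjavalta")
  m <- merge_series(a, b, prefer = "harjavalta")
  expect_equal(m$year, c(1989:1995))
  expect_equal(m$density_index[m$year %in% c(1991, 1993, 1994)],
               c(100, 101, 102))
  expect_equal(m$density_index[m$year == 1992], 4)

  # disjoint ranges concatenate; empty inputs stay empty
  d <- merge_series(a[1:2, ], b[4, , drop = FALSE], prefer = "harjavalta")
  expect_equal(d$year, c(1989, 1990, 1995))
  expect_equal(nrow(merge_series(a[0, ], b[0, ], prefer = "x")), 0)

  # growth across the merge gap is missing, never bridged
  g <- tibble::tibble(year = c(1988, 1989, 1991, 1992), density_index = 40,
                      population_label = "a")
  gg <- suppressMessages(compute_growth_rate(
    tidyr::complete(g, year = 1988:1992)
  ))
  expect_true(is.na(gg$growth_rate[gg$year == 1991]))
})

test_that("occupancy correlation report matches known cases", {
  expect_equal(occupancy_independence(c(1, 2, 3, 4), c(1, 2, 3, 4))$r, 1)
  orth <- occupancy_independence(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(orth$r, 0)
  expect_equal(orth$n, 4)

  set.seed(11)
  z <- matrix(rnorm(2000), ncol = 2) %*% chol(matrix(c(1, .5, .5, 1), 2))
  planted <- occupancy_independence(z[, 1], z[, 2])
  expect_equal(planted$r, 0.5, tolerance = 0.1)
  expect_lt(planted$p_value, 1e-6)

  expect_error(occupancy_independence(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(occupancy_independence(1:2, 1:2), "3 paired")
})

test_that("annual summaries are per-year means of the nest table", {
  nests <- tibble::tibble(
    year = c(2000, 2001, 2001), hatch_date = c(60, 62, 64),
    clutch_size = c(6, 7, 5), fledglings = c(4, 3, 5),
    nest_temp = 15, nest_precip = 20
  )
  s <- annual_summaries(nests)
  expect_equal(s$mean_fledglings, c(4, 4))
  expect_equal(s$mean_hatch_date, c(60, 63))
  expect_equal(s$n_nests, c(1L, 2L))
})

test_that("generator defaults give a grand mean near 4.36 fledglings per nest", {
  gn <- gen_nests(generator_config(seed = 77))
  ann <- annual_summaries(gn$nests)
  expect_equal(mean(ann$mean_fledglings), 4.36, tolerance = 0.05)
})

test_that("csv readers round-trip the generator's files", {
  dir <- withr::local_tempdir()
  out <- gen_full_dataset(small_config(seed = 3), out_dir = dir)
  counts <- read_annual_counts(file.path(dir, "annual_counts.csv"))
  nests <- suppressWarnings(
    read_nest_records(file.path(dir, "nests.csv"), relaxed = TRUE)
  ) # raw gaussian-mode counts can be negative
  clim <- read_monthly_climate(file.path(dir, "climate.csv"))
  expect_equal(counts$boxes_focal, out$counts$boxes_focal)
  expect_equal(nrow(nests), nrow(out$nests))
  expect_equal(clim$temperature, out$climate$temperature, tolerance = 1e-8)

  series <- build_annual_series(counts, nests)
  expect_true(all(c("density_index", "growth_rate", "mean_fledglings")
                  %in% names(series)))
  # density recomputed from back-computed counts matches the simulated index
  # up to count rounding
  joined <- dplyr::inner_join(series, out$series, by = "year",
                              suffix = c("_prep", "_gen"))
  expect_equal(joined$density_index_prep, joined$density_index_gen,
               tolerance = 0.01)
})

test_that("validators flag impossible records and strict mode escalates", {
  bad <- toy_counts()
  bad$boxes_focal[1] <- 200
  expect_warning(validate_annual_counts(bad), "exceeds")
  expect_error(validate_annual_counts(bad, strict = TRUE), "exceeds")
  nests <- tibble::tibble(year = 2000, hatch_date = 60, clutch_size = 5,
                          fledglings = 7, nest_temp = 15, nest_precip = 10)
  expect_warning(validate_nest_records(nests), "exceed")
  expect_silent(validate_nest_records(nests, relaxed = TRUE))
})
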