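test_that("nest-level design binds clusters to between covariates", {
  gn <- gen_nests(generator_config(n_years = 5, nests_per_year = 50, seed = 2))
  spec <- build_msem(gn$nests, gn$between)
  expect_equal(length(spec$years), 5)
  expect_equal(nrow(spec$nests), nrow(gn$nests))

  orphan <- gn$between[-2, ]
  expect_error(build_msem(gn$nests, orphan), "without between-level")

  single <- gn$nests[gn$nests$year != gn$nests$year[1], ]
  single <- dplyr::bind_rows(single, gn$nests[1, ])
  expect_warning(build_msem(single, gn$between), "single nest")
})

test_that("between-level effects decompose exactly on degenerate draws", {
  stub <- msem_fit_stub(list(
    b_hatch_eur = -0.003, b_hatch_afr = -0.048,
    b_clutch_hatch = -0.037, b_clutch_eur = -0.013, b_clutch_afr = 0.019,
    b_fled_clutch = 1.489, b_fled_eur = -0.071, b_fled_afr = 0.670
  ))
  eff <- decompose_effects(stub)
  get <- function(p, e) eff$median[eff$predictor == p & eff$effect == e]
  # hatching date reaches fledglings only via clutch size
  expect_equal(get("hatch_date", "total"), -0.037 * 1.489)
  expect_equal(round(get("hatch_date", "total"), 3), -0.055)
  # winter-temperature routes
  expect_equal(get("eur_winter_temp", "via_clutch"), -0.013 * 1.489)
  expect_equal(get("eur_winter_temp", "via_hatch"),
               -0.003 * -0.037 * 1.489)
  expect_equal(get("eur_winter_temp", "direct"), -0.071)
  expect_equal(get("eur_winter_temp", "total"),
               -0.071 + -0.013 * 1.489 + -0.003 * -0.037 * 1.489)
  # zeroing one path on a route zeroes that route
  stub0 <- msem_fit_stub(list(
    b_hatch_eur = 0, b_hatch_afr = -0.048,
    b_clutch_hatch = -0.037, b_clutch_eur = -0.013, b_clutch_afr = 0.019,
    b_fled_clutch = 1.489, b_fled_eur = -0.071, b_fled_afr = 0.670
  ))
  eff0 <- decompose_effects(stub0)
  expect_equal(
    eff0$median[eff0$predictor == "eur_winter_temp" &
                  eff0$effect == "via_hatch"], 0
  )
})

test_that("per-draw additivity of total effects holds at every draw", {
  gn <- gen_nests(generator_config(n_years = 15, nests_per_year = 20, seed = 6))
  fit <- fit_msem(build_msem(gn$nests, gn$between), iter = 300, seed = 2)
  m <- draws_matrix(derived_per_draw(
    fit$draws,
    total = b_fled_eur + b_clutch_eur * b_fled_clutch +
      b_hatch_eur * b_clutch_hatch * b_fled_clutch,
    direct = b_fled_eur,
    indirect = b_clutch_eur * b_fled_clutch +
      b_hatch_eur * b_clutch_hatch * b_fled_clutch
  ))
  expect_equal(m[, "total"], m[, "direct"] + m[, "indirect"])
})

test_that("within-year hatch-date total effect is the product of within paths", {
  stub <- msem_fit_stub(list(w_clutch_hatch = -0.058, w_fled_clutch = 0.695))
  tot <- within_total_hatch_effect(stub)
  expect_equal(tot$median, -0.058 * 0.695)
  expect_equal(round(tot$median, 3), -0.040)

  zero <- msem_fit_stub(list(w_clutch_hatch = 0, w_fled_clutch = 0.695))
  expect_equal(within_total_hatch_effect(zero)$median, 0)
  # two negative paths give a positive product
  neg <- msem_fit_stub(list(w_clutch_hatch = -0.1, w_fled_clutch = -0.5))
  expect_gt(within_total_hatch_effect(neg)$median, 0)
})

test_that("simple slopes are linear in the precipitation percentile", {
  nests <- tibble::tibble(
    year = rep(1:4, each = 25), hatch_date = 60, clutch_size = 6,
    fledglings = 4, nest_temp = 15,
    nest_precip = rep(seq(0, 48, length.out = 25), 4)
  )
  stub <- msem_fit_stub(
    list(w_fled_temp = -0.009, w_fled_interaction = 0.0044),
    nests = nests
  )
  # at a +10 mm deviation the slope is -0.009 + 0.044 = 0.035
  sl <- simple_slopes(stub, percentiles = c(50, 90))
  expect_equal(sl$median[1], -0.009 + 0.0044 * sl$precip_deviation[1])
  manual <- -0.009 + 0.0044 * 10
  expect_equal(manual, 0.035)

  # interaction = 0: constant slope across percentiles
  flat <- msem_fit_stub(
    list(w_fled_temp = -0.009, w_fled_interaction = 0), nests = nests
  )
  sf <- simple_slopes(flat)
  expect_equal(length(unique(sf$median)), 1)

  # positive interaction: slope increases with precipitation
  pos <- simple_slopes(stub)
  expect_true(all(diff(pos$median) > 0))

  expect_error(simple_slopes(stub, percentiles = numeric()), "percentile")
})

test_that("within-level estimates ignore a constant shift of between covariates", {
  gn <- gen_nests(generator_config(n_years = 15, nests_per_year = 20, seed = 9))
  spec1 <- build_msem(gn$nests, gn$between)
  shifted <- dplyr::mutate(gn$between,
                           eur_winter_temp = eur_winter_temp + 100,
                           afr_winter_temp = afr_winter_temp + 50)
  spec2 <- build_msem(gn$nests, shifted)
  f1 <- fit_msem(spec1, iter = 500, seed = 3)
  f2 <- fit_msem(spec2, iter = 500, seed = 3)
  w1 <- f1$summary[grepl("^w_", f1$summary$term), ]
  w2 <- f2$summary[grepl("^w_", f2$summary$term), ]
  expect_equal(w1$median, w2$median, tolerance = 0.02)
  # and the between slopes themselves are unchanged by the shift
  b1 <- f1$summary$median[f1$summary$term == "b_fled_afr"]
  b2 <- f2$summary$median[f2$summary$term == "b_fled_afr"]
  expect_equal(b1, b2, tolerance = 0.1)
})

test_that("degenerate within variation is flagged by a near-zero variance posterior", {
  set.seed(17)
  jitter6 <- function() rnorm(120, 0, 0.01)
  nests <- tibble::tibble(
    year = rep(1:6, each = 20),
    hatch_date = rep(c(60, 62, 61, 64, 63, 60), each = 20) + jitter6(),
    clutch_size = rep(c(6, 7, 6, 5, 6, 7), each = 20) + jitter6(),
    fledglings = rep(c(4, 5, 4, 3, 4, 5), each = 20) + jitter6(),
    nest_temp = rep(c(14, 15, 16, 15, 14, 15), each = 20) + jitter6(),
    nest_precip = rep(c(20, 25, 22, 28, 24, 21), each = 20) + jitter6()
  )
  bet <- tibble::tibble(year = 1:6, eur_winter_temp = rnorm(6),
                        afr_winter_temp = rnorm(6))
  fit <- fit_msem(build_msem(nests, bet), iter = 300, seed = 4)
  expect_lt(fit$summary$median[fit$summary$term == "w_hatch_var"], 1e-3)
  expect_lt(fit$summary$median[fit$summary$term == "w_fled_resid_var"], 1e-3)
})
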