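test_that("posterior summaries report medians, intervals and zero flags", {
  v <- array(1:100, c(50, 2, 1), dimnames = list(NULL, NULL, "a"))
  sm <- summarize_draws(new_draws(v))
  expect_equal(sm$median, 50.5)
  expect_equal(sm$n_draws, 100)

  set.seed(3)
  sym <- array(rnorm(4000), c(1000, 2, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  sm2 <- summarize_draws(new_draws(sym))
  expect_false(any(sm2$nonzero))
  expect_true(all(sm2$rhat < 1.05))

  set.seed(4)
  nd <- array(rnorm(1e5, 0.4, 0.1), c(25000, 4, 1),
              dimnames = list(NULL, NULL, "theta"))
  sm3 <- summarize_draws(new_draws(nd))
  expect_equal(sm3$median, 0.4, tolerance = 0.01)
  expect_equal(sm3$ci_lower, qnorm(0.025, 0.4, 0.1), tolerance = 0.02)
  expect_equal(sm3$ci_upper, qnorm(0.975, 0.4, 0.1), tolerance = 0.02)
  expect_true(sm3$nonzero)

  expect_error(summarize_draws(new_draws(v), "nope"), "unknown parameter")
})

test_that("derived quantities are evaluated draw by draw", {
  d <- degenerate_draws(list(a = 2, b = 3))
  expect_equal(summarize_draws(derived_per_draw(d, p = a * b), "p")$median, 6)

  set.seed(9)
  ind <- array(rnorm(8000), c(2000, 2, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  prod_med <- summarize_draws(
    derived_per_draw(new_draws(ind), p = a * b), "p"
  )$median
  expect_equal(prod_med, 0, tolerance = 0.05)

  # the median of a product is not the product of medians: values near the
  # fitted-model paths give about -0.013, not the printed joint summary
  set.seed(10)
  toy <- array(c(rnorm(2000, 4.34, 1.3), rnorm(2000, -0.003, 0.00075)),
               c(1000, 2, 2), dimnames = list(NULL, NULL, c("a", "b")))
  med <- summarize_draws(derived_per_draw(new_draws(toy), p = a * b), "p")$median
  expect_equal(med, 4.34 * -0.003, tolerance = 0.15)

  expect_error(derived_per_draw(d, q = a * missing_par), "missing_par")
})

test_that("with diffuse priors and no AR terms the sampler matches least squares", {
  set.seed(42)
  n <- 300
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- drop(X %*% c(1, 2, -0.5)) + rnorm(n, 0, 0.7)
  d <- sample_ar_regression(y, X, integer(), iter = 1000, seed = 7)
  sm <- summarize_draws(d)
  ols <- unname(coef(lm(y ~ 0 + X)))
  expect_equal(sm$median[1:3], ols, tolerance = 0.02)
  expect_equal(sm$median[sm$term == "sigma2"],
               sum(residuals(lm(y ~ 0 + X))^2) / n, tolerance = 0.05)
  expect_true(all(sm$rhat < 1.05))
})

test_that("autoregressive residual coefficients are recovered on long series", {
  set.seed(1)
  n <- 1500
  e <- numeric(n + 100)
  u <- rnorm(n + 100)
  for (t in 3:(n + 100)) e[t] <- 0.4 * e[t - 1] + 0.3 * e[t - 2] + u[t]
  y <- 5 + tail(e, n)
  d <- sample_ar_regression(y, matrix(1, n, 1, dimnames = list(NULL, "int")),
                            1:2, iter = 800, seed = 3)
  sm <- summarize_draws(d)
  expect_equal(sm$median[sm$term == "ar1"], 0.4, tolerance = 0.05)
  expect_equal(sm$median[sm$term == "ar2"], 0.3, tolerance = 0.05)
  # independent oracle: exact Gaussian ML via arima on the same series
  ml <- arima(y, order = c(2, 0, 0), method = "ML")
  expect_equal(sm$median[sm$term == "ar1"], unname(coef(ml)["ar1"]),
               tolerance = 0.03)
  expect_equal(sm$median[sm$term == "ar2"], unname(coef(ml)["ar2"]),
               tolerance = 0.03)
})

test_that("a constant response concentrates the intercept at the constant", {
  y <- rep(7, 40)
  d <- sample_ar_regression(y, matrix(1, 40, 1, dimnames = list(NULL, "int")),
                            integer(), iter = 600, seed = 2)
  sm <- summarize_draws(d, "int")
  expect_equal(sm$median, 7, tolerance = 1e-3)
  expect_lt(sm$ci_upper - sm$ci_lower, 0.01)
})

test_that("seeded runs are reproducible and missing responses are imputed", {
  set.seed(8)
  n <- 80
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- drop(X %*% c(1, 1.5)) + rnorm(n, 0, 0.5)
  y[c(10, 41, 42)] <- NA
  d1 <- sample_ar_regression(y, X, 1L, iter = 600, seed = 5)
  d2 <- sample_ar_regression(y, X, 1L, iter = 600, seed = 5)
  expect_identical(unclass(d1), unclass(d2))
  sm <- summarize_draws(d1)
  expect_equal(sm$median[sm$term == "x"], 1.5, tolerance = 0.3)

  # rows with missing covariates are dropped with a message, breaking the chain
  X2 <- X
  X2[30, 2] <- NA
  expect_message(
    sample_ar_regression(y, X2, 1L, iter = 200, seed = 5),
    "excluded"
  )
})

test_that("two-level sampler recovers a planted within slope under latent centering", {
  set.seed(5)
  J <- 60
  nn <- 40
  ji <- rep(1:J, each = nn)
  nu <- rnorm(J, 10, 1.5)
  x <- nu[ji] + rnorm(J * nn, 0, 2)
  z <- rnorm(J)
  aj <- 2 + 0.5 * z + rnorm(J, 0, 0.6)
  y <- aj[ji] + 0.7 * (x - nu[ji]) + rnorm(J * nn, 0, 1)
  dat <- tibble::tibble(year = ji, y = y, x = x)
  bet <- tibble::tibble(year = 1:J, z = z)
  d <- sample_twolevel(dat, "y", "x", between = bet, iter = 800, seed = 2)
  sm <- summarize_draws(d)
  expect_equal(sm$median[sm$term == "w_x"], 0.7, tolerance = 0.05)
  expect_equal(sm$median[sm$term == "b_z"], 0.5, tolerance = 0.35)
  expect_true(all(sm$rhat < 1.1))

  # independent cross-check: observed-mean-centered random-intercept fit
  skip_if_not_installed("lme4")
  dat$xc <- x - ave(x, ji)
  lf <- lme4::lmer(y ~ xc + (1 | year), data = dat)
  expect_equal(sm$median[sm$term == "w_x"],
               unname(lme4::fixef(lf)["xc"]), tolerance = 0.02)
})

test_that("null between slopes are covered by the intervals at nominal rate", {
  covered <- vapply(1:8, function(i) {
    set.seed(300 + i)
    J <- 40
    nn <- 15
    ji <- rep(1:J, each = nn)
    nu <- rnorm(J, 0, 1)
    x <- nu[ji] + rnorm(J * nn)
    aj <- 1 + rnorm(J, 0, 0.5) # z truly has no effect
    y <- aj[ji] + 0.4 * (x - nu[ji]) + rnorm(J * nn)
    dat <- tibble::tibble(year = ji, y = y, x = x)
    bet <- tibble::tibble(year = 1:J, z = rnorm(J))
    sm <- summarize_draws(
      sample_twolevel(dat, "y", "x", between = bet, iter = 500,
                      seed = 300 + i),
      "b_z"
    )
    sm$ci_lower <= 0 && sm$ci_upper >= 0
  }, logical(1))
  expect_gte(mean(covered), 7 / 8)
})

test_that("nominal 95% intervals cover generating values across replicates", {
  # simulation-based calibration for the AR-regression sampler
  hits <- vapply(1:24, function(i) {
    set.seed(600 + i)
    n <- 60
    X <- cbind(intercept = 1, x = rnorm(n))
    e <- numeric(n + 30)
    u <- rnorm(n + 30, 0, 0.8)
    for (t in 2:(n + 30)) e[t] <- 0.5 * e[t - 1] + u[t]
    y <- drop(X %*% c(1, 2)) + tail(e, n)
    sm <- summarize_draws(
      sample_ar_regression(y, X, 1L, iter = 500, seed = 600 + i), "x"
    )
    sm$ci_lower <= 2 && sm$ci_upper >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8) # ~95% nominal; 24 replicates
})
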