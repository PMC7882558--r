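#' Attach selected climate-window covariates to an annual series
#'
#' Computes the aggregate of each selected window for every year of the
#' series and appends it as a column named after the window's role.
#'
#' @param series Annual tibble with a `year` column.
#' @param climate Monthly climate table.
#' @param selection Tibble with columns `role`, `site`, `variable`,
#'   `open_lag`, `close_lag`.
#' @param reference_month Month anchoring lag 0 (default June).
#' @return `series` with one extra column per selected window.
#' @export
attach_climate_covariates <- function(series, climate, selection,
                                      reference_month = 6L) {
  series <- tibble::as_tibble(series)
  for (i in seq_len(nrow(selection))) {
    w <- selection[i, ]
    agg <- aggregate_window(climate, w$site, w$variable, w$open_lag,
                            w$close_lag, years = series$year,
                            reference_month = reference_month)
    series[[w$role]] <- agg$value
  }
  series
}

#' Build the design of the annual growth-rate model
#'
#' Lays out the two structural equations of the residual dynamic model:
#' annual growth rate regressed on previous-year density index, fledgling
#' production one and two seasons back, and the three selected climate
#' windows; and previous-year density index regressed on fledgling
#' production two seasons back. The first usable growth year is set by the
#' two-season fledgling lag. Rows whose covariates are missing (e.g. across
#' a survey gap) are kept and flagged; the sampler excludes them and
#' restarts the residual series after each.
#'
#' @param series Annual tibble with `year`, `growth_rate`, `density_index`,
#'   `mean_fledglings`, `med_winter_temp`, `eur_spring_precip`,
#'   `afr_autumn_precip` columns (see [attach_climate_covariates()]).
#' @param ar_candidates Candidate residual AR lags for both equations.
#' @return A `climpaths_rdsem_spec` list with per-equation responses,
#'   design matrices and year indices.
#' @export
build_rdsem <- function(series, ar_candidates = 1:3) {
  series <- dplyr::arrange(tibble::as_tibble(series), .data$year)
  need <- c("year", "growth_rate", "density_index", "mean_fledglings",
            "med_winter_temp", "eur_spring_precip", "afr_autumn_precip")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols)) {
    abort(paste0("series missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(diff(series$year) != 1)) {
    abort("series must have one row per consecutive year (use tidyr::complete)")
  }
  lag1 <- function(x) dplyr::lag(x, 1)
  lag2 <- function(x) dplyr::lag(x, 2)
  g <- tibble::tibble(
    year = series$year,
    y = series$growth_rate,
    growth_intercept = 1,
    growth_density_lag1 = lag1(series$density_index),
    growth_fled_lag1 = lag1(series$mean_fledglings),
    growth_fled_lag2 = lag2(series$mean_fledglings),
    growth_med_winter_temp = series$med_winter_temp,
    growth_eur_spring_precip = series$eur_spring_precip,
    growth_afr_autumn_precip = series$afr_autumn_precip
  )
  # growth usable from the 3rd series year at the earliest (2-season lag)
  g <- g[-(1:2), , drop = FALSE]
  d <- tibble::tibble(
    year = series$year,
    y = series$density_index,
    density_intercept = 1,
    density_fled_lag2 = lag1(series$mean_fledglings)
  )
  d <- d[-1, , drop = FALSE]
  usable <- sum(!is.na(g$y) & complete.cases(g[-(1:2)]))
  if (usable < 10) abort("fewer than 10 usable growth-rate years")
  structure(
    list(
      growth = list(y = g$y, X = as.matrix(g[-(1:2)]), years = g$year),
      density = list(y = d$y, X = as.matrix(d[-(1:2)]), years = d$year),
      fled = list(
        lag1 = g$growth_fled_lag1[complete.cases(g[-(1:2)])],
        lag2 = g$growth_fled_lag2[complete.cases(g[-(1:2)])]
      ),
      ar_candidates = ar_candidates,
      n_usable = usable
    ),
    class = "climpaths_rdsem_spec"
  )
}

# Gibbs draws for the mean and variance of an iid Gaussian sample, matching
# the free mean/variance parameters of the exogenous fledgling covariates.
sample_moments <- function(x, kept, chains, priors) {
  n <- length(x)
  xbar <- mean(x)
  out <- array(NA_real_, c(kept, chains, 2))
  for (ch in seq_len(chains)) {
    mu <- xbar
    v <- var(x)
    for (it in seq_len(kept * 2)) {
      v <- draw_var(sum((x - mu)^2), n, priors)
      prec <- n / v + 1 / priors$beta_var
      mu <- rnorm(1, (n * xbar / v) / prec, sqrt(1 / prec))
      if (it > kept) out[it - kept, ch, ] <- c(mu, v)
    }
  }
  out
}

#' Fit the residual dynamic growth-rate model
#'
#' Joint Bayesian fit of the two structural equations by Gibbs sampling,
#' with autoregressive residuals on the requested lags for each equation
#' and free means/variances for the exogenous fledgling covariates. Because
#' the density index is observed, the joint posterior factorises over the
#' two equations; each is sampled with [sample_ar_regression()].
#'
#' @param spec A [build_rdsem()] specification.
#' @param growth_ar,density_ar Residual AR lags for each equation (defaults:
#'   the spec's candidates, normally `1:3`).
#' @param priors,chains,iter,seed As in [sample_ar_regression()].
#' @return A `climpaths_rdsem` fit: posterior draws for every structural
#'   slope, retained AR term, mean, intercept, variance and residual
#'   variance, plus a summary table and convergence flag. Use [tidy()],
#'   [glance()], [prune_ar_terms()], [fledgling_lag2_effects()].
#' @export
fit_rdsem <- function(spec, growth_ar = NULL, density_ar = NULL,
                      priors = default_priors(), chains = 2, iter = 1000,
                      seed = 1) {
  stopifnot(inherits(spec, "climpaths_rdsem_spec"))
  growth_ar <- growth_ar %||% spec$ar_candidates
  density_ar <- density_ar %||% spec$ar_candidates
  gd <- sample_ar_regression(spec$growth$y, spec$growth$X, growth_ar,
                             priors = priors, chains = chains, iter = iter,
                             seed = seed)
  dd <- sample_ar_regression(spec$density$y, spec$density$X, density_ar,
                             priors = priors, chains = chains, iter = iter,
                             seed = seed + 1L)
  ga <- unclass(gd)
  da <- unclass(dd)
  rn <- function(a, eq) {
    nm <- dimnames(a)[[3]]
    nm[nm == "sigma2"] <- paste0(eq, "_resid_var")
    nm <- sub("^ar", paste0(eq, "_ar"), nm)
    dimnames(a)[[3]] <- nm
    a
  }
  ga <- rn(ga, "growth")
  da <- rn(da, "density")
  kept <- dim(ga)[1]
  set.seed(seed + 2L)
  m1 <- sample_moments(spec$fled$lag1, kept, chains, priors)
  m2 <- sample_moments(spec$fled$lag2, kept, chains, priors)
  all <- array(
    c(ga, da, m1, m2),
    c(kept, chains, dim(ga)[3] + dim(da)[3] + 4),
    dimnames = list(NULL, NULL, c(
      dimnames(ga)[[3]], dimnames(da)[[3]],
      "fled_lag1_mean", "fled_lag1_var", "fled_lag2_mean", "fled_lag2_var"
    ))
  )
  draws <- new_draws(all)
  sm <- summarize_draws(draws)
  structure(
    list(
      draws = draws, spec = spec, growth_ar = growth_ar,
      density_ar = density_ar, summary = sm,
      converged = all(sm$rhat < 1.05, na.rm = TRUE),
      chains = chains, iter = iter, seed = seed
    ),
    class = "climpaths_rdsem"
  )
}

#' @export
print.climpaths_rdsem <- function(x, ...) {
  cat("Residual dynamic SEM for annual population growth rate\n")
  cat("  growth AR lags:", if (length(x$growth_ar)) x$growth_ar else "none",
      "| density AR lags:",
      if (length(x$density_ar)) x$density_ar else "none", "\n")
  cat("  converged:", x$converged, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.climpaths_rdsem <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.climpaths_rdsem <- function(x, ...) {
  tibble::tibble(
    n_growth_years = sum(!is.na(x$spec$growth$y)),
    n_density_years = sum(!is.na(x$spec$density$y)),
    growth_ar = paste(x$growth_ar, collapse = ","),
    density_ar = paste(x$density_ar, collapse = ","),
    chains = x$chains, iter = x$iter,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

# Two-sided posterior overlap with zero: min of the two tail masses.
zero_overlap <- function(v) min(mean(v > 0), mean(v < 0))

#' Prune non-significant autoregressive residual terms
#'
#' Starts from the full candidate set of AR lags on both equations'
#' residuals and iteratively removes the AR term whose posterior most
#' widely overlaps zero (largest two-sided tail mass across zero), refits,
#' and stops when every retained AR term's 95% credibility interval
#' excludes zero. Structural paths are never candidates for removal. The
#' drop sequence is recorded in the returned fit's `drop_log`.
#'
#' @inheritParams fit_rdsem
#' @return The final `climpaths_rdsem` fit with a `drop_log` tibble
#'   (`step`, `dropped`, `median`, `ci_lower`, `ci_upper`, `overlap`).
#' @export
prune_ar_terms <- function(spec, priors = default_priors(), chains = 2,
                           iter = 1000, seed = 1) {
  growth_ar <- spec$ar_candidates
  density_ar <- spec$ar_candidates
  log_rows <- list()
  step <- 0L
  repeat {
    fit <- fit_rdsem(spec, growth_ar, density_ar, priors = priors,
                     chains = chains, iter = iter, seed = seed + step)
    ar_terms <- c(
      if (length(growth_ar)) paste0("growth_ar", growth_ar),
      if (length(density_ar)) paste0("density_ar", density_ar)
    )
    if (!length(ar_terms)) break
    m <- draws_matrix(fit$draws)[, ar_terms, drop = FALSE]
    overlap <- apply(m, 2, zero_overlap)
    crossing <- overlap > 0.025 # 95% interval overlaps zero
    if (!any(crossing)) break
    worst <- names(which.max(overlap))
    sm <- fit$summary[fit$summary$term == worst, ]
    step <- step + 1L
    log_rows[[step]] <- tibble::tibble(
      step = step, dropped = worst, median = sm$median,
      ci_lower = sm$ci_lower, ci_upper = sm$ci_upper,
      overlap = max(overlap)
    )
    lag <- as.integer(sub(".*_ar", "", worst))
    if (grepl("^growth", worst)) {
      growth_ar <- setdiff(growth_ar, lag)
    } else {
      density_ar <- setdiff(density_ar, lag)
    }
  }
  fit$drop_log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble::tibble(step = integer(), dropped = character(),
                   median = numeric(), ci_lower = numeric(),
                   ci_upper = numeric(), overlap = numeric())
  fit
}

#' Effect decomposition for fledgling production two seasons back
#'
#' Fledgling production two seasons back is the only variable with both a
#' direct path to growth rate and an indirect path via the next season's
#' density index. Effects are computed draw by draw — the indirect effect
#' is the product of the two path draws, the total is direct plus indirect
#' at every draw — and then summarised, so the median of the product need
#' not equal the product of the path medians.
#'
#' @param fit A `climpaths_rdsem` fit.
#' @return Tibble with rows `direct`, `indirect`, `total` and posterior
#'   median / 95% interval columns.
#' @export
fledgling_lag2_effects <- function(fit) {
  d <- derived_per_draw(
    fit$draws,
    direct = growth_fled_lag2,
    indirect = density_fled_lag2 * growth_density_lag1,
    total = growth_fled_lag2 + density_fled_lag2 * growth_density_lag1
  )
  out <- summarize_draws(d, c("direct", "indirect", "total"))
  dplyr::rename(out, effect = "term")
}
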