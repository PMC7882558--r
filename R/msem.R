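#' Build the two-level nest-production model
#'
#' Binds nest records to their year's between-level climate covariates and
#' checks the model's preconditions: every nest year must have both winter
#' temperature covariates (orphan years are an error), and at least two
#' year clusters are needed for the between level. Single-nest years are
#' retained with a warning — they inform the between level through their
#' one observation.
#'
#' @param nests Nest records (`year`, `hatch_date`, `clutch_size`,
#'   `fledglings`, `nest_temp`, `nest_precip`).
#' @param between Per-year covariates (`year`, `eur_winter_temp`,
#'   `afr_winter_temp`).
#' @return A `climpaths_msem_spec` list.
#' @export
build_msem <- function(nests, between) {
  nests <- tibble::as_tibble(nests)
  between <- tibble::as_tibble(between)
  need_b <- c("year", "eur_winter_temp", "afr_winter_temp")
  missing_cols <- setdiff(need_b, names(between))
  if (length(missing_cols)) {
    abort(paste0("between table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  orphans <- setdiff(unique(nests$year), between$year)
  if (length(orphans)) {
    abort(paste0("nest year(s) without between-level covariates: ",
                 paste(sort(orphans), collapse = ", ")))
  }
  years <- sort(unique(nests$year))
  if (length(years) < 2) abort("between level unidentified with one year")
  nj <- table(factor(nests$year, levels = years))
  if (any(nj == 1)) {
    warn(paste0(sum(nj == 1), " year(s) with a single nest retained"))
  }
  between <- between[match(years, between$year), ]
  structure(
    list(nests = dplyr::arrange(nests, .data$year), between = between,
         years = years),
    class = "climpaths_msem_spec"
  )
}

# Draw a vector of cluster latents from accumulated Gaussian contributions.
draw_latent <- function(prec, num) rnorm(length(prec), num / prec, sqrt(1 / prec))

#' Fit the two-level nest-production model by Gibbs sampling
#'
#' Within years, fledgling number responds to centered nest-weather
#' deviations, their interaction, and clutch-size deviation, while clutch
#' size responds to hatch-date deviation; nest temperature and
#' precipitation deviations are correlated. All centering is on latent
#' year means: each within variable's year mean is a latent variable
#' (random intercept), and at the between level the latent fledgling mean
#' is regressed on the latent clutch, temperature and precipitation means
#' and the two winter-temperature windows, the latent clutch mean on the
#' latent hatch mean and the windows, and the latent hatch mean on the
#' windows. Hatch date reaches fledglings only through clutch size;
#' optionally a direct between-level hatch-to-fledglings path can be
#' freed with `hatch_direct = TRUE`.
#'
#' All full conditionals are conjugate Gaussian / inverse-gamma /
#' inverse-Wishart blocks; fledgling counts are treated as Gaussian.
#'
#' @param spec A [build_msem()] specification.
#' @param hatch_direct Free a direct between-level hatch-date path to
#'   fledglings (default `FALSE`, the fitted model's structure).
#' @param priors,chains,iter,seed As in [sample_ar_regression()].
#' @return A `climpaths_msem` fit with draws for every within and between
#'   parameter, a summary table in within/between blocks, and a
#'   convergence flag.
#' @export
fit_msem <- function(spec, hatch_direct = FALSE, priors = default_priors(),
                     chains = 2, iter = 1500, seed = 1) {
  stopifnot(inherits(spec, "climpaths_msem_spec"))
  nests <- spec$nests
  years <- spec$years
  J <- length(years)
  ji <- match(nests$year, years)
  nj <- as.numeric(table(factor(ji, levels = seq_len(J))))
  h <- nests$hatch_date
  cl <- nests$clutch_size
  fl <- nests$fledglings
  tm <- nests$nest_temp
  pr <- nests$nest_precip
  E <- spec$between$eur_winter_temp
  A <- spec$between$afr_winter_temp
  rs <- function(x) as.numeric(rowsum(x, ji))

  par_names <- c(
    "w_fled_temp", "w_fled_precip", "w_fled_interaction", "w_fled_clutch",
    "w_fled_resid_var", "w_clutch_hatch", "w_clutch_resid_var", "w_hatch_var",
    "w_temp_var", "w_precip_var", "w_temp_precip_cov",
    "b_hatch_intercept", "b_hatch_eur", "b_hatch_afr", "b_hatch_resid_var",
    "b_clutch_intercept", "b_clutch_hatch", "b_clutch_eur", "b_clutch_afr",
    "b_clutch_resid_var",
    "b_fled_intercept", "b_fled_clutch", "b_fled_temp", "b_fled_precip",
    "b_fled_eur", "b_fled_afr", if (hatch_direct) "b_fled_hatch",
    "b_fled_resid_var",
    "b_temp_mean", "b_precip_mean", "b_temp_var", "b_precip_var",
    "b_temp_precip_cov"
  )
  warm <- floor(iter / 2)
  kept <- iter - warm
  out <- array(NA_real_, c(kept, chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))

  ybar <- function(x) as.numeric(tapply(x, factor(ji, levels = seq_len(J)), mean))
  set.seed(seed)
  for (chain in seq_len(chains)) {
    jit <- function(s) rnorm(J, 0, s * (chain > 1))
    H <- ybar(h) + jit(0.2)
    C <- ybar(cl) + jit(0.05)
    Tm <- ybar(tm) + jit(0.2)
    P <- ybar(pr) + jit(0.5)
    L <- ybar(fl) + jit(0.1)
    bwf <- c(0, 0, 0, 0.5)
    s2f <- max(var(fl - L[ji]), 1e-8)
    bh <- 0
    s2c <- max(var(cl - C[ji]), 1e-8)
    s2h <- max(var(h - H[ji]), 1e-8)
    Sw <- stats::cov(cbind(tm - Tm[ji], pr - P[ji])) + diag(1e-8, 2)
    gh <- c(mean(H), 0, 0)
    t2h <- max(var(H), 1e-6)
    gc_ <- c(mean(C), 0, 0, 0)
    t2c <- max(var(C), 1e-6)
    nf <- 6 + hatch_direct
    gf <- c(mean(L), rep(0, nf - 1))
    t2f <- max(var(L), 1e-6)
    muTP <- c(mean(Tm), mean(P))
    Om <- stats::cov(cbind(Tm, P)) + diag(1e-6, 2)

    for (it in seq_len(iter)) {
      dh <- h - H[ji]
      dc <- cl - C[ji]
      dt <- tm - Tm[ji]
      dp <- pr - P[ji]
      dfl <- fl - L[ji]
      # --- within-level parameters ---
      Xf <- cbind(dt, dp, dt * dp, dc)
      bwf <- draw_coefs(Xf, dfl, s2f, priors$beta_var)
      resf <- dfl - drop(Xf %*% bwf)
      s2f <- draw_var(sum(resf^2), length(resf), priors)
      bh <- draw_coefs(matrix(dh), dc, s2c, priors$beta_var)
      resc <- dc - bh * dh
      s2c <- draw_var(sum(resc^2), length(resc), priors)
      s2h <- draw_var(sum(dh^2), length(dh), priors)
      Sw <- draw_cov(cbind(dt, dp), priors)
      # --- latent year means ---
      # hatch mean
      prec <- nj / s2h + bh^2 * nj / s2c + gc_[2]^2 / t2c + 1 / t2h
      a_ij <- cl - C[ji] - bh * h
      num <- rs(h) / s2h - bh * rs(a_ij) / s2c +
        gc_[2] * (C - gc_[1] - gc_[3] * E - gc_[4] * A) / t2c +
        (gh[1] + gh[2] * E + gh[3] * A) / t2h
      if (hatch_direct) {
        rest <- L - gf[1] - gf[2] * C - gf[3] * Tm - gf[4] * P -
          gf[5] * E - gf[6] * A
        prec <- prec + gf[7]^2 / t2f
        num <- num + gf[7] * rest / t2f
      }
      H <- draw_latent(prec, num)
      dh <- h - H[ji]
      # clutch mean
      hd <- if (hatch_direct) gf[7] * H else 0
      prec <- nj / s2c + bwf[4]^2 * nj / s2f + gf[2]^2 / t2f + 1 / t2c
      a_ij <- fl - L[ji] - bwf[1] * dt - bwf[2] * dp - bwf[3] * dt * dp -
        bwf[4] * cl
      num <- rs(cl - bh * dh) / s2c - bwf[4] * rs(a_ij) / s2f +
        gf[2] * (L - gf[1] - gf[3] * Tm - gf[4] * P - gf[5] * E -
                   gf[6] * A - hd) / t2f +
        (gc_[1] + gc_[2] * H + gc_[3] * E + gc_[4] * A) / t2c
      C <- draw_latent(prec, num)
      dc <- cl - C[ji]
      # temperature mean (conditional on precipitation mean)
      cnd_b <- Sw[1, 2] / Sw[2, 2]
      cnd_v <- Sw[1, 1] - Sw[1, 2]^2 / Sw[2, 2]
      w_ij <- bwf[1] + bwf[3] * dp
      a_ij <- fl - L[ji] - bwf[2] * dp - bwf[4] * dc - w_ij * tm
      pr_b <- Om[1, 2] / Om[2, 2]
      pr_v <- Om[1, 1] - Om[1, 2]^2 / Om[2, 2]
      prec <- nj / cnd_v + rs(w_ij^2) / s2f + gf[3]^2 / t2f + 1 / pr_v
      num <- rs(tm - cnd_b * dp) / cnd_v - rs(w_ij * a_ij) / s2f +
        gf[3] * (L - gf[1] - gf[2] * C - gf[4] * P - gf[5] * E -
                   gf[6] * A - hd) / t2f +
        (muTP[1] + pr_b * (P - muTP[2])) / pr_v
      Tm <- draw_latent(prec, num)
      dt <- tm - Tm[ji]
      # precipitation mean (conditional on temperature mean)
      cnd_b <- Sw[1, 2] / Sw[1, 1]
      cnd_v <- Sw[2, 2] - Sw[1, 2]^2 / Sw[1, 1]
      w_ij <- bwf[2] + bwf[3] * dt
      a_ij <- fl - L[ji] - bwf[1] * dt - bwf[4] * dc - w_ij * pr
      pr_b <- Om[1, 2] / Om[1, 1]
      pr_v <- Om[2, 2] - Om[1, 2]^2 / Om[1, 1]
      prec <- nj / cnd_v + rs(w_ij^2) / s2f + gf[4]^2 / t2f + 1 / pr_v
      num <- rs(pr - cnd_b * dt) / cnd_v - rs(w_ij * a_ij) / s2f +
        gf[4] * (L - gf[1] - gf[2] * C - gf[3] * Tm - gf[5] * E -
                   gf[6] * A - hd) / t2f +
        (muTP[2] + pr_b * (Tm - muTP[1])) / pr_v
      P <- draw_latent(prec, num)
      dp <- pr - P[ji]
      # fledgling latent intercept
      within_part <- bwf[1] * dt + bwf[2] * dp + bwf[3] * dt * dp + bwf[4] * dc
      prec <- nj / s2f + 1 / t2f
      num <- rs(fl - within_part) / s2f +
        (gf[1] + gf[2] * C + gf[3] * Tm + gf[4] * P + gf[5] * E +
           gf[6] * A + hd) / t2f
      L <- draw_latent(prec, num)
      # --- between-level parameters ---
      Xh <- cbind(1, E, A)
      gh <- draw_coefs(Xh, H, t2h, priors$beta_var)
      t2h <- draw_var(sum((H - drop(Xh %*% gh))^2), J, priors)
      Xc <- cbind(1, H, E, A)
      gc_ <- draw_coefs(Xc, C, t2c, priors$beta_var)
      t2c <- draw_var(sum((C - drop(Xc %*% gc_))^2), J, priors)
      Xl <- cbind(1, C, Tm, P, E, A)
      if (hatch_direct) Xl <- cbind(Xl, H)
      gf <- draw_coefs(Xl, L, t2f, priors$beta_var)
      t2f <- draw_var(sum((L - drop(Xl %*% gf))^2), J, priors)
      TP <- cbind(Tm, P)
      oinv <- solve(Om)
      prec_mu <- J * oinv + diag(1e-6, 2)
      ch_mu <- chol(prec_mu)
      mu_mean <- solve(prec_mu, oinv %*% colSums(TP))
      muTP <- drop(mu_mean + backsolve(ch_mu, rnorm(2)))
      Om <- draw_cov(sweep(TP, 2, muTP), priors)
      if (it > warm) {
        out[it - warm, chain, ] <- c(
          bwf, s2f, bh, s2c, s2h, Sw[1, 1], Sw[2, 2], Sw[1, 2],
          gh, t2h, gc_, t2c, gf[1:6], if (hatch_direct) gf[7], t2f,
          muTP, Om[1, 1], Om[2, 2], Om[1, 2]
        )
      }
    }
  }
  draws <- new_draws(out)
  sm <- summarize_draws(draws)
  structure(
    list(draws = draws, spec = spec, hatch_direct = hatch_direct,
         summary = sm, converged = all(sm$rhat < 1.05, na.rm = TRUE),
         chains = chains, iter = iter, seed = seed),
    class = "climpaths_msem"
  )
}

#' @export
print.climpaths_msem <- function(x, ...) {
  cat("Two-level SEM for nest-level fledgling production\n")
  cat("  years:", length(x$spec$years), "| nests:", nrow(x$spec$nests),
      "| converged:", x$converged, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.climpaths_msem <- function(x, ...) {
  dplyr::mutate(
    x$summary,
    level = ifelse(grepl("^w_", .data$term), "within", "between"),
    .before = 1
  )
}

#' @exportS3Method generics::glance
glance.climpaths_msem <- function(x, ...) {
  tibble::tibble(
    n_nests = nrow(x$spec$nests), n_years = length(x$spec$years),
    chains = x$chains, iter = x$iter,
    max_rhat = max(x$summary$rhat, na.rm = TRUE), converged = x$converged
  )
}

#' Between-level effect decomposition
#'
#' Total, direct and indirect effects of the two winter-temperature windows
#' and of hatching date on annual mean fledgling production, computed per
#' posterior draw: the route via clutch size multiplies the covariate's
#' clutch path by the clutch-to-fledglings path; the route via hatching
#' date additionally passes through the hatch-to-clutch path; totals add
#' direct and indirect draws. Summaries are medians with 95% intervals of
#' these per-draw quantities, so the summary rows need not add up — sums of
#' medians are not medians of sums.
#'
#' @param fit A `climpaths_msem` fit.
#' @return Tibble: `predictor`, `effect` (`total`, `direct`, `indirect`,
#'   `via_hatch`, `via_clutch`), `median`, `ci_lower`, `ci_upper`,
#'   `n_draws`, `rhat`, `nonzero`. Hatching date has no direct path (unless
#'   the fit freed one) and no route via itself; those rows are omitted.
#' @export
decompose_effects <- function(fit) {
  hd <- fit$hatch_direct
  d <- derived_per_draw(
    fit$draws,
    eur_via_clutch = b_clutch_eur * b_fled_clutch,
    eur_via_hatch = b_hatch_eur * b_clutch_hatch * b_fled_clutch,
    afr_via_clutch = b_clutch_afr * b_fled_clutch,
    afr_via_hatch = b_hatch_afr * b_clutch_hatch * b_fled_clutch,
    hatch_via_clutch = b_clutch_hatch * b_fled_clutch
  )
  d <- derived_per_draw(
    d,
    eur_indirect = eur_via_clutch + eur_via_hatch,
    afr_indirect = afr_via_clutch + afr_via_hatch,
    eur_total = b_fled_eur + eur_via_clutch + eur_via_hatch,
    afr_total = b_fled_afr + afr_via_clutch + afr_via_hatch
  )
  if (hd) {
    d <- derived_per_draw(
      d,
      hatch_total = b_fled_hatch + hatch_via_clutch
    )
  }
  rows <- tibble::tribble(
    ~predictor, ~effect, ~param,
    "eur_winter_temp", "total", "eur_total",
    "eur_winter_temp", "direct", "b_fled_eur",
    "eur_winter_temp", "indirect", "eur_indirect",
    "eur_winter_temp", "via_hatch", "eur_via_hatch",
    "eur_winter_temp", "via_clutch", "eur_via_clutch",
    "afr_winter_temp", "total", "afr_total",
    "afr_winter_temp", "direct", "b_fled_afr",
    "afr_winter_temp", "indirect", "afr_indirect",
    "afr_winter_temp", "via_hatch", "afr_via_hatch",
    "afr_winter_temp", "via_clutch", "afr_via_clutch",
    "hatch_date", "total", if (hd) "hatch_total" else "hatch_via_clutch",
    "hatch_date", "indirect", "hatch_via_clutch",
    "hatch_date", "via_clutch", "hatch_via_clutch"
  )
  if (hd) {
    rows <- dplyr::add_row(rows, predictor = "hatch_date", effect = "direct",
                           param = "b_fled_hatch", .after = 11)
  }
  sm <- summarize_draws(d, unique(rows$param))
  out <- dplyr::left_join(rows, sm, by = c(param = "term"))
  dplyr::select(out, -"param")
}

#' Within-year total effect of hatching date on fledgling number
#'
#' Within years, hatching date influences fledgling number only through
#' clutch size, so its total effect is the per-draw product of the
#' hatch-to-clutch and clutch-to-fledglings within paths.
#'
#' @param fit A `climpaths_msem` fit.
#' @return One-row posterior summary tibble.
#' @export
within_total_hatch_effect <- function(fit) {
  d <- derived_per_draw(fit$draws,
                        within_hatch_total = w_clutch_hatch * w_fled_clutch)
  summarize_draws(d, "within_hatch_total")
}

#' Simple slopes of nestling temperature at precipitation percentiles
#'
#' The within-year temperature effect on fledgling number is moderated by
#' nestling-period precipitation. For each requested percentile of the
#' observed within-year precipitation deviations, the slope
#' `beta_temp + beta_interaction * precip_deviation` is evaluated at every
#' posterior draw and summarised. The centering offset is zero on the
#' latent-centered scale; the raw precipitation value at each percentile is
#' reported alongside.
#'
#' @param fit A `climpaths_msem` fit.
#' @param percentiles Percentiles (0-100) of the within-year precipitation
#'   distribution (default 10, 25, 50, 75, 90).
#' @return Tibble: `percentile`, `precip_deviation`, `precip_raw`,
#'   `median`, `ci_lower`, `ci_upper`.
#' @export
simple_slopes <- function(fit, percentiles = c(10, 25, 50, 75, 90)) {
  if (!length(percentiles)) abort("at least one percentile is required")
  nests <- fit$spec$nests
  yr_mean <- stats::ave(nests$nest_precip, nests$year)
  dev <- nests$nest_precip - yr_mean
  dev_q <- quantile(dev, percentiles / 100, names = FALSE)
  raw_q <- quantile(nests$nest_precip, percentiles / 100, names = FALSE)
  m <- draws_matrix(fit$draws)
  bt <- m[, "w_fled_temp"]
  bi <- m[, "w_fled_interaction"]
  rows <- purrr::map2(seq_along(percentiles), dev_q, function(i, q) {
    s <- bt + bi * q
    qs <- quantile(s, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(
      percentile = percentiles[i], precip_deviation = q,
      precip_raw = raw_q[i], median = qs[2], ci_lower = qs[1],
      ci_upper = qs[3]
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot simple slopes against precipitation percentile
#'
#' @param slopes Output of [simple_slopes()] (or a `climpaths_msem` fit,
#'   in which case slopes are computed with defaults).
#' @return A ggplot object.
#' @export
plot_simple_slopes <- function(slopes) {
  if (inherits(slopes, "climpaths_msem")) slopes <- simple_slopes(slopes)
  ggplot2::ggplot(slopes, ggplot2::aes(x = .data$percentile, y = .data$median)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "percentile of nestling-period precipitation",
      y = "slope of fledgling number on nestling temperature"
    ) +
    ggplot2::theme_minimal()
}
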