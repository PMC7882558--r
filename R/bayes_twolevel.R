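#' Two-level regression with latent group-mean centering, by Gibbs sampling
#'
#' Fits a single-response two-level model in which each within-cluster
#' predictor is split into a latent cluster mean and a within-cluster
#' deviation, the response has a random intercept (its own latent cluster
#' mean), and the random intercept is regressed on observed cluster-level
#' covariates:
#'
#' \deqn{x^{(m)}_{ij} = \nu^{(m)}_j + d^{(m)}_{ij}, \quad
#'       y_{ij} = a_j + \sum_m \beta_m d^{(m)}_{ij} + e_{ij}, \quad
#'       a_j = \gamma_0 + z_j'\gamma + u_j.}
#'
#' Centering on latent (not observed) cluster means avoids the bias that
#' observed-mean centering induces with finite cluster sizes; observed-mean
#' centering is available as a fallback.
#'
#' @param data Data frame of within-level records.
#' @param response Column name of the response.
#' @param within Character vector of within-predictor column names.
#' @param cluster Column name identifying the cluster (e.g. year).
#' @param between Optional data frame of cluster-level covariates with the
#'   cluster column plus covariate columns.
#' @param centering `"latent"` (default) or `"observed"` cluster means.
#' @param priors,chains,iter,seed As in [sample_ar_regression()].
#' @return A [new_draws()] object: within slopes `w_<name>`, within residual
#'   variance `sigma2_within`, predictor within variances `sx2_<name>`,
#'   predictor latent-mean means/variances `mu_<name>`/`tau2_<name>`, between
#'   intercept `b_intercept`, between slopes `b_<name>`, and between residual
#'   variance `tau2_between`.
#' @export
sample_twolevel <- function(data, response, within, cluster = "year",
                            between = NULL, centering = c("latent", "observed"),
                            priors = default_priors(), chains = 2, iter = 1000,
                            seed = 1) {
  centering <- match.arg(centering)
  data <- tibble::as_tibble(data)
  cl <- factor(data[[cluster]])
  J <- nlevels(cl)
  if (J < 2) abort("between level unidentified with a single cluster")
  ji <- as.integer(cl)
  nj <- as.integer(table(ji))
  y <- data[[response]]
  Xw <- as.matrix(data[within])
  p <- length(within)
  if (!is.null(between)) {
    between <- tibble::as_tibble(between)
    bcl <- match(levels(cl), as.character(between[[cluster]]))
    if (anyNA(bcl)) abort("between table missing clusters present in data")
    zn <- setdiff(names(between), cluster)
    Z <- cbind(intercept = 1, as.matrix(between[bcl, zn, drop = FALSE]))
  } else {
    zn <- character()
    Z <- matrix(1, J, 1, dimnames = list(NULL, "intercept"))
  }

  par_names <- c(
    paste0("w_", within), "sigma2_within",
    paste0("sx2_", within), paste0("mu_", within), paste0("tau2_", within),
    "b_intercept", if (length(zn)) paste0("b_", zn), "tau2_between"
  )
  warm <- floor(iter / 2)
  kept <- iter - warm
  out <- array(NA_real_, c(kept, chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))

  xbar <- apply(Xw, 2, function(v) tapply(v, ji, mean))
  xbar <- matrix(xbar, J, p)
  ybar <- tapply(y, ji, mean)

  set.seed(seed)
  for (ch in seq_len(chains)) {
    nu <- xbar + rnorm(J * p, 0, 0.05 * (ch > 1))
    a <- as.numeric(ybar) + rnorm(J, 0, 0.05 * (ch > 1))
    bw <- rep(0, p)
    s2w <- var(y - a[ji])
    sx2 <- pmax(apply(Xw - nu[ji, , drop = FALSE], 2, var), 1e-8)
    mu <- colMeans(nu)
    tau2x <- pmax(apply(nu, 2, var), 1e-8)
    gam <- rep(0, ncol(Z))
    t2b <- max(var(a), 1e-8)

    for (it in seq_len(iter)) {
      D <- Xw - nu[ji, , drop = FALSE]
      # within slopes and residual variance
      r <- y - a[ji]
      bw <- draw_coefs(D, r, s2w, priors$beta_var)
      res <- r - drop(D %*% bw)
      s2w <- draw_var(sum(res^2), length(res), priors)
      # predictor within variances, latent-mean hyperparameters
      for (m in seq_len(p)) {
        sx2[m] <- draw_var(sum(D[, m]^2), nrow(D), priors)
        prec <- J / tau2x[m] + 1 / priors$beta_var
        mu[m] <- rnorm(1, sum(nu[, m]) / tau2x[m] / prec, sqrt(1 / prec))
        tau2x[m] <- draw_var(sum((nu[, m] - mu[m])^2), J, priors)
      }
      # random intercepts
      prior_mean <- drop(Z %*% gam)
      r_within <- y - drop((Xw - nu[ji, , drop = FALSE]) %*% bw)
      sum_r <- as.numeric(rowsum(r_within, ji))
      prec_a <- nj / s2w + 1 / t2b
      mean_a <- (sum_r / s2w + prior_mean / t2b) / prec_a
      a <- rnorm(J, mean_a, sqrt(1 / prec_a))
      # latent predictor means (skip when observed-mean centering requested)
      if (centering == "latent") {
        for (m in seq_len(p)) {
          other <- drop((Xw - nu[ji, , drop = FALSE]) %*% bw) -
            bw[m] * (Xw[, m] - nu[ji, m])
          # y_ij - a_j - other = bw_m (x_m - nu_m) + e
          r2 <- y - a[ji] - other - bw[m] * Xw[, m]
          prec <- nj / sx2[m] + nj * bw[m]^2 / s2w + 1 / tau2x[m]
          num <- as.numeric(rowsum(Xw[, m], ji)) / sx2[m] +
            (-bw[m]) * as.numeric(rowsum(r2, ji)) / s2w +
            mu[m] / tau2x[m]
          nu[, m] <- rnorm(J, num / prec, sqrt(1 / prec))
        }
      } else {
        nu <- xbar
      }
      # between regression of the random intercept
      gam <- draw_coefs(Z, a, t2b, priors$beta_var)
      t2b <- draw_var(sum((a - drop(Z %*% gam))^2), J, priors)
      if (it > warm) {
        out[it - warm, ch, ] <- c(bw, s2w, sx2, mu, tau2x, gam, t2b)
      }
    }
  }
  new_draws(out)
}
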