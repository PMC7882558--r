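#' Prior settings for the Gibbs samplers
#'
#' Diffuse defaults: Normal(0, 1e6) on regression coefficients, intercepts
#' and autoregressive coefficients (no stationarity truncation), and
#' Inverse-Gamma(0.001, 0.001) on variances. Two-by-two covariance blocks use
#' an inverse-Wishart with `iw_df` degrees of freedom and scale
#' `iw_scale * I`.
#'
#' @param beta_var Prior variance of regression/AR coefficients.
#' @param ig_shape,ig_rate Inverse-gamma shape and rate for variances.
#' @param iw_df,iw_scale Inverse-Wishart prior for covariance blocks.
#' @return A list of class `climpaths_priors`.
#' @export
default_priors <- function(beta_var = 1e6, ig_shape = 0.001, ig_rate = 0.001,
                           iw_df = 3, iw_scale = 0.001) {
  structure(
    list(beta_var = beta_var, ig_shape = ig_shape, ig_rate = ig_rate,
         iw_df = iw_df, iw_scale = iw_scale),
    class = "climpaths_priors"
  )
}

# Conjugate draw of regression coefficients given the error variance.
draw_coefs <- function(X, y, sigma2, prior_var) {
  k <- ncol(X)
  prec <- crossprod(X) / sigma2 + diag(1 / prior_var, k)
  ch <- chol(prec)
  mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y) / sigma2))
  drop(mu + backsolve(ch, rnorm(k)))
}

# Conjugate inverse-gamma draw of a variance from residual sum of squares.
draw_var <- function(rss, n, priors) {
  1 / rgamma(1, priors$ig_shape + n / 2, priors$ig_rate + rss / 2)
}

# Inverse-Wishart draw for a covariance block from the matrix of residuals.
draw_cov <- function(resid, priors) {
  n <- nrow(resid)
  p <- ncol(resid)
  s <- crossprod(resid) + diag(priors$iw_scale, p)
  df <- priors$iw_df + n
  w <- rWishart(1, df, solve(s))[, , 1]
  solve(w)
}

# Quasi-difference a column over contiguous segments: x_t - sum phi_k x_{t-k}
# for rows at least max(lags) into their segment.
ar_design_rows <- function(seg_id, lags) {
  if (!length(lags)) return(seq_along(seg_id))
  p <- max(lags)
  ok <- rep(TRUE, length(seg_id))
  for (k in seq_len(p)) {
    lagged_seg <- c(rep(NA, k), head(seg_id, -k))
    ok <- ok & !is.na(lagged_seg) & lagged_seg == seg_id
  }
  which(ok)
}

#' Gaussian regression with autoregressive residuals, by Gibbs sampling
#'
#' Fits `y_t = x_t' beta + eps_t` where the residual follows an
#' autoregressive process on the supplied lags,
#' `eps_t = sum_k phi_k eps_{t-k} + u_t`, `u_t ~ N(0, sigma2)`. The
#' likelihood conditions on the first `max(ar_lags)` observations of each
#' contiguous segment (rows with missing covariates break the series into
#' segments and are excluded). Missing responses are treated as latent and
#' imputed at every sweep from their full conditional under the AR structure.
#'
#' All full conditionals are conjugate: coefficients given `phi` by
#' quasi-differenced least squares, `phi` given coefficients by regressing
#' residuals on their own lags, the innovation variance from an
#' inverse-gamma.
#'
#' @param y Response vector (time order; `NA` allowed and imputed).
#' @param X Design matrix with named columns (include the intercept
#'   explicitly). Rows with missing values are dropped from the likelihood
#'   and break the AR chain.
#' @param ar_lags Integer vector of residual AR lags (e.g. `1:3`, or `2L`;
#'   empty for independent errors).
#' @param priors See [default_priors()].
#' @param chains,iter Number of chains and total iterations per chain; the
#'   first half of each chain is discarded as warm-up.
#' @param seed Integer seed; runs are reproducible bit-for-bit.
#' @return A [new_draws()] object with the regression coefficients (named as
#'   `colnames(X)`), `ar<k>` terms, and the innovation variance `sigma2`.
#' @export
sample_ar_regression <- function(y, X, ar_lags = integer(), priors = default_priors(),
                                 chains = 2, iter = 1000, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  if (length(y) != nrow(X)) abort("y and X lengths differ")
  ar_lags <- sort(unique(as.integer(ar_lags)))
  if (length(ar_lags) && min(ar_lags) < 1) abort("AR lags must be >= 1")

  usable <- complete.cases(X)
  if (!all(usable)) {
    inform(paste0(sum(!usable), " row(s) with missing covariates excluded; ",
                  "the residual series restarts after each"))
  }
  keep <- which(usable)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  # contiguous segments of retained rows
  seg_id <- cumsum(c(1L, diff(keep) != 1L))
  p <- if (length(ar_lags)) max(ar_lags) else 0L
  if (n <= p + k) abort("series too short for the requested model")
  model_rows <- ar_design_rows(seg_id, ar_lags)
  miss <- which(is.na(y))

  par_names <- c(colnames(X), if (length(ar_lags)) paste0("ar", ar_lags), "sigma2")
  warm <- floor(iter / 2)
  kept <- iter - warm
  out <- array(NA_real_, c(kept, chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))

  set.seed(seed)
  y_obs_mean <- mean(y, na.rm = TRUE)
  for (ch in seq_len(chains)) {
    yy <- y
    if (length(miss)) yy[miss] <- y_obs_mean + rnorm(length(miss), 0, sd(y, na.rm = TRUE))
    beta <- drop(qr.solve(crossprod(X) + diag(1e-8, k), crossprod(X, yy)))
    beta <- beta * (1 + 0.1 * (ch - 1)) + rnorm(k, 0, 0.1 * (ch > 1))
    phi <- rep(0, length(ar_lags))
    sigma2 <- var(yy - X %*% beta) * (1 + 0.5 * (ch - 1))
    sigma2 <- max(sigma2, 1e-10)

    for (it in seq_len(iter)) {
      eps <- yy - drop(X %*% beta)
      # impute missing responses from their AR full conditional
      if (length(miss)) {
        for (t in miss) {
          prec <- 0
          num <- 0
          if (t %in% model_rows) {
            m <- sum(phi * vapply(ar_lags, function(l) eps[t - l], 0))
            prec <- prec + 1
            num <- num + m
          }
          for (j in seq_along(ar_lags)) {
            s <- t + ar_lags[j]
            if (s <= n && s %in% model_rows && seg_id[s] == seg_id[t]) {
              rest <- eps[s] + phi[j] * eps[t] -
                sum(phi * vapply(ar_lags, function(l) eps[s - l], 0))
              prec <- prec + phi[j]^2
              num <- num + phi[j] * rest
            }
          }
          if (prec == 0) {
            eps[t] <- rnorm(1, 0, sqrt(sigma2))
          } else {
            eps[t] <- rnorm(1, num / prec, sqrt(sigma2 / prec))
          }
          yy[t] <- eps[t] + drop(X[t, ] %*% beta)
        }
      }
      # coefficients by quasi-differencing
      if (length(ar_lags)) {
        ys <- yy[model_rows]
        Xs <- X[model_rows, , drop = FALSE]
        for (j in seq_along(ar_lags)) {
          l <- ar_lags[j]
          ys <- ys - phi[j] * yy[model_rows - l]
          Xs <- Xs - phi[j] * X[model_rows - l, , drop = FALSE]
        }
      } else {
        ys <- yy
        Xs <- X
      }
      beta <- draw_coefs(Xs, ys, sigma2, priors$beta_var)
      eps <- yy - drop(X %*% beta)
      # AR coefficients given residuals
      if (length(ar_lags)) {
        E <- vapply(ar_lags, function(l) eps[model_rows - l],
                    numeric(length(model_rows)))
        E <- matrix(E, ncol = length(ar_lags))
        phi <- draw_coefs(E, eps[model_rows], sigma2, priors$beta_var)
        u <- eps[model_rows] - drop(E %*% phi)
      } else {
        u <- eps
      }
      sigma2 <- draw_var(sum(u^2), length(u), priors)
      if (it > warm) {
        out[it - warm, ch, ] <- c(beta, phi, sigma2)
      }
    }
  }
  new_draws(out)
}
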