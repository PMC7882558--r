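#' Posterior draws container
#'
#' MCMC output is stored as a 3-d array (iteration x chain x parameter) with
#' parameter names in the third dimension, wrapped in the `climpaths_draws`
#' class. At least two chains are kept so that convergence can be checked by
#' the split potential scale reduction statistic.
#'
#' @param a Numeric array, `dim = c(iterations, chains, parameters)`, with
#'   parameter dimnames.
#' @return A `climpaths_draws` object.
#' @export
new_draws <- function(a) {
  stopifnot(is.array(a), length(dim(a)) == 3)
  if (is.null(dimnames(a)[[3]])) abort("draws need parameter names")
  structure(a, class = "climpaths_draws")
}

#' @export
print.climpaths_draws <- function(x, ...) {
  d <- dim(x)
  cat("<climpaths_draws> ", d[1], " iterations x ", d[2], " chains x ",
      d[3], " parameters\n", sep = "")
  print(summarize_draws(x), ...)
  invisible(x)
}

#' Flatten draws to a matrix
#'
#' @param draws A `climpaths_draws` object.
#' @return Matrix with one column per parameter, chains stacked.
#' @export
draws_matrix <- function(draws) {
  d <- dim(draws)
  m <- matrix(aperm(unclass(draws), c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(draws)[[3]]
  m
}

# Split-chain potential scale reduction (each chain halved, classic
# between/within variance ratio).
split_rhat <- function(x) {
  iter <- nrow(x)
  if (iter < 4) return(NA_real_)
  half <- iter %/% 2
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(iter - half + 1):iter, , drop = FALSE])
  m <- ncol(sub)
  n <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, var)
  w <- mean(s2)
  b <- n * var(mu)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Posterior summaries
#'
#' Per-parameter posterior median, equal-tailed 95% credibility interval,
#' split-chain potential scale reduction, and a flag for parameters whose
#' interval excludes zero.
#'
#' @param draws A `climpaths_draws` object.
#' @param pars Optional character vector restricting/ordering the parameters.
#' @return Tibble: `term`, `median`, `ci_lower`, `ci_upper`, `n_draws`,
#'   `rhat`, `nonzero`.
#' @export
summarize_draws <- function(draws, pars = NULL) {
  nm <- dimnames(draws)[[3]]
  pars <- pars %||% nm
  missing_pars <- setdiff(pars, nm)
  if (length(missing_pars)) {
    abort(paste0("unknown parameter(s): ", paste(missing_pars, collapse = ", ")))
  }
  a <- unclass(draws)
  rows <- purrr::map(pars, function(p) {
    x <- a[, , p, drop = FALSE][, , 1]
    x <- as.matrix(x)
    v <- as.numeric(x)
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(
      term = p, median = q[2], ci_lower = q[1], ci_upper = q[3],
      n_draws = length(v), rhat = split_rhat(x),
      nonzero = q[1] > 0 | q[3] < 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Derived quantities, draw by draw
#'
#' Evaluates expressions of model parameters at every posterior draw and
#' appends the results as new parameters, so that nonlinear functions of
#' parameters (products of paths, sums of direct and indirect effects) are
#' summarised as distributions. The median of a per-draw product is generally
#' not the product of medians.
#'
#' @param draws A `climpaths_draws` object.
#' @param ... Named expressions in terms of existing parameter names, e.g.
#'   `indirect = a * b`. Backticks allow non-syntactic names.
#' @return The draws object with the derived parameters appended.
#' @examples
#' a <- array(rep(c(2, 3), each = 8), c(4, 2, 2),
#'            dimnames = list(NULL, NULL, c("a", "b")))
#' d <- derived_per_draw(new_draws(a), prod_ab = a * b)
#' summarize_draws(d, "prod_ab")$median # 6
#' @export
derived_per_draw <- function(draws, ...) {
  exprs <- rlang::enquos(...)
  if (!length(exprs)) return(draws)
  if (is.null(names(exprs)) || any(names(exprs) == "")) {
    abort("derived quantities must be named")
  }
  a <- unclass(draws)
  d <- dim(a)
  nm <- dimnames(a)[[3]]
  env_list <- lapply(nm, function(p) a[, , p])
  names(env_list) <- nm
  mask <- rlang::new_data_mask(rlang::new_environment(env_list))
  add <- lapply(exprs, function(q) {
    val <- rlang::eval_tidy(q, data = mask)
    if (length(val) == 1) val <- array(val, d[1:2])
    array(as.numeric(val), d[1:2])
  })
  out <- array(c(a, unlist(add)), c(d[1], d[2], d[3] + length(add)),
               dimnames = list(NULL, NULL, c(nm, names(exprs))))
  new_draws(out)
}

#' @exportS3Method generics::tidy
tidy.climpaths_draws <- function(x, ...) summarize_draws(x, ...)
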