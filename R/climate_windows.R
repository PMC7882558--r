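#' Enumerate candidate climate windows
#'
#' A candidate window is a contiguous run of months defined by how many months
#' before the reference month it opens and closes. All pairs with
#' `0 <= close_lag <= open_lag <= max_lag` are candidates, giving
#' `(max_lag + 1) * (max_lag + 2) / 2` windows — 91 for monthly lags up to 12.
#'
#' @param max_lag Largest lag (months before the reference month) considered.
#' @return Tibble: `open_lag`, `close_lag`, `length` (months in the window).
#' @examples
#' nrow(enumerate_windows(12)) # 91
#' @export
enumerate_windows <- function(max_lag) {
  if (length(max_lag) != 1 || is.na(max_lag) || max_lag < 0) {
    abort("max_lag must be a non-negative integer")
  }
  max_lag <- as.integer(max_lag)
  grid <- tidyr::expand_grid(open_lag = 0:max_lag, close_lag = 0:max_lag)
  grid |>
    dplyr::filter(.data$close_lag <= .data$open_lag) |>
    dplyr::mutate(length = .data$open_lag - .data$close_lag + 1L) |>
    dplyr::arrange(.data$open_lag, .data$close_lag)
}

# Calendar (year, month) pairs covered by a window anchored at
# reference_month of the focal year, counting lags backwards across the
# year boundary.
window_months <- function(open_lag, close_lag, year, reference_month) {
  lags <- seq(close_lag, open_lag)
  idx <- 12L * year + (reference_month - 1L) - lags # linear month index
  tibble::tibble(year = idx %/% 12L, month = idx %% 12L + 1L)
}

#' Aggregate a monthly climate series over a window
#'
#' For each focal year, collects the monthly values of one variable at one
#' site over the window (months counted backwards from the reference month,
#' crossing into the previous calendar year as needed) and aggregates them.
#'
#' @param climate Monthly climate table (`site`, `year`, `month`,
#'   `temperature`, `precipitation`).
#' @param site Site identifier.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param open_lag,close_lag Window bounds in months before the reference
#'   month (`close_lag <= open_lag`).
#' @param years Focal years for which to compute the aggregate.
#' @param reference_month Calendar month anchoring lag 0 (default June, the
#'   breeding season).
#' @param aggregate `"mean"` (default; the models use monthly averages) or
#'   `"sum"`.
#' @return Tibble `year`, `value`; `NA` value (with a message) where any
#'   month in the window is missing from `climate`.
#' @export
aggregate_window <- function(climate, site, variable, open_lag, close_lag,
                             years, reference_month = 6L,
                             aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (close_lag > open_lag) abort("close_lag must be <= open_lag")
  sub <- dplyr::filter(tibble::as_tibble(climate), .data$site == !!site)
  if (!variable %in% names(sub)) abort(paste0("unknown variable: ", variable))
  key <- 12L * sub$year + (sub$month - 1L)
  vals <- setNames(sub[[variable]], key)
  lags <- seq(close_lag, open_lag)
  agg <- vapply(years, function(y) {
    idx <- 12L * y + (reference_month - 1L) - lags
    v <- vals[as.character(idx)]
    if (anyNA(v)) return(NA_real_)
    if (aggregate == "mean") mean(v) else sum(v)
  }, numeric(1))
  n_miss <- sum(is.na(agg))
  if (n_miss > 0) {
    inform(paste0("window aggregate missing for ", n_miss, " year(s)"))
  }
  tibble::tibble(year = years, value = agg)
}

# Gaussian AICc for an OLS fit. k counts the residual variance as a
# parameter, matching likelihood-based information criteria.
aicc_ols <- function(rss, n, k) {
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  aic <- -2 * ll + 2 * k
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Score one candidate window against an annual response
#'
#' Ordinary least squares of the annual response on the window aggregate,
#' compared by small-sample-corrected AICc against the intercept-only null
#' fitted to the same years. Negative `delta_aicc` favours the window.
#'
#' @param data Data frame with the response and aggregate columns.
#' @param response,aggregate Column names (strings) of the annual response
#'   and the window aggregate.
#' @param criterion `"aicc"` (default) or plain `"aic"`.
#' @return One-row tibble: `slope`, `intercept`, `delta_aicc`, `n_years`,
#'   `zero_variance` flag. A zero-variance aggregate yields `delta_aicc = Inf`.
#' @export
fit_window_model <- function(data, response = "response",
                             aggregate = "value",
                             criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  y <- data[[response]]
  x <- data[[aggregate]]
  keep <- complete.cases(y, x)
  y <- y[keep]
  x <- x[keep]
  n <- length(y)
  if (n < 5) abort("need at least 5 complete (response, aggregate) years")
  if (sd(x) == 0) {
    warn("zero-variance window aggregate")
    return(tibble::tibble(
      slope = NA_real_, intercept = NA_real_, delta_aicc = Inf,
      n_years = n, zero_variance = TRUE
    ))
  }
  xm <- mean(x)
  ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  rss1 <- sum((y - intercept - slope * x)^2)
  rss0 <- sum((y - ym)^2)
  aic_ols <- function(rss, k) n * (log(2 * pi * rss / n) + 1) + 2 * k
  if (criterion == "aicc") {
    ic1 <- aicc_ols(rss1, n, 3)
    ic0 <- aicc_ols(rss0, n, 2)
  } else {
    ic1 <- aic_ols(rss1, 3)
    ic0 <- aic_ols(rss0, 2)
  }
  tibble::tibble(
    slope = slope, intercept = intercept, delta_aicc = ic1 - ic0,
    n_years = n, zero_variance = FALSE
  )
}

#' Sliding-window scan of climate predictors for an annual response
#'
#' Enumerates every contiguous monthly window up to `max_lag` months before
#' the reference month, for every requested site and climate variable,
#' aggregates the monthly series over each window, and scores it against the
#' annual response by AICc relative to the no-climate null. The scan is
#' deterministic and exploratory: it ranks candidates but never chooses for
#' you (see [select_top_windows()]).
#'
#' @inheritParams aggregate_window
#' @param response Tibble with `year` and `value` columns (e.g. growth rate
#'   or annual mean fledglings).
#' @param sites Sites to scan (default: all in `climate`).
#' @param variables Climate variables to scan.
#' @param max_lag Maximum lag in months (default 12, i.e. 13 monthly anchors
#'   back to the reference month of the previous year).
#' @param criterion Information criterion, `"aicc"` or `"aic"`.
#' @return Tibble with one row per (site, variable, window), columns
#'   `site`, `variable`, `open_lag`, `close_lag`, `length`, `slope`,
#'   `intercept`, `delta_aicc`, `n_years`, ranked by `delta_aicc` (ties:
#'   shorter window, then more recent close).
#' @export
scan_climate_windows <- function(climate, response, sites = NULL,
                                 variables = c("temperature", "precipitation"),
                                 max_lag = 12L, reference_month = 6L,
                                 aggregate = "mean",
                                 criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  climate <- tibble::as_tibble(climate)
  response <- tibble::as_tibble(response)
  sites <- sites %||% unique(climate$site)
  grid <- tidyr::expand_grid(
    site = sites, variable = variables, enumerate_windows(max_lag)
  )
  res <- purrr::pmap(grid, function(site, variable, open_lag, close_lag, length) {
    agg <- aggregate_window(
      climate, site, variable, open_lag, close_lag,
      years = response$year, reference_month = reference_month,
      aggregate = aggregate
    )
    dat <- dplyr::inner_join(response, agg, by = "year",
                             suffix = c("_resp", ""))
    fit_window_model(dat, response = "value_resp", aggregate = "value",
                     criterion = criterion)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  dplyr::arrange(out, .data$delta_aicc, .data$length, .data$close_lag)
}

#' Best window per site and variable
#'
#' Extracts the top-ranked window for each (site, variable) pair from a scan
#' table. The scan may overfit, so this helper is a convenience for building
#' an explicit selection — the model-fitting stages require you to pass the
#' chosen windows yourself (or set `auto = TRUE` in the pipeline config to
#' acknowledge automatic selection).
#'
#' @param scan Result of [scan_climate_windows()].
#' @param n Number of top windows to keep per (site, variable).
#' @return Tibble of selected windows in scan order.
#' @export
select_top_windows <- function(scan, n = 1) {
  scan |>
    dplyr::arrange(.data$delta_aicc, .data$length, .data$close_lag) |>
    dplyr::group_by(.data$site, .data$variable) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$delta_aicc)
}

#' Heatmap of a window scan
#'
#' ΔAICc for every candidate window, one panel per site and variable, with
#' window opening on the x axis and closing on the y axis. More negative
#' (darker) panels indicate windows that out-predict the null model.
#'
#' @param scan Result of [scan_climate_windows()].
#' @return A ggplot object.
#' @export
plot_window_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(
    x = .data$open_lag, y = .data$close_lag, fill = .data$delta_aicc
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(site ~ variable) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "window opens (months before reference)",
      y = "window closes (months before reference)",
      fill = expression(Delta * "AICc")
    ) +
    ggplot2::theme_minimal()
}
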