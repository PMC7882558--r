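#' Read pipeline input tables
#'
#' Thin CSV readers for the three inputs the pipeline consumes: annual nest-box
#' counts, nest-level breeding records, and monthly climate. Files are
#' comma-separated UTF-8 with '.' as the decimal separator. Short headers used
#' on disk (`surveyed`, `focal`, `parid`, `label`, `temp`, `precip`) are mapped
#' to the longer column names used throughout the package.
#'
#' @param path Path to a CSV file.
#' @param strict Validate strictly (errors instead of warnings)?
#' @return A tibble; see [validate_annual_counts()] and friends for the
#'   column contracts.
#' @name readers
NULL

#' @rdname readers
#' @export
read_annual_counts <- function(path, strict = FALSE) {
  df <- tibble::as_tibble(read.csv(path, fileEncoding = "UTF-8"))
  map <- c(
    surveyed = "boxes_surveyed", focal = "boxes_focal",
    parid = "boxes_parid", label = "population_label"
  )
  names(df) <- ifelse(names(df) %in% names(map), map[names(df)], names(df))
  validate_annual_counts(df, strict = strict)
}

#' @rdname readers
#' @param relaxed Allow `fledglings > clutch_size` (raw Gaussian synthetic
#'   output); see [validate_nest_records()].
#' @export
read_nest_records <- function(path, strict = FALSE, relaxed = FALSE) {
  df <- tibble::as_tibble(read.csv(path, fileEncoding = "UTF-8"))
  names(df)[names(df) == "clutch"] <- "clutch_size"
  validate_nest_records(df, strict = strict, relaxed = relaxed)
}

#' @rdname readers
#' @export
read_monthly_climate <- function(path, strict = FALSE) {
  df <- tibble::as_tibble(read.csv(path, fileEncoding = "UTF-8"))
  map <- c(temp = "temperature", precip = "precipitation")
  names(df) <- ifelse(names(df) %in% names(map), map[names(df)], names(df))
  validate_monthly_climate(df, strict = strict)
}

flag_or_fail <- function(bad, msg, strict) {
  if (any(bad, na.rm = TRUE)) {
    if (strict) abort(msg) else warn(msg)
  }
  invisible(NULL)
}

#' Validate input tables
#'
#' Checks the structural invariants of the three input tables. By default
#' violations raise warnings so that exploratory work can continue; with
#' `strict = TRUE` they are errors.
#'
#' Annual counts require columns `year`, `boxes_surveyed`, `boxes_focal`,
#' `boxes_parid` (and optionally `population_label`), with
#' `boxes_focal + boxes_parid <= boxes_surveyed`, positive `boxes_surveyed`,
#' and years unique within a population label. Nest records require `year`,
#' `hatch_date`, `clutch_size` (>= 1), `fledglings` (>= 0, and
#' `<= clutch_size` unless `relaxed`), `nest_temp`, `nest_precip`. Monthly
#' climate requires one record per `(site, year, month)` with month in 1..12.
#'
#' @param counts,nests,climate The table to validate.
#' @param strict Escalate violations to errors?
#' @param relaxed Allow `fledglings > clutch_size` (used for raw Gaussian
#'   synthetic output, where counts are unconstrained draws).
#' @return The validated tibble, invisibly unchanged.
#' @name validators
NULL

#' @rdname validators
#' @export
validate_annual_counts <- function(counts, strict = FALSE) {
  counts <- tibble::as_tibble(counts)
  need <- c("year", "boxes_surveyed", "boxes_focal", "boxes_parid")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(paste0("annual counts missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"population_label" %in% names(counts)) counts$population_label <- "pop"
  flag_or_fail(counts$boxes_surveyed <= 0,
               "boxes_surveyed must be positive", strict)
  flag_or_fail(
    counts$boxes_focal + counts$boxes_parid > counts$boxes_surveyed,
    "boxes_focal + boxes_parid exceeds boxes_surveyed", strict
  )
  dup <- duplicated(counts[c("population_label", "year")])
  flag_or_fail(dup, "duplicated year within a population label", strict)
  counts
}

#' @rdname validators
#' @export
validate_nest_records <- function(nests, strict = FALSE, relaxed = FALSE) {
  nests <- tibble::as_tibble(nests)
  need <- c("year", "hatch_date", "clutch_size", "fledglings",
            "nest_temp", "nest_precip")
  missing_cols <- setdiff(need, names(nests))
  if (length(missing_cols)) {
    abort(paste0("nest records missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  flag_or_fail(!is.finite(nests$hatch_date), "non-finite hatch_date", strict)
  flag_or_fail(nests$clutch_size < 1, "clutch_size below 1", strict)
  flag_or_fail(nests$fledglings < 0, "negative fledgling count", strict)
  if (!relaxed) {
    flag_or_fail(nests$fledglings > nests$clutch_size,
                 "fledglings exceed clutch_size", strict)
  }
  nests
}

#' @rdname validators
#' @export
validate_monthly_climate <- function(climate, strict = FALSE) {
  climate <- tibble::as_tibble(climate)
  need <- c("site", "year", "month", "temperature", "precipitation")
  missing_cols <- setdiff(need, names(climate))
  if (length(missing_cols)) {
    abort(paste0("monthly climate missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  flag_or_fail(!climate$month %in% 1:12, "month outside 1..12", strict)
  dup <- duplicated(climate[c("site", "year", "month")])
  flag_or_fail(dup, "duplicated (site, year, month) record", strict)
  climate
}

#' Density index from nest-box occupancy
#'
#' The annual population density index is the percentage of nest boxes
#' available to the focal species that it actually occupied. Boxes taken by
#' Parids (tits) are not available, so the index is
#' `100 * boxes_focal / (boxes_surveyed - boxes_parid)`.
#'
#' @param counts Annual counts table (see [validate_annual_counts()]).
#' @return `counts` with a `density_index` column appended (percent, 0-100).
#' @examples
#' counts <- tibble::tibble(
#'   year = 1941:1943, boxes_surveyed = c(110, 100, 113),
#'   boxes_focal = c(50, 0, 47), boxes_parid = c(10, 0, 13)
#' )
#' compute_density_index(counts)$density_index
#' @export
compute_density_index <- function(counts) {
  counts <- validate_annual_counts(counts)
  avail <- counts$boxes_surveyed - counts$boxes_parid
  if (any(avail <= 0)) {
    bad <- counts$year[avail <= 0]
    abort(paste0(
      "no nest boxes available to the focal species in year(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  dplyr::mutate(counts, density_index = 100 * .data$boxes_focal / avail)
}

#' Annual population growth rate
#'
#' Growth rate is the log-difference of the density index,
#' `R_t = ln(N_t) - ln(N_{t-1})` (natural log). It is only defined when both
#' years of a consecutive pair are observed; across year gaps it is `NA`.
#'
#' @param series Annual table with `year` and `density_index` columns.
#' @return `series` sorted by year with a `growth_rate` column appended.
#' @export
compute_growth_rate <- function(series) {
  series <- dplyr::arrange(tibble::as_tibble(series), .data$year)
  n <- series$density_index
  if (any(!is.na(n) & n <= 0)) {
    abort("density_index must be positive to take logs")
  }
  lag_ok <- c(FALSE, diff(series$year) == 1)
  r <- log(n) - log(dplyr::lag(n))
  r[!lag_ok] <- NA_real_
  skipped <- sum(!lag_ok[-1])
  if (skipped > 0) {
    inform(paste0("growth rate undefined across ", skipped, " year gap(s)"))
  }
  dplyr::mutate(series, growth_rate = r)
}

#' Merge two annual series from different study areas
#'
#' Takes the union over years of two annual tables; where both observe the
#' same year, the record from the preferred population is kept (for these
#' data, the larger later study area). Years present in neither series remain
#' absent and propagate as gaps (so downstream growth rates across them are
#' `NA`).
#'
#' @param a,b Annual tables carrying a `population_label` column.
#' @param prefer `population_label` whose records win in overlapping years.
#' @return One annual tibble sorted by year.
#' @export
merge_series <- function(a, b, prefer) {
  both <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b))
  if (nrow(both) == 0) return(both)
  if (!"population_label" %in% names(both)) {
    abort("merge_series needs a population_label column")
  }
  both |>
    dplyr::mutate(.pref = .data$population_label == prefer) |>
    dplyr::arrange(.data$year, dplyr::desc(.data$.pref)) |>
    dplyr::distinct(.data$year, .keep_all = TRUE) |>
    dplyr::select(-".pref")
}

#' Correlation between focal and competitor occupancy
#'
#' Tests whether the focal species' occupancy rate tracks Parid occupancy
#' (which would mean box availability depends on the competitor). Pearson
#' correlation with a two-sided test.
#'
#' @param series_focal,series_parid Numeric vectors of paired annual rates, or
#'   data frames with `year` and `value` columns (joined on year).
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
occupancy_independence <- function(series_focal, series_parid) {
  if (is.data.frame(series_focal)) {
    joined <- dplyr::inner_join(
      tibble::as_tibble(series_focal), tibble::as_tibble(series_parid),
      by = "year", suffix = c("_focal", "_parid")
    )
    x <- joined$value_focal
    y <- joined$value_parid
  } else {
    x <- series_focal
    y <- series_parid
  }
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired years")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in an occupancy series")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Annual means of nest-level breeding variables
#'
#' Collapses the nest table to per-year arithmetic means of fledgling count,
#' hatch date, and clutch size — the annual covariates the growth-rate model
#' uses. Years with no nests are simply absent (missing downstream).
#'
#' @param nests Nest records table.
#' @return Tibble: `year`, `mean_fledglings`, `mean_hatch_date`,
#'   `mean_clutch`, `n_nests`.
#' @export
annual_summaries <- function(nests) {
  tibble::as_tibble(nests) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      mean_fledglings = mean(.data$fledglings),
      mean_hatch_date = mean(.data$hatch_date),
      mean_clutch = mean(.data$clutch_size),
      n_nests = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
}

#' Assemble the annual series used by the growth-rate model
#'
#' Convenience wrapper: density index, growth rate, and annual breeding means
#' in one table. Gap years between the first and last observed year are
#' materialised as all-`NA` rows so that lagging is well defined downstream.
#'
#' @param counts Annual counts table.
#' @param nests Optional nest records table for the breeding means.
#' @return Annual tibble with one row per calendar year in the observed span.
#' @export
build_annual_series <- function(counts, nests = NULL) {
  series <- compute_density_index(counts)
  series <- tidyr::complete(series, year = tidyr::full_seq(series$year, 1))
  series <- compute_growth_rate(series)
  if (!is.null(nests)) {
    series <- dplyr::left_join(series, annual_summaries(nests), by = "year")
  }
  series
}
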