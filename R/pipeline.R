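#' Assemble a pipeline configuration
#'
#' One object drives the whole analysis: data sources (a generator
#' configuration, or paths to the three input CSVs), window-scan settings,
#' the window selection rule, sampler controls, an output directory and a
#' seed. Window selection is never silently automatic: either name the
#' windows explicitly via `selected_windows`, or set `auto_select = TRUE`
#' to acknowledge that the exploratory scan's top windows (re-estimated
#' per role from the scan) will be used.
#'
#' @param generator A [generator_config()], or `NULL` when reading CSVs.
#' @param counts_file,nests_file,climate_file Input CSV paths (ignored when
#'   `generator` is given).
#' @param selected_windows Tibble (`role`, `site`, `variable`, `open_lag`,
#'   `close_lag`) naming the windows passed to the structural models. Roles
#'   `med_winter_temp`, `eur_spring_precip`, `afr_autumn_precip` feed the
#'   growth model; `eur_winter_temp`, `afr_winter_temp` feed the
#'   nest-production model.
#' @param auto_select Allow automatic per-role re-selection of window lags
#'   from the scan (explicit opt-in).
#' @param max_lag,reference_month,criterion Scan settings.
#' @param chains,iter_rdsem,iter_msem Sampler controls.
#' @param out_dir Output directory for the report bundle (`NULL` for none).
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `climpaths_pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, counts_file = NULL,
                            nests_file = NULL, climate_file = NULL,
                            selected_windows = NULL, auto_select = FALSE,
                            max_lag = 12L, reference_month = 6L,
                            criterion = "aicc", chains = 2,
                            iter_rdsem = 1000, iter_msem = 1500,
                            out_dir = NULL, seed = 1) {
  structure(
    list(generator = generator, counts_file = counts_file,
         nests_file = nests_file, climate_file = climate_file,
         selected_windows = selected_windows, auto_select = auto_select,
         max_lag = max_lag, reference_month = reference_month,
         criterion = criterion, chains = chains, iter_rdsem = iter_rdsem,
         iter_msem = iter_msem, out_dir = out_dir, seed = seed),
    class = "climpaths_pipeline_config"
  )
}

default_selected_windows <- function() {
  dplyr::select(default_windows(), "role", "site", "variable",
                "open_lag", "close_lag")
}

#' Run the full analysis pipeline
#'
#' Stages: data preparation (density index, growth rate, annual breeding
#' means), the sliding-window scan for both annual responses, window
#' selection (explicit or acknowledged-automatic), the residual dynamic
#' growth-rate model with AR pruning, the two-level nest-production model
#' with effect decomposition and simple slopes, and a report bundle of tidy
#' CSVs. Each stage's output is a pure function of the configuration and
#' inputs; reruns with the same seed reproduce the summaries exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's outputs (`series`,
#'   `scan_growth`, `scan_fledglings`, `selected`, `rdsem`,
#'   `rdsem_effects`, `msem`, `msem_effects`, `slopes`, `convergence`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "climpaths_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  # --- load or generate -------------------------------------------------
  inputs <- stage("load", {
    if (!is.null(config$generator)) {
      gen_full_dataset(config$generator)
    } else {
      list(
        counts = read_annual_counts(config$counts_file),
        nests = read_nest_records(config$nests_file),
        climate = read_monthly_climate(config$climate_file)
      )
    }
  })
  # --- prep -------------------------------------------------------------
  series <- stage("prep", build_annual_series(inputs$counts, inputs$nests))
  # --- scan -------------------------------------------------------------
  growth_resp <- tibble::tibble(year = series$year,
                                value = series$growth_rate)
  fled_resp <- tibble::tibble(year = series$year,
                              value = series$mean_fledglings)
  scan_growth <- stage("scan", scan_climate_windows(
    inputs$climate, growth_resp, max_lag = config$max_lag,
    reference_month = config$reference_month, criterion = config$criterion
  ))
  scan_fled <- stage("scan", scan_climate_windows(
    inputs$climate, fled_resp, max_lag = config$max_lag,
    reference_month = config$reference_month, criterion = config$criterion
  ))
  # --- window selection (explicit, or acknowledged-automatic) -----------
  selected <- stage("select", {
    if (!is.null(config$selected_windows)) {
      config$selected_windows
    } else if (config$auto_select) {
      roles <- default_selected_windows()
      purrr::map_dfr(seq_len(nrow(roles)), function(i) {
        r <- roles[i, ]
        scan <- if (r$role %in% c("eur_winter_temp", "afr_winter_temp"))
          scan_fled else scan_growth
        best <- scan |>
          dplyr::filter(.data$site == r$site, .data$variable == r$variable) |>
          dplyr::slice(1)
        tibble::tibble(role = r$role, site = r$site, variable = r$variable,
                       open_lag = best$open_lag, close_lag = best$close_lag)
      })
    } else {
      abort(paste0(
        "no selected_windows given and auto_select is FALSE; the scan is ",
        "exploratory, so the windows entering the models must be named ",
        "explicitly (or auto-selection acknowledged)"
      ))
    }
  })
  missing_sites <- setdiff(selected$site, unique(inputs$climate$site))
  if (length(missing_sites)) {
    abort(paste0("selected windows reference unknown site(s): ",
                 paste(missing_sites, collapse = ", ")))
  }
  # --- growth model -----------------------------------------------------
  rdsem_fit <- stage("rdsem", {
    ser <- attach_climate_covariates(
      series, inputs$climate,
      selected[selected$role %in% c("med_winter_temp", "eur_spring_precip",
                                    "afr_autumn_precip"), ],
      reference_month = config$reference_month
    )
    spec <- build_rdsem(ser)
    prune_ar_terms(spec, chains = config$chains, iter = config$iter_rdsem,
                   seed = config$seed)
  })
  rdsem_effects <- fledgling_lag2_effects(rdsem_fit)
  # --- nest-production model --------------------------------------------
  msem_fit <- stage("msem", {
    bet <- attach_climate_covariates(
      tibble::tibble(year = sort(unique(inputs$nests$year))), inputs$climate,
      selected[selected$role %in% c("eur_winter_temp", "afr_winter_temp"), ],
      reference_month = config$reference_month
    )
    spec <- build_msem(inputs$nests, bet)
    fit_msem(spec, chains = config$chains, iter = config$iter_msem,
             seed = config$seed + 1L)
  })
  msem_effects <- decompose_effects(msem_fit)
  slopes <- simple_slopes(msem_fit)
  convergence <- dplyr::bind_rows(
    dplyr::mutate(glance(rdsem_fit), model = "rdsem", .before = 1)[
      , c("model", "max_rhat", "converged")],
    dplyr::mutate(glance(msem_fit), model = "msem", .before = 1)[
      , c("model", "max_rhat", "converged")]
  )
  out <- list(
    series = series, scan_growth = scan_growth, scan_fledglings = scan_fled,
    selected = selected, rdsem = rdsem_fit, rdsem_effects = rdsem_effects,
    msem = msem_fit, msem_effects = msem_effects, slopes = slopes,
    convergence = convergence
  )
  # --- report bundle ----------------------------------------------------
  if (!is.null(config$out_dir)) {
    stage("report", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      w <- function(x, f) write.csv(x, file.path(config$out_dir, f),
                                    row.names = FALSE)
      w(series, "annual_series.csv")
      w(scan_growth, "window_scan_growth.csv")
      w(scan_fled, "window_scan_fledglings.csv")
      jsonlite::write_json(selected, file.path(config$out_dir,
                                               "selected_windows.json"),
                           auto_unbox = TRUE, digits = NA)
      w(tidy(rdsem_fit), "rdsem_summary.csv")
      w(rdsem_fit$drop_log, "rdsem_drop_log.csv")
      w(rdsem_effects, "rdsem_effects.csv")
      w(tidy(msem_fit), "msem_summary.csv")
      w(msem_effects, "msem_effects.csv")
      w(slopes, "simple_slopes.csv")
      w(convergence, "convergence.csv")
      writeLines(c(
        paste0("climpaths ", as.character(utils::packageVersion("climpaths"))),
        paste0("R ", R.version.string),
        paste0("seed ", config$seed),
        paste0("date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
      ), file.path(config$out_dir, "run_log.txt"))
    })
  }
  invisible(out)
}
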