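#' Pipeline configuration
#'
#' Collects every setting of the end-to-end collocation pipeline: the per-unit
#' calibration table, which conversions to report, the dual-channel QC
#' thresholds, the daily completeness rule, exclusion windows, and reporting
#' periods.
#'
#' @param calibrations Calibration tibble (see [read_calibrations()]). Units
#'   without a row fall back to the default woodsmoke conversion.
#' @param conversions Conversions to evaluate against the reference; any of
#'   `"woodsmoke"` (per-unit linear cf1 calibration, default where unfitted),
#'   `"alt34"` (count-based, no calibration) and `"usepa"` (humidity-adjusted).
#' @param ad_abs_threshold,ad_frac_threshold Channel discordance thresholds
#'   passed to [fuse_channels()].
#' @param min_hours Daily completeness rule passed to [hourly_to_daily()].
#' @param exclusions Exclusion-window tibble (see [exclusion_windows()]);
#'   `NULL` for none.
#' @param periods Built-in reporting periods: `"all"` (every valid day) and/or
#'   `"apr_sep"` (April-September, the wood-heating months).
#' @param custom_periods Optional tibble with `label`, `start_date`,
#'   `end_date` adding further reporting periods.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(calibrations = read_calibrations(),
                            conversions = c("woodsmoke", "alt34"),
                            ad_abs_threshold = 10,
                            ad_frac_threshold = 0.5,
                            min_hours = 23,
                            exclusions = default_exclusions(),
                            periods = c("all", "apr_sep"),
                            custom_periods = NULL) {
  conversions <- match.arg(conversions, c("woodsmoke", "alt34", "usepa"),
                           several.ok = TRUE)
  periods <- match.arg(periods, c("all", "apr_sep"), several.ok = TRUE)
  if (min_hours < 0 || min_hours > 24) {
    rlang::abort("`min_hours` must lie in [0, 24].",
                 class = "pacolloc_invalid_input")
  }
  structure(list(calibrations = calibrations, conversions = conversions,
                 ad_abs_threshold = ad_abs_threshold,
                 ad_frac_threshold = ad_frac_threshold,
                 min_hours = min_hours, exclusions = exclusions,
                 periods = periods, custom_periods = custom_periods),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `calibrations` (inline table, as in the packaged
#' `calibrations.yaml`), `conversions`, `qc: {ad_abs_threshold,
#' ad_frac_threshold}`, `min_hours`, `exclusions` (list of `label`/`start`/
#' `end`), `periods`, `custom_periods`. Omitted keys take the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cal <- if (!is.null(raw$calibrations)) {
    dplyr::bind_rows(lapply(names(raw$calibrations), function(id) {
      e <- raw$calibrations[[id]]
      tibble::tibble(unit_id = id, intercept = as.numeric(e$intercept),
                     slope = as.numeric(e$slope),
                     source = e$source %||% "fitted_2018")
    }))
  } else {
    read_calibrations()
  }
  excl <- if (!is.null(raw$exclusions)) {
    dplyr::bind_rows(lapply(raw$exclusions, function(w) {
      exclusion_windows(w$label, w$start, w$end)
    }))
  } else {
    default_exclusions()
  }
  custom <- if (!is.null(raw$custom_periods)) {
    dplyr::bind_rows(lapply(raw$custom_periods, function(w) {
      tibble::tibble(label = w$label,
                     start_date = lubridate::as_date(w$start),
                     end_date = lubridate::as_date(w$end))
    }))
  } else {
    NULL
  }
  pipeline_config(
    calibrations = cal,
    conversions = as.character(unlist(raw$conversions %||% c("woodsmoke", "alt34"))),
    ad_abs_threshold = raw$qc$ad_abs_threshold %||% 10,
    ad_frac_threshold = raw$qc$ad_frac_threshold %||% 0.5,
    min_hours = raw$min_hours %||% 23,
    exclusions = excl,
    periods = as.character(unlist(raw$periods %||% c("all", "apr_sep"))),
    custom_periods = custom
  )
}

# per-channel PM2.5 at record level for one unit under one conversion
.convert_records <- function(records, conversion, cal) {
  pm <- switch(
    conversion,
    woodsmoke = list(a = apply_linear_calibration(records$cf1_a, cal),
                     b = apply_linear_calibration(records$cf1_b, cal)),
    alt34 = list(a = alt34(records$n_gt_0p3_a, records$n_gt_0p5_a,
                           records$n_gt_1_a, records$n_gt_2p5_a),
                 b = alt34(records$n_gt_0p3_b, records$n_gt_0p5_b,
                           records$n_gt_1_b, records$n_gt_2p5_b)),
    usepa = list(a = usepa_conversion(records$cf1_a, records$rh),
                 b = usepa_conversion(records$cf1_b, records$rh)),
    rlang::abort(sprintf("Unknown conversion '%s'.", conversion),
                 class = "pacolloc_invalid_input")
  )
  # fusion requires non-negative channel values; the USEPA form can dip
  # below zero at high RH and low cf1
  records$pm_a <- pmax(0, pm$a)
  records$pm_b <- pmax(0, pm$b)
  records
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
                 class = "pacolloc_pipeline_error", parent = e)
  })
}

#' Run the end-to-end collocation pipeline
#'
#' For each configured conversion: convert every unit's 2-minute records to
#' per-channel PM2.5, aggregate to hourly means by interval midpoint, fuse
#' the two channels with the discordance rule, average the fused series
#' across units, aggregate to complete days, mark exclusion windows, pair
#' with the reference daily series, and compute collocation statistics for
#' each reporting period. Deterministic given its inputs.
#'
#' @param config A [pipeline_config()].
#' @param pa Named list of unit record tibbles (as from [simulate_pa_unit()]
#'   or [read_pa_csv()]); names are unit ids used for calibration lookup.
#' @param reference Hourly reference tibble with `timestamp` and `pm25`
#'   (as from [simulate_teom_fdms()] or [read_reference_csv()]).
#' @return A list with `stats` (one row per conversion x period:
#'   [collocation_stats()] columns plus `period` and `conversion`) and
#'   `daily` (wide daily table: `date`, `ref`, one column per conversion).
#' @export
run_pipeline <- function(config, pa, reference) {
  if (is.null(names(pa)) || any(names(pa) == "")) {
    rlang::abort("`pa` must be a named list of unit record tibbles.",
                 class = "pacolloc_invalid_input")
  }

  ref_daily <- .with_stage("reference_aggregation", {
    reference |>
      dplyr::rename(hour_start = timestamp) |>
      hourly_to_daily(min_hours = config$min_hours) |>
      apply_exclusions(config$exclusions)
  })

  daily_by_conv <- lapply(config$conversions, function(conv) {
    unit_hourly <- lapply(names(pa), function(u) {
      cal <- .with_stage(
        "calibration_lookup",
        if (conv == "woodsmoke") lookup_calibration(u, config$calibrations)
        else default_woodsmoke_calibration())
      .with_stage(paste0("unit_processing:", u), {
        pa[[u]] |>
          .convert_records(conv, cal) |>
          records_to_hourly(cols = c(pm_a, pm_b)) |>
          fuse_channels(config$ad_abs_threshold, config$ad_frac_threshold) |>
          dplyr::select(hour_start, pm25)
      })
    })
    .with_stage("site_aggregation", {
      dplyr::bind_rows(unit_hourly) |>
        dplyr::group_by(hour_start) |>
        dplyr::summarise(pm25 = mean(pm25), .groups = "drop") |>
        hourly_to_daily(min_hours = config$min_hours) |>
        apply_exclusions(config$exclusions)
    })
  })
  names(daily_by_conv) <- config$conversions

  period_table <- tibble::tibble(label = character(), months = list(),
                                 start_date = as.Date(character()),
                                 end_date = as.Date(character()))
  if ("all" %in% config$periods) {
    period_table <- dplyr::add_row(period_table, label = "all",
                                   months = list(1:12),
                                   start_date = as.Date(NA), end_date = as.Date(NA))
  }
  if ("apr_sep" %in% config$periods) {
    period_table <- dplyr::add_row(period_table, label = "apr_sep",
                                   months = list(4:9),
                                   start_date = as.Date(NA), end_date = as.Date(NA))
  }
  if (!is.null(config$custom_periods)) {
    for (i in seq_len(nrow(config$custom_periods))) {
      period_table <- dplyr::add_row(
        period_table, label = config$custom_periods$label[i],
        months = list(1:12),
        start_date = config$custom_periods$start_date[i],
        end_date = config$custom_periods$end_date[i])
    }
  }

  stats <- .with_stage("comparison_stats", {
    rows <- list()
    for (conv in config$conversions) {
      for (i in seq_len(nrow(period_table))) {
        cand <- daily_by_conv[[conv]]
        keep <- lubridate::month(cand$date) %in% period_table$months[[i]]
        if (!is.na(period_table$start_date[i])) {
          keep <- keep & cand$date >= period_table$start_date[i] &
            cand$date <= period_table$end_date[i]
        }
        row <- tryCatch({
          pairs <- paired_days(ref_daily, cand[keep, , drop = FALSE])
          dplyr::bind_cols(
            tibble::tibble(period = period_table$label[i], conversion = conv),
            collocation_stats(pairs))
        }, pacolloc_empty_intersection = function(e) {
          rlang::warn(
            sprintf("Period '%s' (%s): no overlapping days; row skipped.",
                    period_table$label[i], conv),
            class = "pacolloc_empty_period")
          NULL
        })
        if (!is.null(row)) rows[[length(rows) + 1]] <- row
      }
    }
    if (length(rows) == 0) {
      rlang::abort("No reporting period had overlapping days.",
                   class = "pacolloc_empty_intersection")
    }
    dplyr::bind_rows(rows)
  })

  daily_wide <- ref_daily |>
    dplyr::filter(complete, !excluded) |>
    dplyr::select(date, ref = pm25)
  for (conv in config$conversions) {
    d <- daily_by_conv[[conv]] |>
      dplyr::filter(complete, !excluded) |>
      dplyr::select(date, pm25)
    names(d)[2] <- conv
    daily_wide <- dplyr::full_join(daily_wide, d, by = "date")
  }
  daily_wide <- dplyr::arrange(daily_wide, date)

  list(stats = stats, daily = daily_wide)
}

#' Format a collocation statistics table as readable text
#'
#' @param stats The `stats` tibble from [run_pipeline()].
#' @return A character vector of report lines.
#' @export
format_report <- function(stats) {
  hdr <- sprintf("%-10s %-10s %5s %6s %6s %6s %6s %6s %8s %8s %8s",
                 "period", "conversion", "n", "r", "r_se", "rmse",
                 "rma", "ols", "ols_int", "mean_ref", "mean_pa")
  rows <- vapply(seq_len(nrow(stats)), function(i) {
    sprintf("%-10s %-10s %5d %6.3f %6.3f %6.2f %6.2f %6.2f %8.2f %8.2f %8.2f",
            stats$period[i], stats$conversion[i], stats$n_days[i],
            stats$r[i], stats$r_se[i], stats$rmse[i], stats$rma_slope[i],
            stats$ols_slope[i], stats$ols_intercept[i], stats$mean_ref[i],
            stats$mean_cand[i])
  }, character(1))
  c(hdr, rows)
}

#' Write pipeline outputs to a directory
#'
#' Writes `collocation_stats.csv`, `daily_pm25.csv` and a pretty-text
#' `report.txt`. Output is byte-identical for identical inputs.
#'
#' @param result The list returned by [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(result$stats, file.path(dir, "collocation_stats.csv"),
                   progress = FALSE)
  readr::write_csv(result$daily, file.path(dir, "daily_pm25.csv"),
                   progress = FALSE)
  writeLines(format_report(result$stats), file.path(dir, "report.txt"))
  invisible(dir)
}
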