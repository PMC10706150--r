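#' Aggregate 2-min sensor records to hourly means
#'
#' Each record is assigned to the clock hour containing the midpoint of its
#' reporting interval, so a record spanning 23:58:59-00:00:59 (midpoint
#' 23:59:59) counts in the 23:00 hour. Hourly values are unweighted means of
#' the assigned records; hours with no records are absent from the output.
#'
#' All timestamps are local standard time (no daylight-saving shifts).
#'
#' @param records A data frame with POSIXct columns `timestamp_start` and
#'   `timestamp_end`, time-sorted, plus numeric measurement columns.
#' @param cols Tidy-selection of the columns to average; defaults to every
#'   numeric column.
#' @return A tibble with `hour_start` (POSIXct, whole hours), the hourly mean
#'   of each selected column (`NA` values within an hour are ignored), and
#'   `n_records`.
#' @export
records_to_hourly <- function(records, cols = NULL) {
  if (!all(c("timestamp_start", "timestamp_end") %in% names(records))) {
    rlang::abort("`records` needs `timestamp_start` and `timestamp_end` columns.",
                 class = "pacolloc_schema_error")
  }
  ts <- records$timestamp_start
  if (is.unsorted(ts)) {
    bad <- which(diff(as.numeric(ts)) < 0)
    rlang::abort(
      sprintf("Records must be time-sorted; out-of-order at row(s): %s",
              paste(utils::head(bad + 1, 5), collapse = ", ")),
      class = "pacolloc_unsorted_records")
  }
  dup <- which(duplicated(ts))
  if (length(dup) > 0) {
    rlang::abort(
      sprintf("Duplicate record start times at row(s): %s",
              paste(utils::head(dup, 5), collapse = ", ")),
      class = "pacolloc_duplicate_records")
  }
  cols <- rlang::enquo(cols)
  if (rlang::quo_is_null(cols)) {
    cols <- rlang::quo(dplyr::where(is.numeric))
  }
  midpoint <- ts + as.numeric(difftime(records$timestamp_end, ts,
                                       units = "secs")) / 2
  records |>
    dplyr::mutate(hour_start = lubridate::floor_date(midpoint, "hour")) |>
    dplyr::group_by(hour_start) |>
    dplyr::summarise(
      dplyr::across(!!cols, ~ mean(.x, na.rm = TRUE)),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ ifelse(is.nan(.x), NA_real_, .x)))
}

#' Aggregate hourly values to daily means under a completeness rule
#'
#' Daily means are computed over valid hours only; days with fewer than
#' `min_hours` valid hourly values are flagged incomplete and carry no daily
#' value. The default of 23 is stricter than the common 18-hour practice:
#' in woodsmoke-affected areas the evening peak dominates the daily mean, so
#' a day missing several evening hours is not comparable.
#'
#' @param hourly A data frame with `hour_start` (POSIXct, whole hours) and the
#'   value column. Negative values (possible for reference instruments) are
#'   retained.
#' @param value_col Name of the value column (default `"pm25"`).
#' @param min_hours Minimum number of valid hours for a complete day
#'   (0-24, default 23); `min_hours = 0` gives a plain calendar-day mean.
#' @return A tibble with `date`, `pm25` (`NA` when incomplete), `n_hours` and
#'   `complete`.
#' @export
hourly_to_daily <- function(hourly, value_col = "pm25", min_hours = 23) {
  if (!value_col %in% names(hourly)) {
    rlang::abort(sprintf("Column `%s` not found.", value_col),
                 class = "pacolloc_schema_error")
  }
  if (min_hours < 0 || min_hours > 24) {
    rlang::abort("`min_hours` must lie in [0, 24].",
                 class = "pacolloc_invalid_input")
  }
  val <- rlang::sym(value_col)
  hourly |>
    dplyr::mutate(date = lubridate::as_date(hour_start)) |>
    dplyr::group_by(date) |>
    dplyr::summarise(
      n_hours = sum(!is.na(!!val)),
      pm25 = mean(!!val, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      complete = n_hours >= min_hours,
      pm25 = ifelse(complete & n_hours > 0, pm25, NA_real_)
    ) |>
    dplyr::select(date, pm25, n_hours, complete)
}

#' Named date-window exclusions
#'
#' Builds a table of labelled exclusion windows, inclusive on both end dates.
#'
#' @param label Character vector of window labels.
#' @param start_date,end_date Dates (or strings coercible to dates), inclusive.
#' @return A tibble with `label`, `start_date`, `end_date`.
#' @export
exclusion_windows <- function(label, start_date, end_date) {
  start_date <- lubridate::as_date(start_date)
  end_date <- lubridate::as_date(end_date)
  if (any(start_date > end_date)) {
    rlang::abort("Exclusion windows need start_date <= end_date.",
                 class = "pacolloc_invalid_input")
  }
  tibble::tibble(label = as.character(label),
                 start_date = start_date, end_date = end_date)
}

#' Default exclusion windows for the Armidale collocation record
#'
#' Two windows: the Black Summer bushfire period (2019-11-01 to 2020-01-31),
#' when extreme smoke made the comparison unrepresentative, and
#' January-May 2022, when the reference TEOM record was suspect.
#'
#' @return A tibble of exclusion windows.
#' @export
default_exclusions <- function() {
  exclusion_windows(
    label = c("black_summer_bushfires", "teom_data_problem"),
    start_date = c("2019-11-01", "2022-01-01"),
    end_date = c("2020-01-31", "2022-05-31")
  )
}

#' Mark daily values falling inside exclusion windows
#'
#' Days inside any window (dates inclusive) are flagged `excluded` and carry
#' the label of the first matching window for audit. Values are retained, not
#' deleted; downstream pairing skips excluded days.
#'
#' @param daily A daily tibble as from [hourly_to_daily()].
#' @param windows An exclusion-window tibble; an empty table is the identity.
#' @return `daily` with added `excluded` (logical) and `exclusion_label`.
#' @export
apply_exclusions <- function(daily, windows = default_exclusions()) {
  excluded <- rep(FALSE, nrow(daily))
  lab <- rep(NA_character_, nrow(daily))
  if (!is.null(windows) && nrow(windows) > 0) {
    for (i in rev(seq_len(nrow(windows)))) {
      inside <- daily$date >= windows$start_date[i] &
        daily$date <= windows$end_date[i]
      excluded <- excluded | inside
      lab[inside] <- windows$label[i]
    }
  }
  daily$excluded <- excluded
  daily$exclusion_label <- lab
  daily
}
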