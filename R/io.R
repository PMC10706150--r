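# canonical PA record columns; `dialect` in read_pa_csv maps these onto the
# columns actually present in a file
.pa_mandatory <- c("timestamp_start", "timestamp_end", "cf1_a", "cf1_b",
                   "n_gt_0p3_a", "n_gt_0p5_a", "n_gt_1_a", "n_gt_2p5_a",
                   "n_gt_0p3_b", "n_gt_0p5_b", "n_gt_1_b", "n_gt_2p5_b")
.pa_optional <- c("rh", "cfa")

# timestamps must be local standard time; an explicit UTC offset or zone
# designator means the exporter applied a conversion we refuse to guess at
.reject_tz_designators <- function(x) {
  bad <- grepl("(Z$)|([+-][0-9]{2}:?[0-9]{2}$)", trimws(x))
  if (any(bad, na.rm = TRUE)) {
    rlang::abort(
      sprintf("Timestamps must be local standard time without zone designators; offending row(s): %s",
              paste(utils::head(which(bad), 5), collapse = ", ")),
      class = "pacolloc_timezone_error")
  }
  invisible(TRUE)
}

.parse_lst <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  .reject_tz_designators(x)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' Read a canonical PurpleAir-style 2-minute CSV
#'
#' Reads a record stream in the package's canonical column layout:
#' `timestamp_start`, `timestamp_end` (local standard time,
#' `YYYY-MM-DD HH:MM:SS`), per-channel `cf1_a`/`cf1_b`, eight cumulative
#' count columns `n_gt_{0p3,0p5,1,2p5}_{a,b}`, and optional `rh` and `cfa`.
#' Files from other export vintages are mapped through `dialect`. Rows with
#' unparseable timestamps, negative cf1, or non-monotone counts are skipped
#' with a warning reporting the counts; files lacking mandatory columns (or
#' empty) raise a schema error naming them.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(cf1_a = "pm2.5_cf_1", rh = "humidity")`.
#' @return A tibble of validated sensor records.
#' @export
read_pa_csv <- function(path, dialect = NULL) {
  # read everything as text so zone designators on timestamps reach the
  # validator instead of being silently converted by the reader
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    rlang::abort(sprintf("File '%s' is empty or unreadable.", path),
                 class = "pacolloc_schema_error")
  }
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(.pa_mandatory, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Missing mandatory column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "pacolloc_schema_error")
  }
  for (opt in .pa_optional) if (!opt %in% names(raw)) raw[[opt]] <- NA_real_
  for (num in setdiff(c(.pa_mandatory, .pa_optional),
                      c("timestamp_start", "timestamp_end"))) {
    raw[[num]] <- suppressWarnings(as.numeric(raw[[num]]))
  }

  raw$timestamp_start <- .parse_lst(raw$timestamp_start)
  raw$timestamp_end <- .parse_lst(raw$timestamp_end)

  bad_time <- is.na(raw$timestamp_start) | is.na(raw$timestamp_end) |
    raw$timestamp_end <= raw$timestamp_start
  bad_cf1 <- !bad_time & (is.na(raw$cf1_a) | is.na(raw$cf1_b) |
                            raw$cf1_a < 0 | raw$cf1_b < 0)
  mono <- function(p) {
    cn <- paste0(c("n_gt_0p3", "n_gt_0p5", "n_gt_1", "n_gt_2p5"), p)
    !(raw[[cn[1]]] >= raw[[cn[2]]] & raw[[cn[2]]] >= raw[[cn[3]]] &
        raw[[cn[3]]] >= raw[[cn[4]]] & raw[[cn[4]]] >= 0)
  }
  bad_counts <- !bad_time & !bad_cf1 & (mono("_a") | mono("_b"))
  bad_counts[is.na(bad_counts)] <- TRUE
  bad <- bad_time | bad_cf1 | bad_counts
  if (any(bad)) {
    rlang::warn(
      sprintf("Skipped %d malformed row(s) (%d bad timestamp, %d negative/missing cf1, %d non-monotone counts); kept %d.",
              sum(bad), sum(bad_time), sum(bad_cf1), sum(bad_counts),
              sum(!bad)),
      class = "pacolloc_rows_skipped")
  }
  out <- raw[!bad, c(.pa_mandatory, .pa_optional)]
  if (nrow(out) == 0) {
    rlang::abort("No valid records after validation.",
                 class = "pacolloc_schema_error")
  }
  out[order(out$timestamp_start), ]
}

#' Write sensor records to the canonical CSV layout
#'
#' @param records A record tibble (e.g. from [simulate_pa_unit()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pa_csv <- function(records, path) {
  out <- records
  out$timestamp_start <- format(out$timestamp_start, "%Y-%m-%d %H:%M:%S")
  out$timestamp_end <- format(out$timestamp_end, "%Y-%m-%d %H:%M:%S")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an hourly reference-station CSV
#'
#' Canonical columns: `timestamp` (hour start, local standard time), `pm25`
#' (µg/m³; negatives are valid reference output and retained), and optional
#' `pm10` and `neph`. Missing hours are simply absent.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `timestamp`, `pm25` and any optional columns present.
#' @export
read_reference_csv <- function(path) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    rlang::abort(sprintf("File '%s' is empty or unreadable.", path),
                 class = "pacolloc_schema_error")
  }
  if (!all(c("timestamp", "pm25") %in% names(raw))) {
    rlang::abort("Reference file needs `timestamp` and `pm25` columns.",
                 class = "pacolloc_schema_error")
  }
  for (num in intersect(c("pm25", "pm10", "neph"), names(raw))) {
    raw[[num]] <- suppressWarnings(as.numeric(raw[[num]]))
  }
  raw$timestamp <- .parse_lst(raw$timestamp)
  bad <- is.na(raw$timestamp)
  if (any(bad)) {
    rlang::warn(sprintf("Skipped %d row(s) with unparseable timestamps.",
                        sum(bad)),
                class = "pacolloc_rows_skipped")
    raw <- raw[!bad, ]
  }
  keep <- intersect(c("timestamp", "pm25", "pm10", "neph"), names(raw))
  raw[order(raw$timestamp), keep]
}

#' Write an hourly reference stream to CSV
#'
#' @param reference Hourly tibble with `timestamp`, `pm25`, optionally `pm10`
#'   and `neph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(reference, path) {
  out <- reference
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
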