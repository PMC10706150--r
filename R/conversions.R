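# ALT-3.4 mass weights: empirical density factor 3.4 times the per-channel
# water-sphere mass coefficients for the 0.3-0.5, 0.5-1 and 1-2.5 micron bins.
.alt_factor <- 3.4
.alt_w <- c(w0p5 = 0.00030418, w1 = 0.0018512, w2p5 = 0.02069706)

#' Per-unit linear sensor calibration
#'
#' A calibration maps the raw Plantower `cf1` output of one PurpleAir unit to
#' reference-equivalent PM2.5 as `pm25 = intercept + slope * cf1`. Units that
#' were never co-located with a reference monitor use the default woodsmoke
#' conversion (intercept 0.53, slope 0.55).
#'
#' @param unit_id Character label identifying the sensor unit.
#' @param intercept Intercept in µg/m³.
#' @param slope Dimensionless slope; must be positive.
#' @param source Either `"fitted_2018"` (fitted against a reference monitor)
#'   or `"default_woodsmoke"`.
#' @return A list of class `pa_calibration` with fields `unit_id`,
#'   `intercept`, `slope`, `source`.
#' @examples
#' cal <- sensor_calibration("Arm1", 0.53, 0.580)
#' apply_linear_calibration(20, cal)
#' @export
sensor_calibration <- function(unit_id, intercept, slope,
                               source = c("fitted_2018", "default_woodsmoke")) {
  source <- match.arg(source)
  if (!is.numeric(intercept) || !is.numeric(slope) || length(intercept) != 1 ||
      length(slope) != 1 || !is.finite(intercept) || !is.finite(slope)) {
    rlang::abort("`intercept` and `slope` must be single finite numbers.",
                 class = "pacolloc_invalid_calibration")
  }
  if (slope <= 0) {
    rlang::abort("Calibration slope must be positive.",
                 class = "pacolloc_invalid_calibration")
  }
  structure(list(unit_id = as.character(unit_id), intercept = intercept,
                 slope = slope, source = source),
            class = "pa_calibration")
}

#' @export
print.pa_calibration <- function(x, ...) {
  cat(sprintf("<pa_calibration> %s: pm25 = %.3g + %.3g * cf1 [%s]\n",
              x$unit_id, x$intercept, x$slope, x$source))
  invisible(x)
}

#' The default woodsmoke conversion
#'
#' The conversion applied to uncalibrated units in woodsmoke-affected areas:
#' intercept 0.53 µg/m³, slope 0.55.
#'
#' @return A `pa_calibration` object.
#' @export
default_woodsmoke_calibration <- function() {
  sensor_calibration("default_woodsmoke", 0.53, 0.55, "default_woodsmoke")
}

#' Packaged per-unit calibration table
#'
#' Reads the calibration table shipped with the package (eight units deployed
#' at the Armidale reference site; see the methods vignette). The table maps
#' `unit_id` to intercept and slope of the linear cf1 calibration.
#'
#' @param path Path to a YAML file with a `calibrations` mapping. Defaults to
#'   the packaged table.
#' @return A tibble with columns `unit_id`, `intercept`, `slope`, `source`.
#' @export
read_calibrations <- function(path = system.file("extdata", "calibrations.yaml",
                                                 package = "pacolloc")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$calibrations)) {
    rlang::abort("Calibration file lacks a `calibrations` table.",
                 class = "pacolloc_schema_error")
  }
  rows <- lapply(names(raw$calibrations), function(id) {
    entry <- raw$calibrations[[id]]
    tibble::tibble(
      unit_id = id,
      intercept = as.numeric(entry$intercept),
      slope = as.numeric(entry$slope),
      source = entry$source %||% "fitted_2018"
    )
  })
  dplyr::bind_rows(rows)
}

#' Look up the calibration for a unit
#'
#' Unknown units fall back to the default woodsmoke conversion with a warning,
#' mirroring field practice for units that were never co-located.
#'
#' @param unit_id Unit label.
#' @param calibrations Calibration tibble as from [read_calibrations()].
#' @return A `pa_calibration` object.
#' @export
lookup_calibration <- function(unit_id, calibrations = read_calibrations()) {
  hit <- calibrations[calibrations$unit_id == unit_id, ]
  if (nrow(hit) == 0) {
    rlang::warn(
      sprintf("No calibration for unit '%s'; using default woodsmoke conversion.",
              unit_id),
      class = "pacolloc_default_calibration")
    return(default_woodsmoke_calibration())
  }
  sensor_calibration(unit_id, hit$intercept[[1]], hit$slope[[1]],
                     source = hit$source[[1]])
}

#' Apply a linear cf1 calibration
#'
#' Converts raw `cf1` values to PM2.5 as `intercept + slope * cf1`.
#'
#' @param cf1 Numeric vector of raw cf1 values (µg/m³); must be non-negative.
#' @param cal A `pa_calibration`, or anything with `intercept` and `slope`
#'   fields. Defaults to the woodsmoke conversion.
#' @return PM2.5 in µg/m³, same length as `cf1`. `NA` passes through.
#' @export
apply_linear_calibration <- function(cf1, cal = default_woodsmoke_calibration()) {
  bad <- which(!is.na(cf1) & cf1 < 0)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("cf1 must be non-negative; offending record(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      class = "pacolloc_invalid_input")
  }
  cal$intercept + cal$slope * cf1
}

.check_counts <- function(n_gt_0p3, n_gt_0p5, n_gt_1, n_gt_2p5) {
  ok <- is.na(n_gt_0p3) | is.na(n_gt_0p5) | is.na(n_gt_1) | is.na(n_gt_2p5) |
    (n_gt_0p3 >= n_gt_0p5 & n_gt_0p5 >= n_gt_1 & n_gt_1 >= n_gt_2p5 &
       n_gt_2p5 >= 0)
  if (!all(ok)) {
    rlang::abort(
      sprintf(
        "Cumulative size-channel counts must satisfy >0.3 >= >0.5 >= >1 >= >2.5 >= 0; offending record(s): %s",
        paste(utils::head(which(!ok), 5), collapse = ", ")),
      class = "pacolloc_invalid_counts")
  }
  invisible(TRUE)
}

#' ALT-3.4 particle-count conversion to PM2.5
#'
#' Converts cumulative Plantower size-channel counts to PM2.5 mass by
#' differencing the channels into bin counts N1 (0.3-0.5 µm), N2 (0.5-1 µm)
#' and N3 (1-2.5 µm) and summing water-sphere bin masses scaled by the
#' empirical factor 3.4:
#' `3.4 * (0.00030418 N1 + 0.0018512 N2 + 0.02069706 N3)`.
#' No per-unit calibration is required.
#'
#' @param n_gt_0p3,n_gt_0p5,n_gt_1,n_gt_2p5 Cumulative counts of particles
#'   larger than 0.3, 0.5, 1 and 2.5 µm per unit sampled volume. Averaged
#'   records may carry fractional counts. Must be monotone non-increasing.
#' @return PM2.5 in µg/m³ (non-negative), vectorised over the inputs.
#' @examples
#' alt34(1110, 110, 10, 0)
#' @export
alt34 <- function(n_gt_0p3, n_gt_0p5, n_gt_1, n_gt_2p5) {
  .check_counts(n_gt_0p3, n_gt_0p5, n_gt_1, n_gt_2p5)
  n1 <- n_gt_0p3 - n_gt_0p5
  n2 <- n_gt_0p5 - n_gt_1
  n3 <- n_gt_1 - n_gt_2p5
  .alt_factor * (.alt_w[["w0p5"]] * n1 + .alt_w[["w1"]] * n2 +
                   .alt_w[["w2p5"]] * n3)
}

#' Sub-micron mass fraction (P1) of the ALT-3.4 estimate
#'
#' The fraction of ALT-3.4 PM2.5 mass contributed by particles below 1 µm:
#' `P1 = (W0.5 + W1) / (W0.5 + W1 + W2.5)`. Low P1 indicates a coarse
#' (dust-like) aerosol; woodsmoke aerosols sit near 1.
#'
#' @inheritParams alt34
#' @return Fraction in `[0, 1]`; `NA` (with a warning) where the total ALT-3.4
#'   mass is zero and the fraction is undefined.
#' @export
p1_fraction <- function(n_gt_0p3, n_gt_0p5, n_gt_1, n_gt_2p5) {
  .check_counts(n_gt_0p3, n_gt_0p5, n_gt_1, n_gt_2p5)
  n1 <- n_gt_0p3 - n_gt_0p5
  n2 <- n_gt_0p5 - n_gt_1
  n3 <- n_gt_1 - n_gt_2p5
  sub <- .alt_factor * (.alt_w[["w0p5"]] * n1 + .alt_w[["w1"]] * n2)
  tot <- sub + .alt_factor * .alt_w[["w2p5"]] * n3
  out <- sub / tot
  undef <- !is.na(tot) & tot == 0
  if (any(undef)) {
    rlang::warn(
      sprintf("P1 undefined for %d record(s) with zero ALT-3.4 mass; returned NA.",
              sum(undef)),
      class = "pacolloc_undefined_fraction")
    out[undef] <- NA_real_
  }
  out
}

#' Nephelometer scattering to woodsmoke PM2.5
#'
#' Applies the published woodsmoke relationship
#' `PM2.5 = 0.53 + 22.186 * neph`. The coefficient 22.186 is bound to the
#' scattering output of the Aurora 1000G integrating nephelometer it was
#' fitted against; inputs are treated as instrument-reported scattering
#' values. Negative scattering (instrument noise) is allowed.
#'
#' @param scattering Numeric vector of nephelometer readings.
#' @return PM2.5 in µg/m³.
#' @export
neph_to_pm25 <- function(scattering) {
  if (any(!is.finite(scattering) & !is.na(scattering))) {
    rlang::abort("Scattering values must be finite.",
                 class = "pacolloc_invalid_input")
  }
  0.53 + 22.186 * scattering
}

#' US EPA humidity-adjusted PurpleAir conversion
#'
#' The US EPA nationwide conversion
#' `PM2.5 = 0.524 * cf1 - 0.0862 * RH + 5.75`. The two RH terms form an
#' RH-dependent intercept: -2.87 µg/m³ at 100% RH, zero near 66.7% RH and
#' 2.91 µg/m³ at 33% RH.
#'
#' @param cf1 Raw cf1 values (µg/m³).
#' @param rh Relative humidity in percent, within `[0, 100]`.
#' @return PM2.5 in µg/m³ (may be negative at high RH and low cf1).
#' @examples
#' usepa_conversion(0, c(100, 66.7, 33))
#' @export
usepa_conversion <- function(cf1, rh) {
  bad <- which(!is.na(rh) & (rh < 0 | rh > 100))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("RH must lie in [0, 100]; offending record(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      class = "pacolloc_invalid_input")
  }
  0.524 * cf1 - 0.0862 * rh + 5.75
}
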