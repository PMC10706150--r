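#' Configuration for the synthetic collocation simulator
#'
#' Bundles every tunable of the synthetic woodsmoke site: the minute-scale
#' truth process, the dual-channel optical sensors, and the FDMS TEOM
#' reference. All randomness flows from `seed`; independent instrument
#' streams draw from sub-seeds derived from it, so adding an instrument never
#' perturbs the others. Defaults describe a Southern Hemisphere woodsmoke
#' town: low summer baseline, strong winter evening peaks, a near-pure
#' sub-micron aerosol in winter and a larger coarse share in summer.
#'
#' @param seed Integer seed driving all streams.
#' @param n_days Number of simulated days.
#' @param start_date First simulated day (local standard time).
#' @param baseline_pm Background PM2.5, µg/m³.
#' @param evening_peak_pm Amplitude of the wood-heater evening peak, µg/m³,
#'   before seasonal modulation.
#' @param peak_hour,peak_width_h Centre (hour of day) and width (hours) of the
#'   wrapped-Gaussian diurnal kernel.
#' @param seasonal_amplitude Relative seasonal modulation of the evening peak
#'   (0 = none); winter-high, centred on day-of-year 183.
#' @param p1_winter,p1_summer Sub-micron mass fractions of the aerosol in
#'   mid-winter and mid-summer, each in (0, 1).
#' @param truth_noise_sd Log-scale standard deviation of the multiplicative
#'   lognormal noise on the minute-scale truth.
#' @param truth_noise_ar Per-minute AR(1) coefficient of that noise
#'   (0 = white; 0.9 gives roughly a 10-minute correlation scale).
#' @param sensor_noise_cv Coefficient of variation of the per-channel,
#'   per-record multiplicative sensor noise.
#' @param units Character vector of unit ids to simulate at the site.
#' @param per_unit_calibrations Calibration tibble (see [read_calibrations()]);
#'   units absent from it fall back to the default woodsmoke conversion.
#' @param n1_n2_ratio Fixed count ratio N1:N2 used when synthesising
#'   size-channel counts within the sub-micron fraction.
#' @param pa_coarse_response Fraction of the 1-2.5 µm (coarse-within-PM2.5)
#'   mass the optical sensor registers; 1 means the sensor sees it all, lower
#'   values inject the dust-day underestimation seen in mixed aerosols.
#' @param spike_rate Expected one-channel spurious spikes per year per unit.
#' @param spike_magnitude Added PM2.5 of a spike, µg/m³ (applied to one
#'   channel for one hour).
#' @param teom_noise_sd Hourly reference noise sd, µg/m³ (negatives permitted,
#'   as real FDMS TEOMs produce).
#' @param teom_duty_cycle If `TRUE`, the reference hourly value averages the
#'   truth only over the five 6-minute measurement windows of the 12-minute
#'   FDMS cycle; if `FALSE`, over the full hour.
#' @param fdms_phase Minute within the 12-minute cycle at which a measurement
#'   window opens (default 0: minutes 0-5, 12-17, ...).
#' @param coarse_pm_mean Mean coarse (PM10 - PM2.5) mass at the reference
#'   station, µg/m³.
#' @param coarse_seasonal Relative seasonal modulation of the coarse mass
#'   (summer-high).
#' @param neph_noise_sd Noise sd of the synthetic nephelometer, in scattering
#'   units.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_days = 365L,
                              start_date = "2021-01-01",
                              baseline_pm = 3,
                              evening_peak_pm = 25,
                              peak_hour = 21,
                              peak_width_h = 3,
                              seasonal_amplitude = 0.8,
                              p1_winter = 0.97,
                              p1_summer = 0.75,
                              truth_noise_sd = 0.25,
                              truth_noise_ar = 0.9,
                              sensor_noise_cv = 0.05,
                              units = c("Arm1", "ARC2"),
                              per_unit_calibrations = read_calibrations(),
                              n1_n2_ratio = 9,
                              pa_coarse_response = 1,
                              spike_rate = 1.25,
                              spike_magnitude = 50,
                              teom_noise_sd = 2,
                              teom_duty_cycle = TRUE,
                              fdms_phase = 0,
                              coarse_pm_mean = 4.5,
                              coarse_seasonal = 0.3,
                              neph_noise_sd = 0.02) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_days <- as.integer(n_days)
  cfg$start_date <- lubridate::as_date(start_date)
  stopifnot(cfg$n_days > 0, baseline_pm >= 0, evening_peak_pm >= 0,
            truth_noise_sd >= 0, sensor_noise_cv >= 0, spike_rate >= 0,
            teom_noise_sd >= 0, n1_n2_ratio > 0,
            pa_coarse_response >= 0, pa_coarse_response <= 1)
  if (p1_winter <= 0 || p1_winter > 1 || p1_summer <= 0 || p1_summer > 1) {
    rlang::abort("Sub-micron fractions must lie in (0, 1].",
                 class = "pacolloc_invalid_input")
  }
  structure(cfg, class = "simulation_config")
}

# sub-seed for a named stream; kept well below 2^31
.stream_seed <- function(cfg, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (abs(cfg$seed) * 7919L + h) %% 2147480000L
}

.minute_times <- function(cfg) {
  start <- lubridate::as_datetime(cfg$start_date, tz = "UTC")
  start + 60 * (seq_len(cfg$n_days * 1440L) - 1L)
}

# winter-high seasonal cosine in [-1, 1], centred on day-of-year 183
.season_cos <- function(times) {
  doy <- lubridate::yday(times) + (lubridate::hour(times) * 60 +
                                     lubridate::minute(times)) / 1440
  cos(2 * pi * (doy - 183) / 365.25)
}

#' Simulate the minute-scale true PM2.5 and sub-micron fraction
#'
#' The truth process is `(baseline + peak * diurnal(t) * season(t)) * exp(z_t)`
#' where the diurnal kernel is a wrapped Gaussian peaking in the evening, the
#' seasonal factor is a winter-high cosine, and `z_t` is AR(1) Gaussian noise
#' on the log scale. The true sub-micron fraction P1 interpolates between its
#' winter (high) and summer (low) values along the same seasonal cosine.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A tibble with `time` (minute resolution, POSIXct), `pm_true`
#'   (µg/m³) and `p1_true`.
#' @export
simulate_truth <- function(config) {
  times <- .minute_times(config)
  n <- length(times)
  h <- lubridate::hour(times) + lubridate::minute(times) / 60
  dh <- pmin(abs(h - config$peak_hour), 24 - abs(h - config$peak_hour))
  diurnal <- exp(-0.5 * (dh / config$peak_width_h)^2)
  cosw <- .season_cos(times)
  season <- pmax(0, 1 + config$seasonal_amplitude * cosw)
  clean <- config$baseline_pm + config$evening_peak_pm * diurnal * season

  if (config$truth_noise_sd > 0) {
    z <- withr::with_seed(.stream_seed(config, "truth"), {
      rho <- config$truth_noise_ar
      innov <- stats::rnorm(n, 0, config$truth_noise_sd * sqrt(1 - rho^2))
      as.numeric(stats::filter(innov, rho, method = "recursive",
                               init = stats::rnorm(1, 0, config$truth_noise_sd)))
    })
    pm <- clean * exp(z)
  } else {
    pm <- clean
  }

  w <- (1 + cosw) / 2 # 1 mid-winter, 0 mid-summer
  p1 <- config$p1_summer + (config$p1_winter - config$p1_summer) * w
  tibble::tibble(time = times, pm_true = pm, p1_true = p1)
}

# synthesise cumulative size-channel counts whose ALT-3.4 mass equals `mass`
# with sub-micron fraction `p1`, splitting sub-micron counts N1:N2 = ratio:1
.counts_for_mass <- function(mass, p1, ratio) {
  w <- .alt_factor * .alt_w
  n3 <- (1 - p1) * mass / w[["w2p5"]]
  n2 <- p1 * mass / (ratio * w[["w0p5"]] + w[["w1"]])
  n1 <- ratio * n2
  list(n_gt_0p3 = n3 + n2 + n1, n_gt_0p5 = n3 + n2, n_gt_1 = n3,
       n_gt_2p5 = rep(0, length(mass)))
}

#' Simulate one dual-channel optical sensor unit
#'
#' Produces the 2-minute record stream of one PurpleAir-style unit observing
#' the truth series. Per channel, `cf1` inverts the unit's linear calibration
#' (so `apply_linear_calibration()` recovers the observed mass), carries
#' multiplicative Gaussian noise of cv `sensor_noise_cv`, and is floored at
#' zero. Size-channel counts are synthesised so that [alt34()] on them equals
#' the channel's observed mass with the true sub-micron fraction, using a
#' fixed N1:N2 split. Rare one-channel spikes of `spike_magnitude` µg/m³ are
#' injected into a random channel for whole hours at Poisson rate
#' `spike_rate` per year; injected hours are recorded in the `spikes`
#' attribute of the result.
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [simulation_config()].
#' @param unit_id Unit label; calibrations come from
#'   `config$per_unit_calibrations`, falling back (with a warning) to the
#'   default woodsmoke conversion.
#' @return A tibble of 2-minute records: `timestamp_start`, `timestamp_end`,
#'   `cf1_a`, `cf1_b`, `cfa`, `rh`, and cumulative counts
#'   `n_gt_{0p3,0p5,1,2p5}_{a,b}`. Attributes: `unit_id`, `calibration`,
#'   `spikes` (tibble of `hour_start`, `channel`).
#' @export
simulate_pa_unit <- function(truth, config, unit_id) {
  cal <- lookup_calibration(unit_id, config$per_unit_calibrations)
  n2min <- nrow(truth) %/% 2L
  agg2 <- function(x) colMeans(matrix(x[seq_len(2L * n2min)], nrow = 2L))
  pm2 <- agg2(truth$pm_true)
  p1 <- agg2(truth$p1_true)
  t_start <- truth$time[seq(1L, by = 2L, length.out = n2min)]

  # mass the optical sensor registers: full sub-micron signal, attenuated
  # response to the 1-2.5 micron tail
  seen <- pm2 * (p1 + (1 - p1) * config$pa_coarse_response)

  out <- withr::with_seed(.stream_seed(config, paste0("unit:", unit_id)), {
    noise <- function() 1 + stats::rnorm(n2min, 0, config$sensor_noise_cv)
    cf1_a <- pmax(0, (seen - cal$intercept) / cal$slope * noise())
    cf1_b <- pmax(0, (seen - cal$intercept) / cal$slope * noise())

    years <- config$n_days / 365.25
    n_spikes <- stats::rpois(1, config$spike_rate * years)
    hours <- unique(lubridate::floor_date(t_start, "hour"))
    spikes <- tibble::tibble(
      hour_start = sort(sample(hours, min(n_spikes, length(hours)))),
      channel = sample(c("a", "b"), min(n_spikes, length(hours)),
                       replace = TRUE)
    )
    rec_hour <- lubridate::floor_date(t_start + 60, "hour")
    for (i in seq_len(nrow(spikes))) {
      idx <- rec_hour == spikes$hour_start[i]
      if (spikes$channel[i] == "a") {
        cf1_a[idx] <- cf1_a[idx] + config$spike_magnitude / cal$slope
      } else {
        cf1_b[idx] <- cf1_b[idx] + config$spike_magnitude / cal$slope
      }
    }

    rh <- pmin(100, pmax(20, 70 + 10 * sin(2 * pi * (lubridate::hour(t_start) - 4) / 24) +
                           stats::rnorm(n2min, 0, 5)))
    list(cf1_a = cf1_a, cf1_b = cf1_b, rh = rh, spikes = spikes)
  })

  mass_a <- cal$intercept + cal$slope * out$cf1_a
  mass_b <- cal$intercept + cal$slope * out$cf1_b
  cnt_a <- .counts_for_mass(mass_a, p1, config$n1_n2_ratio)
  cnt_b <- .counts_for_mass(mass_b, p1, config$n1_n2_ratio)

  rec <- tibble::tibble(
    timestamp_start = t_start,
    timestamp_end = t_start + 120,
    cf1_a = out$cf1_a,
    cf1_b = out$cf1_b,
    cfa = out$cf1_a, # carried for round-trip IO, never used in analysis
    rh = out$rh,
    n_gt_0p3_a = cnt_a$n_gt_0p3, n_gt_0p5_a = cnt_a$n_gt_0p5,
    n_gt_1_a = cnt_a$n_gt_1, n_gt_2p5_a = cnt_a$n_gt_2p5,
    n_gt_0p3_b = cnt_b$n_gt_0p3, n_gt_0p5_b = cnt_b$n_gt_0p5,
    n_gt_1_b = cnt_b$n_gt_1, n_gt_2p5_b = cnt_b$n_gt_2p5
  )
  attr(rec, "unit_id") <- unit_id
  attr(rec, "calibration") <- cal
  attr(rec, "spikes") <- out$spikes
  rec
}

#' Simulate the hourly FDMS TEOM reference stream
#'
#' An FDMS TEOM weighs particles for 6 minutes, then samples filtered air for
#' 6 minutes, five cycles per hour, so it observes the truth for only half of
#' each hour. The simulated hourly value is the mean of the minute-scale truth
#' over the five measurement windows (minutes `fdms_phase` to `fdms_phase+5`
#' of each 12-minute cycle), plus Gaussian noise; negatives are retained, as
#' real instruments report them. PM10 adds a summer-high coarse component.
#'
#' @inheritParams simulate_pa_unit
#' @return A tibble with `timestamp` (hour start), `pm25`, `pm10` (µg/m³).
#' @export
simulate_teom_fdms <- function(truth, config) {
  hour_start <- lubridate::floor_date(truth$time, "hour")
  if (config$teom_duty_cycle) {
    min_in_cycle <- (lubridate::minute(truth$time) - config$fdms_phase) %% 12
    keep <- min_in_cycle < 6
  } else {
    keep <- rep(TRUE, nrow(truth))
  }
  base <- tibble::tibble(hour_start = hour_start[keep],
                         pm = truth$pm_true[keep]) |>
    dplyr::group_by(hour_start) |>
    dplyr::summarise(pm25 = mean(pm), .groups = "drop")

  cosw <- .season_cos(base$hour_start)
  coarse <- pmax(0, config$coarse_pm_mean * (1 - config$coarse_seasonal * cosw))
  withr::with_seed(.stream_seed(config, "teom"), {
    base$pm25 <- base$pm25 + stats::rnorm(nrow(base), 0, config$teom_noise_sd)
    base$pm10 <- base$pm25 + coarse +
      stats::rnorm(nrow(base), 0, config$teom_noise_sd / 2)
  })
  dplyr::rename(base, timestamp = hour_start)
}

#' Simulate a complete collocation site
#'
#' Composes the truth process, one record stream per configured sensor unit,
#' the hourly FDMS TEOM reference (PM2.5 and PM10), and an hourly
#' nephelometer stream (scattering that inverts the woodsmoke relationship,
#' plus noise).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `config`, `truth`, `pa` (named list of record
#'   tibbles) and `reference` (hourly tibble with `timestamp`, `pm25`, `pm10`,
#'   `neph`).
#' @export
simulate_site <- function(config = simulation_config()) {
  truth <- simulate_truth(config)
  pa <- lapply(config$units, function(u) simulate_pa_unit(truth, config, u))
  names(pa) <- config$units
  reference <- simulate_teom_fdms(truth, config)

  truth_hour <- truth |>
    dplyr::mutate(hour_start = lubridate::floor_date(time, "hour")) |>
    dplyr::group_by(hour_start) |>
    dplyr::summarise(pm = mean(pm_true), .groups = "drop")
  neph <- withr::with_seed(.stream_seed(config, "neph"), {
    (truth_hour$pm - 0.53) / 22.186 +
      stats::rnorm(nrow(truth_hour), 0, config$neph_noise_sd)
  })
  reference$neph <- neph[match(reference$timestamp, truth_hour$hour_start)]

  list(config = config, truth = truth, pa = pa, reference = reference)
}
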