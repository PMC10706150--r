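#' Fuse the two laser channels of one unit into hourly PM2.5
#'
#' Each PurpleAir unit carries two identical laser sensors ("A" and "B");
#' hardware faults show up as discordance between them. For each hour, with
#' `L = min(pm_a, pm_b)`, `H = max(pm_a, pm_b)`, `AD = H - L` and
#' `m = (L + H) / 2`:
#' an hour is discordant when `AD` exceeds `ad_abs_threshold` *and* exceeds
#' `ad_frac_threshold * m`. Discordant hours are fused as
#' `wt1 * L + (1 - wt1) * H` with `wt1 = 0.5 * (1 + min(1, AD / m))`, so the
#' high channel is ignored entirely once `AD >= m`. Concordant hours use the
#' plain mean. Hours with a single reporting channel are retained, flagged
#' discordant with `wt_low = 1`; hours with neither channel are dropped with
#' a `pacolloc_missing_hour` warning.
#'
#' @param pairs A data frame with columns `pm_a` and `pm_b` (hourly channel
#'   means, µg/m³, `NA` when a channel is missing); any other columns (e.g.
#'   `hour_start`) are carried through.
#' @param ad_abs_threshold Absolute discordance threshold, µg/m³ (default 10).
#' @param ad_frac_threshold Fractional threshold on the channel mean
#'   (default 0.5, i.e. "exceeds 50% of the mean").
#' @return A tibble with the carried columns plus `pm25` (fused value),
#'   `discordant` (logical), `wt_low` (weight on the low channel, in
#'   `[0.5, 1]`) and `n_channels` (1 or 2).
#' @examples
#' fuse_channels(data.frame(pm_a = c(8, 5, 10), pm_b = c(8, 40, 24)))
#' @export
fuse_channels <- function(pairs, ad_abs_threshold = 10, ad_frac_threshold = 0.5) {
  if (!all(c("pm_a", "pm_b") %in% names(pairs))) {
    rlang::abort("`pairs` must have columns `pm_a` and `pm_b`.",
                 class = "pacolloc_schema_error")
  }
  pairs <- tibble::as_tibble(pairs)
  both_missing <- is.na(pairs$pm_a) & is.na(pairs$pm_b)
  if (any(both_missing)) {
    rlang::warn(
      sprintf("Dropping %d hour(s) with neither channel reporting.",
              sum(both_missing)),
      class = "pacolloc_missing_hour")
    pairs <- pairs[!both_missing, , drop = FALSE]
  }
  a <- pairs$pm_a
  b <- pairs$pm_b
  if (any(c(a, b) < 0, na.rm = TRUE)) {
    rlang::abort("Channel means must be non-negative.",
                 class = "pacolloc_invalid_input")
  }

  lo <- pmin(a, b, na.rm = TRUE)
  hi <- pmax(a, b, na.rm = TRUE)
  single <- xor(is.na(a), is.na(b))
  ad <- hi - lo
  m <- (lo + hi) / 2

  disc <- !single & ad > ad_abs_threshold & ad > ad_frac_threshold * m
  # m = 0 with AD above a positive absolute threshold cannot occur for
  # non-negative channels; guard anyway so a zero mean never divides.
  if (any(disc & m <= 0)) {
    rlang::abort("Discordant hour with non-positive channel mean.",
                 class = "pacolloc_degenerate_hour")
  }
  wt_low <- rep(0.5, length(ad))
  wt_low[disc] <- 0.5 * (1 + pmin(1, ad[disc] / m[disc]))
  wt_low[single] <- 1

  pm25 <- wt_low * lo + (1 - wt_low) * hi

  out <- pairs
  out$pm25 <- pm25
  out$discordant <- disc | single
  out$wt_low <- wt_low
  out$n_channels <- 2L - as.integer(single)
  out
}

#' Discordance rate of a channel-pair series
#'
#' Fuses a series of hourly channel pairs and reports how often the two-channel
#' discordance rule trips, scaled to hours per year. Single-channel hours are
#' not counted: the rate measures A/B disagreement, not data gaps.
#'
#' @inheritParams fuse_channels
#' @param pairs A data frame with `hour_start` (POSIXct) plus `pm_a`, `pm_b`.
#' @return A list with `n_discordant`, `years` (span of the series) and
#'   `rate_per_year`.
#' @export
discordance_rate <- function(pairs, ad_abs_threshold = 10,
                             ad_frac_threshold = 0.5) {
  if (nrow(pairs) == 0 || !"hour_start" %in% names(pairs)) {
    rlang::abort("`pairs` must be non-empty with an `hour_start` column.",
                 class = "pacolloc_invalid_input")
  }
  span_s <- as.numeric(difftime(max(pairs$hour_start), min(pairs$hour_start),
                                units = "secs")) + 3600
  if (span_s <= 0) {
    rlang::abort("Series has zero duration.", class = "pacolloc_invalid_input")
  }
  fused <- fuse_channels(pairs, ad_abs_threshold, ad_frac_threshold)
  n_disc <- sum(fused$discordant & fused$n_channels == 2L)
  years <- span_s / (365.25 * 24 * 3600)
  list(n_discordant = n_disc, years = years, rate_per_year = n_disc / years)
}
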