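#' Pair reference and candidate daily series
#'
#' Inner-joins two daily series on date, keeping only days that are complete
#' and not excluded in both. Columns `complete` and `excluded`, when present,
#' gate the join; series without them are taken at face value.
#'
#' @param ref,cand Daily tibbles (as from [hourly_to_daily()], optionally
#'   after [apply_exclusions()]) with columns `date` and `pm25`.
#' @return A tibble with `date`, `ref` and `cand` (µg/m³).
#' @export
paired_days <- function(ref, cand) {
  keep <- function(d) {
    if ("complete" %in% names(d)) d <- d[d$complete, , drop = FALSE]
    if ("excluded" %in% names(d)) d <- d[!d$excluded, , drop = FALSE]
    d[!is.na(d$pm25), c("date", "pm25")]
  }
  pairs <- dplyr::inner_join(
    dplyr::rename(keep(ref), ref = pm25),
    dplyr::rename(keep(cand), cand = pm25),
    by = "date"
  )
  if (nrow(pairs) == 0) {
    rlang::abort("No overlapping complete, non-excluded days between the series.",
                 class = "pacolloc_empty_intersection")
  }
  pairs
}

#' Collocation summary statistics
#'
#' The standard summary of a daily collocation comparison between a candidate
#' sensor and a reference monitor:
#' Pearson correlation `r` with standard error `sqrt((1 - r^2) / (n - 2))`;
#' `RMSE = sqrt(mean((cand - ref)^2))`; the reduced-major-axis slope
#' `sign(r) * sd(ref) / sd(cand)` (appropriate when both instruments carry
#' error); and the ordinary least-squares fit of reference on candidate
#' (`ref = slope * cand + intercept`). Regression orientation is
#' reference-on-candidate throughout.
#'
#' @param pairs A tibble from [paired_days()] with columns `ref` and `cand`.
#' @return A one-row tibble: `n_days`, `r`, `r_se`, `rmse`, `rma_slope`,
#'   `ols_slope`, `ols_intercept`, `mean_ref`, `mean_cand`.
#' @examples
#' d <- tibble::tibble(ref = c(4, 8, 15, 16, 23), cand = c(5, 7, 14, 18, 22))
#' collocation_stats(d)
#' @export
collocation_stats <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) {
    rlang::abort("At least 3 paired days are required.",
                 class = "pacolloc_insufficient_pairs")
  }
  x <- pairs$cand
  y <- pairs$ref
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Degenerate series: zero variance in one member.",
                 class = "pacolloc_degenerate_series")
  }
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    n_days = n,
    r = r,
    r_se = sqrt((1 - r^2) / (n - 2)),
    rmse = sqrt(mean((x - y)^2)),
    rma_slope = sign(r) * stats::sd(y) / stats::sd(x),
    ols_slope = unname(stats::coef(fit)[2]),
    ols_intercept = unname(stats::coef(fit)[1]),
    mean_ref = mean(y),
    mean_cand = mean(x)
  )
}

#' Residual diagnostics against aerosol size composition
#'
#' Correlates the daily collocation residuals (`ref - cand`) with the
#' sub-micron mass fraction P1 from the candidate sensor and with the
#' reference PM2.5/PM10 ratio. A positive residual-P1 correlation together
#' with a negative residual-ratio correlation is the signature of candidate
#' underestimation on coarse-particle (dust) days.
#'
#' @param pairs A tibble with columns `ref`, `cand` and at least one of `p1`
#'   (daily sub-micron fraction) and `pm_ratio` (daily reference PM2.5/PM10).
#' @return A one-row tibble with `n_days`, `r_resid_p1`, `r_resid_ratio`
#'   (`NA` where the covariate is absent or the residuals are constant; a
#'   constant-residual series raises a `pacolloc_degenerate_series` warning).
#' @export
residual_diagnostics <- function(pairs) {
  if (nrow(pairs) < 3) {
    rlang::abort("At least 3 paired days are required.",
                 class = "pacolloc_insufficient_pairs")
  }
  resid <- pairs$ref - pairs$cand
  cor_or_na <- function(covar) {
    if (is.null(covar)) return(NA_real_)
    ok <- !is.na(resid) & !is.na(covar)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(resid[ok]) == 0 || stats::sd(covar[ok]) == 0) {
      rlang::warn("Constant residuals or covariate: correlation undefined.",
                  class = "pacolloc_degenerate_series")
      return(NA_real_)
    }
    stats::cor(resid[ok], covar[ok])
  }
  col <- function(nm) if (nm %in% names(pairs)) pairs[[nm]] else NULL
  tibble::tibble(
    n_days = nrow(pairs),
    r_resid_p1 = cor_or_na(col("p1")),
    r_resid_ratio = cor_or_na(col("pm_ratio"))
  )
}
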