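# Independent scalar re-implementation of the discordance-weighted fusion
# rule, used only as a test oracle.
fuse_oracle <- function(a, b, abs_thr = 10, frac_thr = 0.5) {
  lo <- min(a, b)
  hi <- max(a, b)
  ad <- hi - lo
  m <- (lo + hi) / 2
  if (ad > abs_thr && ad > frac_thr * m) {
    wt1 <- 0.5 * (1 + min(1, ad / m))
    wt1 * lo + (1 - wt1) * hi
  } else {
    m
  }
}

# Brute-force collocation statistics from explicit sums (no cor()/lm()).
stats_oracle <- function(cand, ref) {
  n <- length(cand)
  mx <- sum(cand) / n
  my <- sum(ref) / n
  sxy <- sum((cand - mx) * (ref - my))
  sxx <- sum((cand - mx)^2)
  syy <- sum((ref - my)^2)
  r <- sxy / sqrt(sxx * syy)
  list(
    r = r,
    r_se = sqrt((1 - r^2) / (n - 2)),
    rmse = sqrt(sum((cand - ref)^2) / n),
    rma_slope = sign(r) * sqrt(syy / sxx),
    ols_slope = sxy / sxx,
    ols_intercept = my - (sxy / sxx) * mx
  )
}

# random monotone cumulative count vectors (possibly fractional)
random_counts <- function(n) {
  n1 <- stats::runif(n, 0, 5000)
  n2 <- stats::runif(n, 0, 500)
  n3 <- stats::runif(n, 0, 50)
  n4 <- stats::runif(n, 0, 5)
  tibble::tibble(
    n_gt_2p5 = n4, n_gt_1 = n4 + n3, n_gt_0p5 = n4 + n3 + n2,
    n_gt_0p3 = n4 + n3 + n2 + n1
  )
}

# small daily series helper: `complete`, non-excluded days
daily_series <- function(dates, pm25) {
  tibble::tibble(date = lubridate::as_date(dates), pm25 = pm25,
                 n_hours = 24L, complete = TRUE)
}

lst <- function(x) as.POSIXct(x, tz = "UTC")
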