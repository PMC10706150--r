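test_that("paired_days inner-joins complete, non-excluded days", {
  dates <- lubridate::as_date("2022-05-01") + 0:9
  ref <- daily_series(dates, 1:10)
  cand <- daily_series(dates, 2:11)
  expect_equal(nrow(paired_days(ref, cand)), 10)
  expect_equal(nrow(paired_days(ref[-c(1, 2), ], cand)), 8)
  ref_x <- apply_exclusions(ref, exclusion_windows("all", dates[1], dates[10]))
  expect_error(paired_days(ref_x, cand), class = "pacolloc_empty_intersection")
})

test_that("identity and exact-scaling inputs give closed-form statistics", {
  withr::with_seed(31, v <- runif(10, 2, 30))
  ident <- collocation_stats(tibble::tibble(ref = v, cand = v))
  expect_equal(ident$r, 1)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$rma_slope, 1)
  expect_equal(ident$ols_slope, 1)
  expect_equal(ident$ols_intercept, 0, tolerance = 1e-12)
  doubled <- collocation_stats(tibble::tibble(ref = 2 * v, cand = v))
  expect_equal(doubled$rma_slope, 2)
  expect_equal(doubled$ols_slope, 2)
  expect_equal(doubled$ols_intercept, 0, tolerance = 1e-12)
  expect_equal(doubled$rmse, sqrt(mean(v^2)))
  expect_error(collocation_stats(tibble::tibble(ref = c(1, 2), cand = c(1, 2))),
               class = "pacolloc_insufficient_pairs")
  expect_error(collocation_stats(tibble::tibble(ref = rep(3, 5), cand = 1:5)),
               class = "pacolloc_degenerate_series")
})

test_that("statistics match a brute-force formula oracle on random pairs", {
  withr::with_seed(32, {
    cand <- runif(50, 0, 40)
    ref <- 0.9 * cand + rnorm(50, 0, 3)
  })
  got <- collocation_stats(tibble::tibble(ref = ref, cand = cand))
  want <- stats_oracle(cand, ref)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$r_se, want$r_se, tolerance = 1e-12)
  expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
  expect_equal(got$rma_slope, want$rma_slope, tolerance = 1e-12)
  expect_equal(got$ols_slope, want$ols_slope, tolerance = 1e-12)
  expect_equal(got$ols_intercept, want$ols_intercept, tolerance = 1e-12)
})

test_that("RMA is reciprocal under axis swap and OLS attenuates relative to it", {
  withr::with_seed(33, {
    cand <- runif(80, 0, 40)
    ref <- 1.2 * cand + rnorm(80, 0, 4)
  })
  fwd <- collocation_stats(tibble::tibble(ref = ref, cand = cand))
  rev <- collocation_stats(data.frame(ref = cand, cand = ref))
  expect_equal(fwd$rma_slope * rev$rma_slope, 1, tolerance = 1e-12)
  expect_lte(abs(fwd$ols_slope), abs(fwd$rma_slope))
  # rmse is invariant to pair order
  perm <- sample(80)
  shuf <- collocation_stats(tibble::tibble(ref = ref[perm], cand = cand[perm]))
  expect_equal(shuf$rmse, fwd$rmse)
  expect_equal(shuf$r, fwd$r)
})

test_that("rmse estimates the candidate noise scale on collocated data", {
  sigma <- 2.5
  withr::with_seed(34, {
    truth <- runif(2000, 0, 40)
    cand <- truth + rnorm(2000, 0, sigma)
  })
  got <- collocation_stats(tibble::tibble(ref = truth, cand = cand))
  expect_equal(got$rmse, sigma, tolerance = 0.1 * sigma)
})

test_that("residual diagnostics recover the coarse-aerosol bias signature", {
  n <- 120
  withr::with_seed(35, {
    p1 <- runif(n, 0.6, 0.98)
    ref <- runif(n, 3, 25)
    # candidate misses coarse mass: underestimates most when p1 is low
    cand <- ref - 4 * (1 - p1) + rnorm(n, 0, 0.3)
    pm_ratio <- 0.3 + 0.6 * (p1 - 0.6) / 0.38 + rnorm(n, 0, 0.03)
  })
  pairs <- tibble::tibble(ref = ref, cand = cand, p1 = p1, pm_ratio = pm_ratio)
  diag <- residual_diagnostics(pairs)
  # by construction low-P1 (dusty) days underestimate: residuals fall with P1
  # and with the PM2.5/PM10 ratio
  expect_lt(diag$r_resid_p1, -0.5)
  expect_lt(diag$r_resid_ratio, -0.5)
  # residuals exactly equal to p1: perfect positive correlation
  exact <- tibble::tibble(ref = p1 + 5, cand = rep(5, n), p1 = p1)
  expect_equal(residual_diagnostics(exact)$r_resid_p1, 1)
  # constant residuals: undefined, flagged degenerate
  const <- tibble::tibble(ref = 1:10 + 2, cand = 1:10, p1 = runif(10))
  expect_warning(out <- residual_diagnostics(const),
                 class = "pacolloc_degenerate_series")
  expect_true(is.na(out$r_resid_p1))
})
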